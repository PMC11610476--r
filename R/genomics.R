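# Genomic stages: chromosomal distribution, tandem-duplication detection
# from gene order plus global protein identity, exon/intron structure.

#' Gene counts per chromosome
#'
#' @param genes A gene-model table (see [read_gene_models()]).
#' @return Named integer vector of counts in natural chromosome order;
#'   counts sum to the number of genes.
#' @export
chromosome_distribution <- function(genes) {
  if (nrow(genes) == 0) return(stats::setNames(integer(), character()))
  uc <- unique(genes$chromosome)
  uc <- uc[natural_chrom_order(uc)]
  tab <- table(factor(genes$chromosome, levels = uc))
  stats::setNames(as.integer(tab), names(tab))
}

#' Percent identity of two proteins by global alignment
#'
#' Needleman-Wunsch global alignment via [Biostrings::pairwiseAlignment()]
#' with BLOSUM62, gap opening 10 and gap extension 0.5; identity is
#' matches / alignment length (PID1).
#'
#' @param seq_a,seq_b Amino-acid strings.
#' @return Percent identity in [0, 100].
#' @export
protein_identity <- function(seq_a, seq_b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  Biostrings::pid(aln, type = "PID1")
}

#' Detect tandem-duplicated gene pairs
#'
#' Tandem duplicates are adjacent paralogous family genes on the same
#' chromosome: pairs separated by at most `max_intervening` other family
#' genes in chromosomal order whose encoded proteins share at least
#' `min_identity` percent global identity (see [protein_identity()]).
#'
#' @param genes Gene-model table with `gene_id`, `chromosome`, `start`,
#'   `protein_id`.
#' @param proteins Protein table supplying the encoded sequences (matched on
#'   `protein_id`).
#' @param max_intervening Maximum number of family genes allowed between the
#'   two members of a pair.
#' @param min_identity Minimum percent identity.
#' @return A data.frame `gene_a`, `gene_b`, `chromosome`,
#'   `intervening_genes`, `identity`, with `gene_a` upstream of `gene_b`.
#' @export
detect_tandem_duplicates <- function(genes, proteins, max_intervening = 1,
                                     min_identity = 70) {
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      chromosome = character(), intervening_genes = integer(),
                      identity = numeric(), stringsAsFactors = FALSE)
  if (nrow(genes) < 2) return(empty)
  seq_of <- stats::setNames(proteins$sequence, proteins$id)
  missing <- setdiff(genes$protein_id, names(seq_of))
  if (length(missing)) {
    warning("no protein sequence for gene(s) encoding: ",
            paste(missing, collapse = ", "), "; skipped", call. = FALSE)
    genes <- genes[genes$protein_id %in% names(seq_of), , drop = FALSE]
  }
  rows <- list()
  for (chrom in unique(genes$chromosome)) {
    g <- genes[genes$chromosome == chrom, , drop = FALSE]
    g <- g[order(g$start, g$end, g$gene_id), , drop = FALSE]
    n <- nrow(g)
    if (n < 2) next
    for (i in seq_len(n - 1)) {
      for (j in seq.int(i + 1, min(n, i + 1 + max_intervening))) {
        ident <- protein_identity(seq_of[[g$protein_id[i]]],
                                  seq_of[[g$protein_id[j]]])
        if (ident >= min_identity) {
          rows[[length(rows) + 1]] <- data.frame(
            gene_a = g$gene_id[i], gene_b = g$gene_id[j],
            chromosome = chrom, intervening_genes = j - i - 1L,
            identity = ident, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Exon/intron structure summary
#'
#' Per-gene exon and intron counts (introns = exons - 1) and, when a
#' subset assignment is supplied, the mean intron count per subset reported
#' to one decimal.
#'
#' @param genes Gene-model table with `gene_id` and `n_exons` (or an
#'   `exons` list-column).
#' @param subsets Optional named character vector mapping `gene_id` to a
#'   subset label.
#' @return A list with `per_gene` (data.frame `gene_id`, `n_exons`,
#'   `n_introns`) and `per_subset` (data.frame `subset`, `n_genes`,
#'   `mean_introns`; NULL when `subsets` is missing).
#' @export
exon_intron_structure <- function(genes, subsets = NULL) {
  n_exons <- if ("n_exons" %in% names(genes)) genes$n_exons
             else vapply(genes$exons, nrow, integer(1))
  per_gene <- data.frame(gene_id = genes$gene_id,
                         n_exons = as.integer(n_exons),
                         n_introns = as.integer(n_exons) - 1L,
                         stringsAsFactors = FALSE)
  per_subset <- NULL
  if (!is.null(subsets)) {
    lab <- subsets[per_gene$gene_id]
    keep <- !is.na(lab)
    if (any(keep)) {
      agg <- stats::aggregate(per_gene$n_introns[keep],
                              by = list(subset = lab[keep]),
                              FUN = function(v) round(mean(v), 1))
      cnt <- table(lab[keep])
      per_subset <- data.frame(subset = agg$subset,
                               n_genes = as.integer(cnt[agg$subset]),
                               mean_introns = agg$x,
                               stringsAsFactors = FALSE)
    }
  }
  list(per_gene = per_gene, per_subset = per_subset)
}
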