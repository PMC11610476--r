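# Reading/writing the standard formats the pipeline touches, plus the
# chromosome-order gene nomenclature.

#' Read a protein FASTA file into a validated protein table
#'
#' Wraps [Biostrings::readAAStringSet()] and enforces the conventions the
#' rest of the pipeline assumes: uppercase single-letter residues, unique
#' identifiers (the first whitespace-delimited token of each header), no
#' empty sequences, and an alphabet restricted to the 20 standard residues
#' plus `X`. `X` residues are tolerated with a warning (downstream
#' physicochemical sums skip them); any other letter is an error.
#'
#' @param path Path to a FASTA file.
#' @param source Provenance tag recorded on every record (defaults to the
#'   file name).
#' @return A data.frame with columns `id`, `sequence`, `source`.
#' @export
read_protein_fasta <- function(path, source = basename(path)) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  set <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  seqs <- toupper(as.character(set))
  as_protein_table(ids, seqs, source)
}

#' Assemble and validate a protein table from vectors
#'
#' @param ids Character vector of identifiers.
#' @param sequences Character vector of amino-acid sequences.
#' @param source Provenance tag.
#' @return A data.frame with columns `id`, `sequence`, `source`.
#' @export
as_protein_table <- function(ids, sequences, source = "in-memory") {
  stopifnot(length(ids) == length(sequences))
  sequences <- toupper(gsub("[\\s*]", "", sequences, perl = TRUE))
  if (length(ids) == 0) {
    return(data.frame(id = character(), sequence = character(),
                      source = character(), stringsAsFactors = FALSE))
  }
  if (anyNA(ids) || any(!nzchar(ids))) {
    stop("malformed FASTA header: empty identifier")
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate sequence identifier(s): ", paste(dup, collapse = ", "))
  }
  empty <- ids[!nzchar(sequences)]
  if (length(empty)) {
    stop("empty sequence for entry: ", paste(empty, collapse = ", "))
  }
  allowed <- c(AA_STANDARD, "X")
  for (i in seq_along(sequences)) {
    res <- unique(strsplit(sequences[i], "")[[1]])
    bad <- setdiff(res, allowed)
    if (length(bad)) {
      stop("entry ", ids[i], " contains non-standard residue(s): ",
           paste(bad, collapse = ", "))
    }
    if ("X" %in% res) {
      warning("entry ", ids[i],
              " contains X residues; they are excluded from ",
              "physicochemical sums", call. = FALSE)
    }
  }
  data.frame(id = ids, sequence = sequences, source = source,
             stringsAsFactors = FALSE)
}

#' Write a protein table to FASTA
#'
#' @param proteins A protein table (see [read_protein_fasta()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(proteins, path) {
  set <- Biostrings::AAStringSet(proteins$sequence)
  names(set) <- proteins$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Parses gene/mRNA/exon features via [rtracklayer::import()] and collapses
#' each gene to a single transcript model: when a gene has several mRNAs the
#' exon set of the longest mRNA (largest summed exon length) is used.
#' Coordinates are 1-based inclusive throughout.
#'
#' @param path Path to a GFF3 file.
#' @return A data.frame with one row per gene: `gene_id`, `chromosome`,
#'   `start`, `end`, `strand`, `protein_id`, `n_exons`, and a list-column
#'   `exons` of two-column (start, end) matrices sorted by start.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) {
    stop("GFF3 file not found: ", path)
  }
  gr <- rtracklayer::import(path, format = "gff3")
  meta <- S4Vectors::mcols(gr)
  type <- as.character(meta$type)
  get_id <- function(x) as.character(x$ID)
  first_parent <- function(x) {
    p <- x$Parent
    vapply(as.list(p), function(v) if (length(v)) as.character(v)[1] else NA_character_,
           character(1))
  }
  genes <- gr[type == "gene"]
  mrnas <- gr[type %in% c("mRNA", "transcript")]
  exons <- gr[type == "exon"]
  if (length(genes) == 0) stop("no gene features in ", path)
  mrna_parent <- first_parent(S4Vectors::mcols(mrnas))
  exon_parent <- first_parent(S4Vectors::mcols(exons))
  if (length(exons) && anyNA(exon_parent)) {
    stop("exon feature(s) without a Parent link in ", path)
  }
  if (length(mrnas) && anyNA(mrna_parent)) {
    stop("mRNA feature(s) without a Parent link in ", path)
  }
  gene_ids <- get_id(S4Vectors::mcols(genes))
  mrna_ids <- get_id(S4Vectors::mcols(mrnas))
  rows <- lapply(seq_along(genes), function(i) {
    gid <- gene_ids[i]
    g <- genes[i]
    mi <- which(mrna_parent == gid)
    if (length(mi) == 0) {
      stop("gene ", gid, " has no mRNA children")
    }
    exon_sets <- lapply(mi, function(j) {
      ei <- which(exon_parent == mrna_ids[j])
      if (length(ei) == 0) stop("mRNA ", mrna_ids[j], " has no exons")
      ex <- exons[ei]
      m <- cbind(start = GenomicRanges::start(ex), end = GenomicRanges::end(ex))
      m[order(m[, "start"]), , drop = FALSE]
    })
    lens <- vapply(exon_sets, function(m) sum(m[, "end"] - m[, "start"] + 1L),
                   numeric(1))
    best <- mi[which.max(lens)]
    ex <- exon_sets[[which.max(lens)]]
    gs <- GenomicRanges::start(g); ge <- GenomicRanges::end(g)
    if (any(ex[, "start"] < gs) || any(ex[, "end"] > ge)) {
      stop("exon outside gene span for gene ", gid)
    }
    if (nrow(ex) > 1 && any(ex[-1, "start"] <= ex[-nrow(ex), "end"])) {
      stop("overlapping exons in gene ", gid)
    }
    pid <- S4Vectors::mcols(mrnas[match(best, seq_along(mrnas))])$protein_id
    if (is.null(pid) || is.na(pid)) pid <- mrna_ids[best]
    list(gene_id = gid,
         chromosome = as.character(GenomicRanges::seqnames(g)),
         start = gs, end = ge,
         strand = as.character(GenomicRanges::strand(g)),
         protein_id = as.character(pid),
         exons = ex)
  })
  out <- data.frame(
    gene_id = vapply(rows, `[[`, character(1), "gene_id"),
    chromosome = vapply(rows, `[[`, character(1), "chromosome"),
    start = vapply(rows, `[[`, numeric(1), "start"),
    end = vapply(rows, `[[`, numeric(1), "end"),
    strand = vapply(rows, `[[`, character(1), "strand"),
    protein_id = vapply(rows, `[[`, character(1), "protein_id"),
    stringsAsFactors = FALSE
  )
  out$n_exons <- vapply(rows, function(r) nrow(r$exons), integer(1))
  out$exons <- lapply(rows, `[[`, "exons")
  out
}

#' Natural ordering of chromosome names
#'
#' Chromosomes carrying a numeric suffix (Zj01, chr2, 10, ...) sort by that
#' number; names without one (unplaced scaffolds) sort after all numbered
#' chromosomes, alphabetically.
#'
#' @param chroms Character vector of chromosome names.
#' @return An integer ranking usable with [order()].
#' @export
natural_chrom_order <- function(chroms) {
  num <- suppressWarnings(as.numeric(sub("^.*?(\\d+)\\s*$", "\\1", chroms)))
  has_num <- grepl("\\d+\\s*$", chroms)
  num[!has_num] <- NA
  order(ifelse(has_num, 0L, 1L), num, chroms)
}

#' Name family genes by chromosomal order
#'
#' Genes are sorted by chromosome (natural order, see
#' [natural_chrom_order()]) and ascending start coordinate, then named
#' `prefix-1` .. `prefix-N`. Ties on (chromosome, start) are broken by end
#' coordinate and then gene id, with a warning.
#'
#' @param genes A gene-model table (see [read_gene_models()]), or any
#'   data.frame with `gene_id`, `chromosome`, `start` (and optionally `end`).
#' @param prefix Name prefix, e.g. `"ZjC2H2"`.
#' @return A data.frame `gene_id`, `name`, `chromosome`, `start` in naming
#'   order; the gene_id -> name mapping is a bijection.
#' @export
assign_gene_names <- function(genes, prefix) {
  stopifnot(all(c("gene_id", "chromosome", "start") %in% names(genes)))
  if (nrow(genes) == 0) {
    return(data.frame(gene_id = character(), name = character(),
                      chromosome = character(), start = numeric(),
                      stringsAsFactors = FALSE))
  }
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id")
  key <- paste(genes$chromosome, genes$start)
  if (anyDuplicated(key)) {
    warning("genes with identical (chromosome, start); ",
            "tie broken by end then gene_id", call. = FALSE)
  }
  uc <- unique(genes$chromosome)
  uc_sorted <- uc[natural_chrom_order(uc)]
  chrom_rank <- match(genes$chromosome, uc_sorted)
  end <- if ("end" %in% names(genes)) genes$end else rep(0, nrow(genes))
  ord <- order(chrom_rank, genes$start, end, genes$gene_id)
  out <- data.frame(
    gene_id = genes$gene_id[ord],
    name = paste0(prefix, "-", seq_len(nrow(genes))),
    chromosome = genes$chromosome[ord],
    start = genes$start[ord],
    stringsAsFactors = FALSE
  )
  out
}

#' Write a tab-separated table
#'
#' Thin wrapper with the conventions used for every report the pipeline
#' emits (no quoting, no row names).
#'
#' @param x A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(x, path) {
  is_list <- vapply(x, is.list, logical(1))
  x[is_list] <- lapply(x[is_list], function(col)
    vapply(col, function(v) paste(unlist(v), collapse = ","), character(1)))
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
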