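# Synthetic-data generators: proteomes with planted finger architectures,
# FPKM matrices with planted profile groups, enzyme panels with treatment
# effects, and toy gene models. Background residues exclude C and H so no
# unplanned fingers can arise and round-trip tests are exact; a "hostile"
# mode re-admits them to stress-test the scanner.

# residue alphabet for background/filler positions
.background_alphabet <- function(hostile = FALSE) {
  if (hostile) AA_STANDARD else setdiff(AA_STANDARD, c("C", "H"))
}

.bg <- function(n, alphabet) {
  if (n <= 0) return("")
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

#' Describe a planted finger architecture
#'
#' @param label Planted classification label (e.g. `"A1a"`, `"B"`,
#'   `"C1-2"`, `"C2"`, `"C1C2mixed"`); recovered by the classifier on the
#'   generated protein.
#' @param signatures Character vector of finger spacing signatures in order
#'   (see [parse_signature()]).
#' @param linkers Integer vector of residue counts between consecutive
#'   fingers (length = fingers - 1).
#' @param qalggh If `TRUE`, insert QALGGH at the start of the first
#'   finger's helix.
#' @param satall If `TRUE`, append the SATALLQKAAQMGS block near the C
#'   terminus.
#' @param pcycc If `TRUE`, insert PCYCC in a non-finger region after the
#'   last finger.
#' @param flank Residue counts of background before the first and after the
#'   last finger.
#' @return An object of class `architecture_spec`.
#' @export
finger_architecture <- function(label, signatures, linkers = integer(),
                                qalggh = FALSE, satall = FALSE,
                                pcycc = FALSE, flank = c(15, 15)) {
  stopifnot(length(signatures) >= 0,
            length(linkers) == max(0, length(signatures) - 1),
            all(linkers >= 0))
  lapply(signatures, parse_signature)  # validates
  structure(list(label = label, signatures = signatures,
                 linkers = as.integer(linkers), qalggh = isTRUE(qalggh),
                 satall = isTRUE(satall), pcycc = isTRUE(pcycc),
                 flank = as.integer(flank)),
            class = "architecture_spec")
}

#' Realize one protein from an architecture
#'
#' Coordinating residues are placed exactly per signature; all other
#' positions (helices, gaps, linkers, flanks) are drawn from a background
#' distribution that excludes C and H, so the planted fingers are the only
#' grammar matches. Requested motifs go to their canonical locations:
#' QALGGH at the start of the first helix (its histidine then lies well
#' inside the helix and cannot seed a spurious parse), PCYCC in the
#' non-finger region after the last finger followed by a guard of
#' background, SATALLQKAAQMGS at the C terminus.
#'
#' @param arch An [finger_architecture()].
#' @param seed Optional integer seed (sets the RNG; generation is
#'   deterministic per seed).
#' @param hostile If `TRUE`, background residues may include C and H.
#' @return A single amino-acid string.
#' @export
make_protein <- function(arch, seed = NULL, hostile = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  alpha <- .background_alphabet(hostile)
  pieces <- .bg(arch$flank[1], alpha)
  for (i in seq_along(arch$signatures)) {
    sig <- parse_signature(arch$signatures[i])
    helix_len <- sig$gaps[2]
    helix <- if (arch$qalggh && i == 1) {
      if (helix_len < nchar(MOTIF_QALGGH)) {
        stop("helix too short for QALGGH in finger ", i)
      }
      paste0(MOTIF_QALGGH, .bg(helix_len - nchar(MOTIF_QALGGH), alpha))
    } else {
      .bg(helix_len, alpha)
    }
    finger <- paste0("C", .bg(sig$gaps[1], alpha), "C", helix,
                     sig$terminals[1], .bg(sig$gaps[3], alpha),
                     sig$terminals[2])
    pieces <- paste0(pieces, finger)
    if (i < length(arch$signatures)) {
      pieces <- paste0(pieces, .bg(arch$linkers[i], alpha))
    }
  }
  if (arch$pcycc) {
    # guard background on both sides keeps the motif's cysteines from
    # completing a grammar window with any planted residue
    pieces <- paste0(pieces, .bg(25, alpha), MOTIF_PCYCC, .bg(25, alpha))
  }
  if (arch$satall) {
    pieces <- paste0(pieces, .bg(5, alpha), MOTIF_SATALL_FULL)
  }
  paste0(pieces, .bg(arch$flank[2], alpha))
}

#' Built-in architecture presets for every classification label
#'
#' Templates mirroring the published family layout: the four A1 subsets use
#' the published four-finger signature rows (tandem linkers) plus their
#' diagnostic motifs; A2 is three fingers split into a tandem pair plus a
#' dispersed finger; A4 is a single tandem array of three canonical
#' fingers; B is the nine-finger TF3A layout with linkers
#' (20,5,5,30,5,5,5,5) giving an isolated first finger plus tandem arrays
#' 2-4 and 5-9; C1-k is k dispersed canonical fingers (H-gap 3); C2 and C3
#' are single fingers with H-gaps 4 and 5; C1C2mixed is one H-gap-3 and one
#' H-gap-4 finger, dispersed.
#'
#' @return Named list of [finger_architecture()] objects.
#' @export
architecture_presets <- function() {
  t1 <- a1_templates()
  a1 <- function(subset) {
    r <- t1[t1$subset == subset, ]
    finger_architecture(subset,
                        c(r$finger1, r$finger2, r$finger3, r$finger4),
                        linkers = c(6, 6, 6), qalggh = TRUE,
                        satall = identical(r$motif, "SATALL"),
                        pcycc = identical(r$motif, "PCYCC"))
  }
  can <- "CX2CX12HX3H"
  presets <- list(
    A1a = a1("A1a"), A1b = a1("A1b"), A1c = a1("A1c"), A1d = a1("A1d"),
    A2 = finger_architecture("A2", rep(can, 3), linkers = c(5, 20),
                             qalggh = TRUE),
    A4 = finger_architecture("A4", rep(can, 3), linkers = c(5, 5),
                             qalggh = TRUE),
    B = finger_architecture("B", rep(can, 9),
                            linkers = c(20, 5, 5, 30, 5, 5, 5, 5)),
    C2 = finger_architecture("C2", "CX2CX12HX4H", qalggh = TRUE),
    C3 = finger_architecture("C3", "CX2CX12HX5H"),
    C1C2mixed = finger_architecture("C1C2mixed",
                                    c("CX2CX12HX3H", "CX2CX12HX4H"),
                                    linkers = 15, qalggh = TRUE)
  )
  for (k in 1:5) {
    presets[[paste0("C1-", k)]] <-
      finger_architecture(paste0("C1-", k), rep(can, k),
                          linkers = rep(15L, max(0, k - 1)), qalggh = TRUE)
  }
  presets
}

#' Default proteome composition of the synthetic study
#'
#' Copies per architecture label mirroring the published 77-protein family:
#' A1a-d 13/1/3/7, A2 2, A4 3, B 2, C1-1..C1-5 19/11/1/2/1, C1C2mixed 2,
#' C2 9, C3 1.
#'
#' @return Named integer vector label -> copies (sums to 77).
#' @export
study_proteome_composition <- function() {
  c(A1a = 13L, A1b = 1L, A1c = 3L, A1d = 7L, A2 = 2L, A4 = 3L, B = 2L,
    "C1-1" = 19L, "C1-2" = 11L, "C1-3" = 1L, "C1-4" = 2L, "C1-5" = 1L,
    C1C2mixed = 2L, C2 = 9L, C3 = 1L)
}

#' Generate a synthetic proteome with planted labels
#'
#' @param composition Named integer vector label -> copies; labels must
#'   exist in [architecture_presets()] (or supply `presets`). Default:
#'   [study_proteome_composition()].
#' @param seed Integer seed; identical composition + seed gives
#'   byte-identical output.
#' @param presets Optional list of [finger_architecture()] objects.
#' @param hostile Background may include C/H (stress-test mode).
#' @param id_prefix Identifier prefix for generated proteins.
#' @return A list: `proteins` (protein table) and `truth` (data.frame
#'   `protein_id`, `label`).
#' @export
make_proteome <- function(composition = study_proteome_composition(),
                          seed = 1, presets = architecture_presets(),
                          hostile = FALSE, id_prefix = "SYN") {
  set.seed(seed)
  missing <- setdiff(names(composition), names(presets))
  if (length(missing)) stop("no preset for label(s): ",
                            paste(missing, collapse = ", "))
  ids <- character(); labels <- character(); seqs <- character()
  idx <- 0L
  for (lab in names(composition)) {
    for (copy in seq_len(composition[[lab]])) {
      idx <- idx + 1L
      ids <- c(ids, sprintf("%s%03d", id_prefix, idx))
      labels <- c(labels, lab)
      seqs <- c(seqs, make_protein(presets[[lab]], hostile = hostile))
    }
  }
  list(proteins = as_protein_table(ids, seqs, source = "synthetic"),
       truth = data.frame(protein_id = ids, label = labels,
                          stringsAsFactors = FALSE))
}

# Gaussian-bump archetype profiles in [0, 1]: k profiles over m conditions
# with peaks sliding across the condition axis.
.profile_archetypes <- function(k, m) {
  centers <- seq(1, m, length.out = k)
  arch <- t(vapply(centers, function(ctr)
    exp(-0.5 * ((seq_len(m) - ctr) / 0.8)^2), numeric(m)))
  arch
}

#' Generate an FPKM matrix with planted profile groups
#'
#' Expressed genes are split round-robin over `k` archetype profiles
#' (Gaussian bumps whose peaks slide across the conditions); their FPKM is
#' `base + span * archetype + Normal(0, noise_sd)` truncated at zero. A
#' designated number of genes is scaled below the expression threshold
#' (uniform values below it) so the expression filter removes them.
#'
#' @param n_genes Total genes (default 77).
#' @param conditions Condition labels (default the four water-stress
#'   treatments CK/LS/MS/SS).
#' @param k Planted profile groups (default 7).
#' @param n_below Genes kept below the FPKM threshold (default 34, leaving
#'   43 expressed).
#' @param noise_sd Gaussian noise sd on the linear FPKM scale (0 for exact
#'   round trips).
#' @param base,span Linear-scale offset and amplitude of the archetypes.
#' @param threshold Expression threshold the silent genes stay below.
#' @param seed Integer seed.
#' @param gene_ids Optional gene identifiers (length `n_genes`).
#' @return A list: `fpkm` (matrix genes x conditions), `truth` (data.frame
#'   `gene_id`, `group`; NA group for the below-threshold genes).
#' @export
make_fpkm <- function(n_genes = 77, conditions = c("CK", "LS", "MS", "SS"),
                      k = 7, n_below = 34, noise_sd = 0, base = 5,
                      span = 45, threshold = 1, seed = 1, gene_ids = NULL) {
  stopifnot(n_below >= 0, n_below <= n_genes, n_genes - n_below >= k || k == 0)
  set.seed(seed)
  m <- length(conditions)
  if (is.null(gene_ids)) gene_ids <- sprintf("gene%03d", seq_len(n_genes))
  arch <- .profile_archetypes(k, m)
  n_expr <- n_genes - n_below
  group <- rep(seq_len(k), length.out = n_expr)
  fpkm <- matrix(0, n_genes, m, dimnames = list(gene_ids, conditions))
  for (i in seq_len(n_expr)) {
    mu <- base + span * arch[group[i], ]
    fpkm[i, ] <- pmax(0, mu + stats::rnorm(m, 0, noise_sd))
  }
  if (n_below > 0) {
    fpkm[seq.int(n_expr + 1, n_genes), ] <-
      matrix(stats::runif(n_below * m, 0, 0.9 * threshold), n_below, m)
  }
  truth <- data.frame(gene_id = gene_ids,
                      group = c(group, rep(NA_integer_, n_below)),
                      stringsAsFactors = FALSE)
  list(fpkm = fpkm, truth = truth)
}

#' Generate a synthetic enzyme panel
#'
#' Replicate values drawn Normal(mean, sd) per (treatment, analyte); the
#' default truth is the published water-stress reference panel
#' ([enzyme_reference()]) with n = 3 replicates.
#'
#' @param reference Data.frame `treatment`, `analyte`, `mean`, `sd` (and
#'   optionally `unit`); defaults to [enzyme_reference()].
#' @param n_replicates Replicates per cell (default 3).
#' @param seed Integer seed.
#' @return Long-format data.frame `treatment`, `replicate`, `analyte`,
#'   `unit`, `value`.
#' @export
make_enzyme_panel <- function(reference = enzyme_reference(),
                              n_replicates = 3, seed = 1) {
  stopifnot(n_replicates >= 1)
  if (any(reference$sd < 0)) stop("negative sd in reference")
  set.seed(seed)
  rows <- list()
  for (r in seq_len(nrow(reference))) {
    v <- stats::rnorm(n_replicates, reference$mean[r], reference$sd[r])
    rows[[length(rows) + 1]] <- data.frame(
      treatment = reference$treatment[r],
      replicate = seq_len(n_replicates),
      analyte = reference$analyte[r],
      unit = if ("unit" %in% names(reference)) reference$unit[r] else "",
      value = v, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate toy gene models for a synthetic proteome
#'
#' Places one gene per protein across chromosomes (default: 12 chromosomes
#' with the published per-chromosome family counts, max 10 on the second,
#' one on the eleventh), with non-overlapping coordinates and random exon
#' counts. A designated pair of consecutive genes on the same chromosome is
#' planted as a tandem duplication by making the second gene encode the
#' first gene's protein sequence.
#'
#' @param proteins A protein table (the planted duplicate rewrites the
#'   sequence of the second pair member; the returned list carries the
#'   adjusted table).
#' @param chrom_counts Named integer vector chromosome -> gene count
#'   summing to `nrow(proteins)`.
#' @param tandem_pair Integer 2-vector of gene indices (in naming order) to
#'   plant as a duplicated pair, or NULL.
#' @param seed Integer seed.
#' @return A list: `genes` (gene-model table with `gene_id`, `chromosome`,
#'   `start`, `end`, `strand`, `protein_id`, `n_exons`), `proteins` (the
#'   possibly adjusted protein table).
#' @export
make_gene_models <- function(proteins,
                             chrom_counts = c(Zj01 = 7, Zj02 = 10, Zj03 = 3,
                                              Zj04 = 8, Zj05 = 7, Zj06 = 8,
                                              Zj07 = 7, Zj08 = 7, Zj09 = 6,
                                              Zj10 = 6, Zj11 = 1, Zj12 = 7),
                             tandem_pair = c(21, 22), seed = 1) {
  n <- nrow(proteins)
  if (sum(chrom_counts) != n) {
    stop("chrom_counts must sum to the number of proteins (", n, ")")
  }
  set.seed(seed)
  chrom <- rep(names(chrom_counts), chrom_counts)
  start <- unlist(lapply(chrom_counts, function(cnt)
    cumsum(5000 + sample.int(200000, cnt))))
  width <- 1000 + sample.int(3000, n)
  genes <- data.frame(
    gene_id = paste0("gene:", proteins$id),
    chromosome = chrom,
    start = as.numeric(start),
    end = as.numeric(start + width),
    strand = sample(c("+", "-"), n, replace = TRUE),
    protein_id = proteins$id,
    n_exons = sample(1:8, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  if (!is.null(tandem_pair)) {
    a <- tandem_pair[1]; b <- tandem_pair[2]
    stopifnot(a >= 1, b <= n, genes$chromosome[a] == genes$chromosome[b])
    proteins$sequence[b] <- proteins$sequence[a]
  }
  list(genes = genes, proteins = proteins)
}
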