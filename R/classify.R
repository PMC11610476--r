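# Hierarchical structural classification of C2H2 zinc-finger proteins:
# sets A/B/C from the tandem-array layout, subgroups and subsets from
# finger spacing (H-gaps), spacing-signature templates and diagnostic
# motifs.

#' Classification configuration
#'
#' Tunable rules of the structural classifier. The defaults reproduce the
#' published jujube family layout: set B is triggered by a TF3A-like
#' architecture (at least `set_b_min_fingers` fingers organized in at least
#' `set_b_min_arrays` tandem arrays); set A requires at least one tandem
#' array of two or more fingers; everything else with fingers is set C.
#' Within non-A1 set A members, proteins whose fingers span more than one
#' arrangement component (a tandem array plus extra dispersed fingers) are
#' A2, proteins with a single tandem array are A4; this boundary is a
#' documented heuristic.
#'
#' @param tandem_threshold Maximum linker length (residues) for a tandem
#'   arrangement.
#' @param set_b_min_fingers Minimum finger count for set B.
#' @param set_b_min_arrays Minimum tandem-array count for set B.
#' @param a2_min_fingers Minimum finger count for the A2 multi-component
#'   rule.
#' @return A list of class `classify_config`.
#' @export
classify_config <- function(tandem_threshold = 10, set_b_min_fingers = 6,
                            set_b_min_arrays = 2, a2_min_fingers = 3) {
  structure(list(tandem_threshold = tandem_threshold,
                 set_b_min_fingers = set_b_min_fingers,
                 set_b_min_arrays = set_b_min_arrays,
                 a2_min_fingers = a2_min_fingers),
            class = "classify_config")
}

#' Detect a diagnostic motif in a protein
#'
#' Three motifs are recognized: `QALGGH` (the plant Q-type hexapeptide,
#' searched only inside finger helices, i.e. between the second cysteine and
#' the first terminal residue of each finger), `SATALL` (the lead of the
#' conserved C-terminal SATALLQKAAQMGS block, searched in the region after
#' the last finger), and `PCYCC` (a conserved non-finger block, searched
#' anywhere). The `region` argument can override the default search region.
#'
#' @param sequence Amino-acid string.
#' @param motif One of `"QALGGH"`, `"SATALL"`, `"PCYCC"`.
#' @param region `"helix"`, `"c_terminal"` or `"anywhere"`; defaults to the
#'   motif's canonical region.
#' @param fingers Finger table from [scan_fingers()]; required for
#'   region `"helix"` and used to delimit `"c_terminal"`.
#' @return A list with `found` (logical) and `positions` (integer vector of
#'   match starts in the full sequence).
#' @export
detect_motif <- function(sequence, motif = c("QALGGH", "SATALL", "PCYCC"),
                         region = NULL, fingers = NULL) {
  motif <- match.arg(motif)
  if (is.null(region)) {
    region <- switch(motif, QALGGH = "helix", SATALL = "c_terminal",
                     PCYCC = "anywhere")
  }
  pattern <- switch(motif, QALGGH = MOTIF_QALGGH, SATALL = MOTIF_SATALL,
                    PCYCC = MOTIF_PCYCC)
  hit_positions <- function(text, offset = 0L) {
    p <- gregexpr(pattern, text, fixed = TRUE)[[1]]
    if (p[1] == -1) integer() else as.integer(p) + offset
  }
  positions <- switch(
    region,
    anywhere = hit_positions(sequence),
    helix = {
      if (is.null(fingers)) stop("region 'helix' requires finger evidence")
      unlist(lapply(seq_len(nrow(fingers)), function(i)
        hit_positions(fingers$helix[i], offset = fingers$c2[i])))
    },
    c_terminal = {
      from <- if (!is.null(fingers) && nrow(fingers) > 0)
        max(fingers$t2) + 1L else 1L
      if (from > nchar(sequence)) integer()
      else hit_positions(substr(sequence, from, nchar(sequence)),
                         offset = from - 1L)
    },
    stop("unknown region: ", region)
  )
  list(found = length(positions) > 0, positions = as.integer(positions))
}

# Set label from finger count and array layout.
.assign_set <- function(n_fingers, n_arrays, config) {
  if (n_fingers == 0) return("unclassified")
  if (n_fingers >= config$set_b_min_fingers &&
      n_arrays >= config$set_b_min_arrays) return("B")
  if (n_arrays >= 1) return("A")
  "C"
}

#' Assign the structural set from grouped fingers
#'
#' @param fingers Finger table from [scan_fingers()].
#' @param arrays Grouping from [group_arrays()].
#' @param config A [classify_config()].
#' @return `"A"`, `"B"`, `"C"` or `"unclassified"` (zero fingers).
#' @export
assign_set <- function(fingers, arrays, config = classify_config()) {
  .assign_set(nrow(fingers), length(arrays$arrays), config)
}

# Subgroup/subset within set C from the per-finger H-gaps (gap between the
# two terminal coordinating residues). Returns list(subgroup, subset, flags).
.assign_subgroup_C <- function(h_gaps, n_fingers) {
  flags <- character()
  typical <- h_gaps[h_gaps %in% 3:5]
  if (length(typical) < length(h_gaps)) {
    flags <- c(flags, "atypical_h_gap")
    warning("atypical H-gap(s) outside 3-5; classifying by remaining gaps",
            call. = FALSE)
    if (length(typical) == 0) typical <- pmin(pmax(h_gaps, 3), 5)
  }
  u <- sort(unique(typical))
  if (identical(u, c(3L, 4L)) || identical(u, c(3, 4))) {
    return(list(subgroup = "C1", subset = "C1C2mixed", flags = flags))
  }
  if (length(u) > 1) {
    flags <- c(flags, "mixed_h_gap_majority")
    warning("mixed H-gaps ", paste(u, collapse = "/"),
            "; classifying by majority gap", call. = FALSE)
    tab <- table(typical)
    g <- as.integer(names(tab)[which.max(tab)])
  } else {
    g <- u[1]
  }
  if (g == 3) {
    list(subgroup = "C1", subset = paste0("C1-", n_fingers), flags = flags)
  } else if (g == 4) {
    list(subgroup = "C2", subset = "none", flags = flags)
  } else {
    list(subgroup = "C3", subset = "none", flags = flags)
  }
}

# Subgroup/subset within set A. A1 is recognized by the four-finger template
# (finger 1 canonical CX2CX12HX3H, finger 2 with a C-C gap of 4); its subset
# comes from the diagnostic motifs and the A1c row of the signature
# templates. Non-A1 members split into A2/A4 by arrangement components.
.assign_subgroup_A <- function(fingers, grouping, has_satall, has_pcycc,
                               config) {
  flags <- character()
  n <- nrow(fingers)
  is_a1 <- n == 4 &&
    fingers$signature[1] == "CX2CX12HX3H" &&
    fingers$gap1[2] == 4
  if (is_a1) {
    if (has_pcycc) return(list(subgroup = "A1", subset = "A1d", flags = flags))
    if (has_satall) return(list(subgroup = "A1", subset = "A1a", flags = flags))
    if (fingers$gap2[2] == 20 && fingers$signature[3] == "CX2CX13HX3C") {
      return(list(subgroup = "A1", subset = "A1c", flags = flags))
    }
    return(list(subgroup = "A1", subset = "A1b", flags = flags))
  }
  n_components <- length(grouping$components)
  if (n >= config$a2_min_fingers && n_components > 1) {
    list(subgroup = "A2", subset = "none", flags = flags)
  } else if (n_components == 1) {
    list(subgroup = "A4", subset = "none", flags = flags)
  } else {
    warning("ambiguous A2/A4 architecture; defaulting to A4", call. = FALSE)
    list(subgroup = "A4", subset = "none", flags = c(flags, "a2_a4_ambiguous"))
  }
}

#' Classify a single protein from its sequence
#'
#' Runs [scan_fingers()] and [group_arrays()], then applies the hierarchical
#' rules: set B for TF3A-like proteins (many fingers in several tandem
#' arrays), set A for proteins with a tandem array, set C for single or
#' dispersed fingers. Set C splits into C1/C2/C3 by the H-gap (3/4/5
#' residues between the two terminal coordinating residues); pure-C1
#' proteins get subset C1-k with k the finger count, and proteins mixing
#' H-gaps 3 and 4 are the C1C2mixed subset within C1. Set A splits into A1
#' (four-finger signature template, with subsets A1a-A1d decided by the
#' SATALL/PCYCC motifs and the A1c spacing row) and the heuristic A2/A4
#' split.
#'
#' @param id Protein identifier.
#' @param sequence Amino-acid string.
#' @param grammar A [finger_grammar()].
#' @param config A [classify_config()].
#' @return A one-row data.frame: `protein_id`, `n_fingers`, `set`,
#'   `subgroup`, `subset`, `n_arrays`, `n_isolated`, `tandem` (has a tandem
#'   array), `q_type`, `has_satall`, `has_pcycc`, `h_gaps`
#'   (comma-separated), `signatures` (comma-separated), `flags`.
#' @export
classify_protein <- function(id, sequence, grammar = finger_grammar(),
                             config = classify_config()) {
  fingers <- scan_fingers(sequence, grammar)
  grouping <- group_arrays(fingers, config$tandem_threshold)
  n <- nrow(fingers)
  set <- .assign_set(n, length(grouping$arrays), config)
  q_type <- if (n > 0)
    detect_motif(sequence, "QALGGH", fingers = fingers)$found else FALSE
  has_satall <- detect_motif(sequence, "SATALL", fingers = fingers)$found
  has_pcycc <- detect_motif(sequence, "PCYCC")$found
  subgroup <- "none"; subset <- "none"; flags <- character()
  if (set == "C") {
    r <- .assign_subgroup_C(fingers$gap3, n)
    subgroup <- r$subgroup; subset <- r$subset; flags <- r$flags
  } else if (set == "A") {
    r <- .assign_subgroup_A(fingers, grouping, has_satall, has_pcycc, config)
    subgroup <- r$subgroup; subset <- r$subset; flags <- r$flags
  } else if (set == "B") {
    subgroup <- "B"
  }
  data.frame(
    protein_id = id, n_fingers = n, set = set, subgroup = subgroup,
    subset = subset,
    n_arrays = length(grouping$arrays),
    n_isolated = length(grouping$isolated),
    tandem = length(grouping$arrays) >= 1,
    q_type = q_type, has_satall = has_satall, has_pcycc = has_pcycc,
    h_gaps = paste(fingers$gap3, collapse = ","),
    signatures = paste(fingers$signature, collapse = ","),
    flags = paste(flags, collapse = ";"),
    stringsAsFactors = FALSE
  )
}

#' Classify a whole proteome and summarize it
#'
#' Applies [classify_protein()] to every record and tallies the partition.
#' Per-protein warnings are propagated; a single atypical protein never
#' aborts the run.
#'
#' @param proteins A protein table (see [read_protein_fasta()]).
#' @param grammar A [finger_grammar()].
#' @param config A [classify_config()].
#' @return An object of class `proteome_classification`: a list with
#'   `records` (per-protein data.frame) and `summary` (list with `n`,
#'   `sets`, `subgroups`, `subsets`, `n_tandem_proteins`,
#'   `n_unclassified`).
#' @export
classify_proteome <- function(proteins, grammar = finger_grammar(),
                              config = classify_config()) {
  records <- do.call(rbind, lapply(seq_len(nrow(proteins)), function(i)
    classify_protein(proteins$id[i], proteins$sequence[i], grammar, config)))
  if (is.null(records)) {
    records <- classify_protein("x", "A", grammar, config)[0, ]
  }
  classified <- records[records$set != "unclassified", , drop = FALSE]
  count_of <- function(x) {
    x <- x[x != "none"]
    if (length(x) == 0) return(integer())
    tab <- table(x)
    stats::setNames(as.integer(tab), names(tab))
  }
  summary <- list(
    n = nrow(records),
    sets = count_of(classified$set),
    subgroups = count_of(classified$subgroup),
    subsets = count_of(classified$subset),
    n_tandem_proteins = sum(classified$tandem),
    n_unclassified = sum(records$set == "unclassified")
  )
  structure(list(records = records, summary = summary),
            class = "proteome_classification")
}

#' @export
print.proteome_classification <- function(x, ...) {
  s <- x$summary
  cat(sprintf("proteome classification: %d proteins (%d without fingers)\n",
              s$n, s$n_unclassified))
  fmt <- function(v) paste(sprintf("%s=%d", names(v), v), collapse = ", ")
  cat("  sets:      ", fmt(s$sets), "\n")
  cat("  subgroups: ", fmt(s$subgroups), "\n")
  cat("  subsets:   ", fmt(s$subsets), "\n")
  cat("  proteins with a tandem array:", s$n_tandem_proteins, "\n")
  invisible(x)
}
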