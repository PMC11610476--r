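# Independent brute-force oracle for the finger scanner, plus small
# fixture builders shared across test files.

# Enumerate every grammar-compatible substring of `sequence`: for each
# spacing triple (a, b, c) allowed by the grammar, slide the fixed-shape
# window over the sequence and keep the windows whose four coordinating
# positions carry the required residues. Independent of the package's
# incremental scanner.
enumerate_finger_windows <- function(sequence, grammar = finger_grammar()) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  is_c <- chars == "C"
  is_t <- chars %in% grammar$terminals
  is_h <- chars == "H"
  hits <- list()
  for (a in grammar$pair1_gap) {
    for (b in grammar$inner_gap) {
      for (cc in grammar$pair2_gap) {
        L <- a + b + cc + 4L
        if (L > n) next
        i <- seq_len(n - L + 1L)
        c2 <- i + a + 1L; t1 <- c2 + b + 1L; t2 <- i + L - 1L
        ok <- is_c[i] & is_c[c2] & is_t[t1] & is_t[t2]
        if (grammar$require_h) ok <- ok & (is_h[t1] | is_h[t2])
        for (w in which(ok)) {
          hits[[length(hits) + 1L]] <- data.frame(
            c1 = i[w], c2 = c2[w], t1 = t1[w], t2 = t2[w],
            gap1 = a, gap2 = b, gap3 = cc,
            canonical = is_h[t1[w]] && is_h[t2[w]])
        }
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(c1 = integer(), c2 = integer(), t1 = integer(),
                      t2 = integer(), gap1 = integer(), gap2 = integer(),
                      gap3 = integer(), canonical = logical()))
  }
  do.call(rbind, hits)
}

# Greedy leftmost / canonical-preferred / shortest selection over the full
# enumeration; mirrors the published tie-break policy, not the scanner's
# code path.
oracle_scan <- function(sequence, grammar = finger_grammar()) {
  hits <- enumerate_finger_windows(sequence, grammar)
  picked <- hits[0, ]
  cursor <- 1L
  repeat {
    avail <- hits[hits$c1 >= cursor, , drop = FALSE]
    if (nrow(avail) == 0) break
    cand <- avail[avail$c1 == min(avail$c1), , drop = FALSE]
    cand <- cand[order(!cand$canonical, cand$t2, cand$gap1, cand$gap2), ,
                 drop = FALSE]
    picked <- rbind(picked, cand[1, ])
    cursor <- cand$t2[1] + 1L
  }
  rownames(picked) <- NULL
  picked
}

# Random test sequence with C and H enriched so finger-like windows occur.
random_test_sequence <- function(len) {
  alpha <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
             "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  probs <- rep(0.7 / 18, 20)
  probs[alpha == "C"] <- 0.15
  probs[alpha == "H"] <- 0.15
  paste(sample(alpha, len, replace = TRUE, prob = probs), collapse = "")
}

# A canonical finger string with given flanking/linker filler.
canonical_finger <- function(h_gap = 3) {
  paste0("C", "AA", "C", strrep("A", 12), "H", strrep("A", h_gap), "H")
}

# Toy GFF3 writer for gene-model fixtures: `genes` is a list of lists with
# chromosome, id, start, end, strand, exons (matrix), optionally several
# mRNAs via exon_sets (list of matrices).
write_toy_gff3 <- function(genes, path) {
  lines <- "##gff-version 3"
  for (g in genes) {
    lines <- c(lines, sprintf("%s\ttoy\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                              g$chromosome, g$start, g$end, g$strand, g$id))
    exon_sets <- if (!is.null(g$exon_sets)) g$exon_sets else list(g$exons)
    for (k in seq_along(exon_sets)) {
      tid <- sprintf("%s.t%d", g$id, k)
      pid <- if (!is.null(g$protein_id))
        sprintf(";protein_id=%s", g$protein_id) else ""
      lines <- c(lines,
                 sprintf("%s\ttoy\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s%s",
                         g$chromosome, g$start, g$end, g$strand, tid, g$id,
                         pid))
      ex <- exon_sets[[k]]
      for (e in seq_len(nrow(ex))) {
        lines <- c(lines,
                   sprintf("%s\ttoy\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
                           g$chromosome, ex[e, 1], ex[e, 2], g$strand,
                           tid, e, tid))
      }
    }
  }
  writeLines(lines, path)
  path
}

# Planted label of a classification record, for round-trip comparison with
# generator truth labels.
recovered_label <- function(records) {
  ifelse(records$subset != "none", records$subset,
         ifelse(records$subgroup != "none", records$subgroup, records$set))
}
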