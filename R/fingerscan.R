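# C2H2 zinc-finger detection: a spacing grammar over the coordinating
# residues (two cysteines plus two terminal His/Cys), left-to-right
# non-overlapping scanning, and grouping of fingers into tandem arrays by
# linker length.

#' Construct a finger-detection grammar
#'
#' A finger is a window `C X(a) C X(b) T1 X(c) T2` where `a` is the gap
#' between the two cysteines, `b` the gap between the second cysteine and
#' the first terminal coordinating residue, `c` the gap between the two
#' terminal residues, and `T1`/`T2` are drawn from `terminals`. The default
#' ranges (1-4, 12-20, 3-7, terminals H/C with at least one H) form the
#' union of the canonical plant consensus Cys-X2-4-Cys-X12-His-X3-5-His and
#' the degenerate A1-subset signatures (e.g. CX4CX20HX4H, CX1CX12HX3C,
#' CX1CX12HX7H). A finger with both terminals H is called canonical.
#'
#' @param pair1_gap Allowed residue counts between the two cysteines.
#' @param inner_gap Allowed residue counts between the second cysteine and
#'   the first terminal residue.
#' @param pair2_gap Allowed residue counts between the two terminal residues
#'   (the "H-gap" that partitions set C into C1/C2/C3).
#' @param terminals Allowed terminal coordinating residues.
#' @param require_h If `TRUE` (default) at least one of the two terminal
#'   residues must be histidine.
#' @return An object of class `finger_grammar`.
#' @export
#' @examples
#' g <- finger_grammar()
#' scan_fingers(paste0("M", "C", "AA", "C", strrep("A", 12), "H", "AAA", "H"), g)
finger_grammar <- function(pair1_gap = 1:4, inner_gap = 12:20,
                           pair2_gap = 3:7, terminals = c("H", "C"),
                           require_h = TRUE) {
  stopifnot(length(pair1_gap) > 0, length(inner_gap) > 0,
            length(pair2_gap) > 0,
            all(pair1_gap >= 1), all(inner_gap >= 1), all(pair2_gap >= 1))
  structure(list(pair1_gap = as.integer(sort(unique(pair1_gap))),
                 inner_gap = as.integer(sort(unique(inner_gap))),
                 pair2_gap = as.integer(sort(unique(pair2_gap))),
                 terminals = unique(toupper(terminals)),
                 require_h = isTRUE(require_h)),
            class = "finger_grammar")
}

#' @export
print.finger_grammar <- function(x, ...) {
  rng <- function(v) if (length(v) == 1) v else paste0(min(v), "-", max(v))
  cat(sprintf("finger grammar: CX%sCX%s[%s]X%s[%s]%s\n",
              rng(x$pair1_gap), rng(x$inner_gap),
              paste(x$terminals, collapse = ""),
              rng(x$pair2_gap), paste(x$terminals, collapse = ""),
              if (x$require_h) " (>=1 H)" else ""))
  invisible(x)
}

#' Format a finger's spacing signature
#'
#' @param gaps Integer vector (a, b, c): gaps C-C, C-T1, T1-T2.
#' @param terminals Character vector of the two terminal residue letters.
#' @return A signature string such as `"CX2CX12HX3H"`.
#' @export
#' @examples
#' finger_signature(c(2, 12, 3), c("H", "H"))
finger_signature <- function(gaps, terminals) {
  stopifnot(length(gaps) == 3, length(terminals) == 2)
  sprintf("CX%dCX%d%sX%d%s", gaps[1], gaps[2], terminals[1],
          gaps[3], terminals[2])
}

#' Parse a spacing signature string
#'
#' Inverse of [finger_signature()].
#'
#' @param signature A string like `"CX2CX12HX3H"`.
#' @return A list with `gaps` (integer 3-vector) and `terminals`
#'   (character 2-vector).
#' @export
parse_signature <- function(signature) {
  m <- regmatches(signature,
                  regexec("^CX(\\d+)CX(\\d+)([A-Z])X(\\d+)([A-Z])$", signature))[[1]]
  if (length(m) != 6) stop("malformed finger signature: ", signature)
  list(gaps = as.integer(m[c(2, 3, 5)]), terminals = m[c(4, 6)])
}

# All grammar matches with c1 at position `i`, as a list of rows.
.matches_at <- function(chars, i, grammar) {
  n <- length(chars)
  out <- list()
  if (chars[i] != "C") return(out)
  for (a in grammar$pair1_gap) {
    c2 <- i + a + 1L
    if (c2 > n || chars[c2] != "C") next
    for (b in grammar$inner_gap) {
      t1 <- c2 + b + 1L
      if (t1 > n || !(chars[t1] %in% grammar$terminals)) next
      for (cc in grammar$pair2_gap) {
        t2 <- t1 + cc + 1L
        if (t2 > n || !(chars[t2] %in% grammar$terminals)) next
        if (grammar$require_h && chars[t1] != "H" && chars[t2] != "H") next
        out[[length(out) + 1L]] <- list(c1 = i, c2 = c2, t1 = t1, t2 = t2,
                                        gap1 = a, gap2 = b, gap3 = cc,
                                        t1_res = chars[t1], t2_res = chars[t2])
      }
    }
  }
  out
}

.finger_row <- function(chars, m) {
  canonical <- m$t1_res == "H" && m$t2_res == "H"
  data.frame(start = m$c1, end = m$t2, c1 = m$c1, c2 = m$c2,
             t1 = m$t1, t2 = m$t2,
             gap1 = m$gap1, gap2 = m$gap2, gap3 = m$gap3,
             t1_res = m$t1_res, t2_res = m$t2_res,
             helix = paste(chars[(m$c2 + 1L):(m$t1 - 1L)], collapse = ""),
             canonical = canonical,
             signature = finger_signature(c(m$gap1, m$gap2, m$gap3),
                                          c(m$t1_res, m$t2_res)),
             stringsAsFactors = FALSE)
}

.empty_fingers <- function() {
  data.frame(start = integer(), end = integer(), c1 = integer(),
             c2 = integer(), t1 = integer(), t2 = integer(),
             gap1 = integer(), gap2 = integer(), gap3 = integer(),
             t1_res = character(), t2_res = character(),
             helix = character(), canonical = logical(),
             signature = character(), stringsAsFactors = FALSE)
}

#' Scan a protein sequence for zinc fingers
#'
#' Deterministic left-to-right scan producing non-overlapping fingers. At
#' each scan position the leftmost grammar match wins; when several parses
#' share the same start, the canonical (H/H-terminated) parse is preferred,
#' then the shortest (smallest end), then the smallest C-C and inner gaps.
#' Scanning resumes immediately after the accepted finger's last
#' coordinating residue.
#'
#' @param sequence A single amino-acid string (uppercase).
#' @param grammar A [finger_grammar()].
#' @return A data.frame with one row per finger in sequence order: positions
#'   `start`, `end`, `c1`, `c2`, `t1`, `t2` (1-based), gaps `gap1`..`gap3`,
#'   terminal residues, the inter-cysteine/terminal `helix` subsequence,
#'   `canonical`, and `signature`.
#' @export
scan_fingers <- function(sequence, grammar = finger_grammar()) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  chars <- strsplit(toupper(sequence), "")[[1]]
  n <- length(chars)
  c_pos <- which(chars == "C")
  rows <- list()
  cursor <- 1L
  for (i in c_pos) {
    if (i < cursor) next
    ms <- .matches_at(chars, i, grammar)
    if (length(ms) == 0) next
    pref <- order(!vapply(ms, function(m) m$t1_res == "H" && m$t2_res == "H",
                          logical(1)),
                  vapply(ms, `[[`, integer(1), "t2"),
                  vapply(ms, `[[`, integer(1), "gap1"),
                  vapply(ms, `[[`, integer(1), "gap2"))
    best <- ms[[pref[1]]]
    rows[[length(rows) + 1L]] <- .finger_row(chars, best)
    cursor <- best$t2 + 1L
  }
  if (length(rows) == 0) return(.empty_fingers())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Scan every protein of a protein table
#'
#' @param proteins A protein table (see [read_protein_fasta()]).
#' @param grammar A [finger_grammar()].
#' @return A data.frame of fingers with a leading `protein_id` column.
#' @export
scan_proteome <- function(proteins, grammar = finger_grammar()) {
  per <- lapply(seq_len(nrow(proteins)), function(i) {
    f <- scan_fingers(proteins$sequence[i], grammar)
    if (nrow(f)) cbind(protein_id = proteins$id[i], f,
                       stringsAsFactors = FALSE) else NULL
  })
  per <- per[!vapply(per, is.null, logical(1))]
  if (length(per) == 0) {
    return(cbind(protein_id = character(), .empty_fingers()))
  }
  out <- do.call(rbind, per)
  rownames(out) <- NULL
  out
}

#' Group ordered fingers into tandem arrays
#'
#' The linker between two consecutive fingers is the residue count strictly
#' between the last coordinating residue of the left finger and the first
#' cysteine of the right finger. Consecutive fingers with linker less than
#' or equal to `tandem_threshold` are merged transitively into one tandem
#' array; components of size one are reported as isolated fingers.
#'
#' @param fingers A finger table from [scan_fingers()], in sequence order.
#' @param tandem_threshold Maximum linker length (residues) for a tandem
#'   arrangement; the default 10 reflects the published short-linker rule
#'   (1-10 residues tandem, more than 10 dispersed).
#' @return A list: `components` (list of integer finger-index vectors in
#'   order), `arrays` (the components with two or more members), `isolated`
#'   (integer vector of lone finger indices), `linkers` (numeric vector of
#'   the n-1 inter-finger linker lengths).
#' @export
#' @examples
#' f <- scan_fingers(paste0(
#'   strrep("A", 5), "C", "AA", "C", strrep("A", 12), "H", "AAA", "H",
#'   strrep("A", 5), "C", "AA", "C", strrep("A", 12), "H", "AAA", "H"))
#' group_arrays(f)
group_arrays <- function(fingers, tandem_threshold = 10) {
  n <- nrow(fingers)
  if (n == 0) {
    return(list(components = list(), arrays = list(), isolated = integer(),
                linkers = numeric()))
  }
  if (is.unsorted(fingers$start)) stop("fingers must be in sequence order")
  if (n > 1 && any(fingers$start[-1] <= fingers$end[-n])) {
    stop("overlapping fingers")
  }
  linkers <- if (n > 1) fingers$start[-1] - fingers$end[-n] - 1 else numeric()
  breaks <- which(linkers > tandem_threshold)
  bounds <- c(0, breaks, n)
  components <- lapply(seq_len(length(bounds) - 1), function(i)
    seq.int(bounds[i] + 1L, bounds[i + 1L]))
  sizes <- lengths(components)
  list(components = components,
       arrays = components[sizes >= 2],
       isolated = as.integer(unlist(components[sizes == 1])),
       linkers = linkers)
}
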