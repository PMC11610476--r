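# ExPASy-style physicochemical profiling: molecular weight, theoretical pI,
# instability index, GRAVY, amino-acid and atomic composition.

# Residue vector with X dropped (warning) and any other letter rejected.
.clean_residues <- function(sequence, what) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  if (length(chars) == 0) stop("empty sequence")
  bad <- setdiff(unique(chars), c(AA_STANDARD, "X"))
  if (length(bad)) {
    stop("non-standard residue(s) in sequence: ", paste(bad, collapse = ", "))
  }
  if (any(chars == "X")) {
    warning("X residues excluded from ", what, call. = FALSE)
    chars <- chars[chars != "X"]
    if (length(chars) == 0) stop("sequence contains only X residues")
  }
  chars
}

#' Molecular weight of a protein (average masses)
#'
#' Sum of average residue masses plus one water, using the ExPASy average
#' amino-acid mass table. `X` residues are excluded with a warning.
#'
#' @param sequence Amino-acid string.
#' @return Weight in daltons.
#' @export
#' @examples
#' molecular_weight("G")  # 75.07
molecular_weight <- function(sequence) {
  chars <- .clean_residues(sequence, "molecular weight")
  sum(AA_MASS[chars] - WATER_MASS) + WATER_MASS
}

# Net charge at a given pH under the Bjellqvist/ExPASy two-group model.
.net_charge <- function(counts, nterm_res, cterm_res, ph) {
  pk_n <- PK_NTERM_BY_RESIDUE[nterm_res]
  if (is.na(pk_n)) pk_n <- PK_POSITIVE[["Nterm"]]
  pk_c <- PK_CTERM_BY_RESIDUE[cterm_res]
  if (is.na(pk_c)) pk_c <- PK_NEGATIVE[["Cterm"]]
  pos <- 1 / (1 + 10^(ph - pk_n))
  for (res in c("K", "R", "H")) {
    pos <- pos + counts[res] / (1 + 10^(ph - PK_POSITIVE[[res]]))
  }
  neg <- 1 / (1 + 10^(pk_c - ph))
  for (res in c("D", "E", "C", "Y")) {
    neg <- neg + counts[res] / (1 + 10^(PK_NEGATIVE[[res]] - ph))
  }
  unname(pos - neg)
}

#' Theoretical isoelectric point
#'
#' pH at which the net charge of the protein crosses zero under a
#' Henderson-Hasselbalch model over D, E, C, Y, H, K, R and the two termini,
#' with the Bjellqvist/ExPASy pKa set. Solved by bisection on [0, 14] to
#' |delta pH| < 0.005.
#'
#' @param sequence Amino-acid string.
#' @param tol Bisection half-width at convergence.
#' @return pI in pH units (full precision; display convention is 2
#'   decimals).
#' @export
isoelectric_point <- function(sequence, tol = 0.005) {
  chars <- .clean_residues(sequence, "pI")
  counts <- vapply(AA_STANDARD, function(a) sum(chars == a), numeric(1))
  lo <- 0; hi <- 14
  # net charge is strictly decreasing in pH: positive at 0, negative at 14
  while ((hi - lo) / 2 > tol) {
    mid <- (lo + hi) / 2
    if (.net_charge(counts, chars[1], chars[length(chars)], mid) > 0) {
      lo <- mid
    } else {
      hi <- mid
    }
  }
  (lo + hi) / 2
}

#' Instability index (Guruprasad dipeptide-weight method)
#'
#' `(10 / L) * sum(DIWV)` over the L - 1 consecutive residue pairs, with the
#' published dipeptide instability weight values. Values above 40
#' conventionally mark a protein as unstable.
#'
#' @param sequence Amino-acid string of length >= 2 (after excluding X).
#' @return The dimensionless index.
#' @export
instability_index <- function(sequence) {
  chars <- .clean_residues(sequence, "instability index")
  L <- length(chars)
  if (L < 2) stop("instability index needs at least 2 residues")
  idx <- cbind(match(chars[-L], AA_STANDARD), match(chars[-1], AA_STANDARD))
  10 / L * sum(DIWV[idx])
}

#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over all residues; negative values mark
#' hydrophilic proteins.
#'
#' @param sequence Amino-acid string.
#' @return Mean hydropathy in [-4.5, 4.5].
#' @export
#' @examples
#' gravy("I")   # 4.5
#' gravy("IR")  # 0
gravy <- function(sequence) {
  chars <- .clean_residues(sequence, "GRAVY")
  mean(KD_HYDROPATHY[chars])
}

#' Amino-acid composition
#'
#' @param sequence Amino-acid string.
#' @return Named integer vector of counts over the 20 standard residues
#'   (X excluded with a warning).
#' @export
aa_composition <- function(sequence) {
  chars <- .clean_residues(sequence, "composition")
  vapply(AA_STANDARD, function(a) sum(chars == a), integer(1))
}

#' Atomic composition (C, H, N, O, S)
#'
#' Element counts of the polypeptide: residue formulas plus one water.
#'
#' @param sequence Amino-acid string.
#' @return Named integer vector over C, H, N, O, S.
#' @export
atomic_composition <- function(sequence) {
  counts <- aa_composition(sequence)
  atoms <- as.integer(counts %*% AA_ATOMS)
  names(atoms) <- colnames(AA_ATOMS)
  atoms["H"] <- atoms["H"] + 2L
  atoms["O"] <- atoms["O"] + 1L
  atoms
}

#' Physicochemical profile table for a proteome
#'
#' One row per protein: length, molecular weight, theoretical pI,
#' instability index and GRAVY. Per-protein errors are collected (the row
#' carries NA and the message) rather than aborting the table.
#'
#' @param proteins A protein table (see [read_protein_fasta()]).
#' @return A data.frame: `protein_id`, `length`, `mw`, `pi`, `instability`,
#'   `gravy`, `error`.
#' @export
profile_table <- function(proteins) {
  if (nrow(proteins) == 0) {
    return(data.frame(protein_id = character(), length = integer(),
                      mw = numeric(), pi = numeric(), instability = numeric(),
                      gravy = numeric(), error = character(),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_len(nrow(proteins)), function(i) {
    s <- proteins$sequence[i]
    out <- data.frame(protein_id = proteins$id[i],
                      length = NA_integer_, mw = NA_real_, pi = NA_real_,
                      instability = NA_real_, gravy = NA_real_,
                      error = "", stringsAsFactors = FALSE)
    tryCatch({
      out$length <- nchar(s)
      out$mw <- molecular_weight(s)
      out$pi <- isoelectric_point(s)
      out$instability <- instability_index(s)
      out$gravy <- gravy(s)
    }, error = function(e) out$error <<- conditionMessage(e))
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
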