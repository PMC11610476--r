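# Expression processing: FPKM filtering, log2 transform, profile-group
# clustering, and qPCR 2^-ddCt fold changes.

#' Filter a matrix to expressed genes
#'
#' Retains genes (rows) whose maximum FPKM across conditions is strictly
#' greater than `threshold` ("expressed" means FPKM larger than 1 in at
#' least one condition).
#'
#' @param m Numeric matrix, genes x conditions, non-negative.
#' @param threshold FPKM threshold (default 1).
#' @return The filtered matrix.
#' @export
filter_expressed <- function(m, threshold = 1) {
  stopifnot(is.matrix(m))
  if (any(m < 0)) stop("negative FPKM values")
  m[apply(m, 1, max) > threshold, , drop = FALSE]
}

#' log2(x + 1) transform
#'
#' Pseudo-count of 1 keeps zeros at zero and the transform strictly
#' monotone.
#'
#' @param m Non-negative numeric matrix (or vector).
#' @return Transformed values.
#' @export
log2_transform <- function(m) {
  if (any(m < 0)) stop("negative values cannot be log2-transformed")
  log2(m + 1)
}

# Row z-score with a guard for constant rows (returned as all-zero).
.zscore_rows <- function(m) {
  mu <- rowMeans(m)
  sd <- apply(m, 1, stats::sd)
  z <- (m - mu) / ifelse(sd > 0, sd, 1)
  z[sd == 0, ] <- 0
  list(z = z, constant = sd == 0)
}

#' Cluster expression profiles into k groups
#'
#' Rows are z-scored per gene, pairwise correlation distance (1 - Pearson r)
#' is computed, and average-linkage hierarchical clustering is cut into `k`
#' groups. Groups are relabelled 1..k by the peak position of their mean
#' z-profile (ties by peak height, then by first member) so labels are
#' stable under row permutation. Constant (zero-variance) rows cannot enter
#' the correlation distance; they are assigned afterwards to the nearest
#' centroid (Euclidean on z-profiles) with a warning.
#'
#' @param m Numeric matrix (typically log2-transformed FPKM), genes x
#'   conditions, with rownames.
#' @param k Number of profile groups (default 7).
#' @return A list of class `profile_grouping`: `groups` (named integer
#'   vector gene -> group), `k`, `method` (record of distance/linkage),
#'   `centroids` (k x conditions matrix of mean z-profiles).
#' @export
cluster_profiles <- function(m, k = 7) {
  stopifnot(is.matrix(m), nrow(m) >= k, k >= 1)
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  zs <- .zscore_rows(m)
  z <- zs$z
  usable <- which(!zs$constant)
  if (length(usable) < k) stop("fewer than k non-constant rows")
  if (k == 1) {
    cl <- stats::setNames(rep(1L, nrow(m)), rownames(m))
  } else {
    d <- stats::as.dist(1 - stats::cor(t(z[usable, , drop = FALSE])))
    hc <- stats::hclust(d, method = "average")
    cut <- stats::cutree(hc, k = k)
    cl <- stats::setNames(rep(NA_integer_, nrow(m)), rownames(m))
    cl[usable] <- cut
  }
  centroids <- t(vapply(seq_len(k), function(g) {
    idx <- which(cl == g)
    colMeans(z[idx, , drop = FALSE])
  }, numeric(ncol(m))))
  if (any(zs$constant)) {
    warning("constant row(s) assigned by nearest centroid: ",
            paste(rownames(m)[zs$constant], collapse = ", "), call. = FALSE)
    for (i in which(zs$constant)) {
      dist2 <- rowSums((centroids - matrix(z[i, ], nrow = k, ncol = ncol(m),
                                           byrow = TRUE))^2)
      cl[i] <- which.min(dist2)
    }
  }
  # relabel deterministically by centroid peak position
  peak <- apply(centroids, 1, which.max)
  height <- vapply(seq_len(k), function(g) centroids[g, peak[g]], numeric(1))
  first <- vapply(seq_len(k), function(g) min(which(cl == g)), numeric(1))
  new_order <- order(peak, -height, first)
  relabel <- match(seq_len(k), new_order)
  groups <- stats::setNames(relabel[cl], names(cl))
  structure(list(groups = groups, k = k,
                 method = list(distance = "1 - Pearson correlation",
                               linkage = "average", zscore = TRUE),
                 centroids = centroids[new_order, , drop = FALSE]),
            class = "profile_grouping")
}

#' @export
print.profile_grouping <- function(x, ...) {
  cat(sprintf("profile grouping: %d genes in %d groups (%s, %s linkage)\n",
              length(x$groups), x$k, x$method$distance, x$method$linkage))
  print(table(x$groups))
  invisible(x)
}

#' qPCR relative expression by the 2^-ddCt method
#'
#' `dCt = Ct_target - Ct_reference` per sample; `ddCt = dCt_treated -
#' dCt_control`; fold change is `2^-ddCt`.
#'
#' @param ct_target_treated,ct_ref_treated Target and reference-gene Ct of
#'   the treated sample.
#' @param ct_target_control,ct_ref_control Target and reference-gene Ct of
#'   the control (calibrator) sample.
#' @return Fold change (vectorized over replicates).
#' @export
#' @examples
#' ddct_fold_change(25, 20, 26, 20)  # dCt 5 vs 6 -> 2
ddct_fold_change <- function(ct_target_treated, ct_ref_treated,
                             ct_target_control, ct_ref_control) {
  args <- list(ct_target_treated, ct_ref_treated,
               ct_target_control, ct_ref_control)
  if (any(vapply(args, function(a) any(is.na(a)) || length(a) == 0,
                 logical(1)))) {
    stop("missing Ct value(s)")
  }
  if (any(unlist(args) <= 0)) stop("Ct values must be positive")
  d_treated <- ct_target_treated - ct_ref_treated
  d_control <- ct_target_control - ct_ref_control
  2^(-(d_treated - d_control))
}

#' Summarize replicate-level qPCR measurements
#'
#' Computes the per-replicate fold change against the mean dCt of the
#' calibrator group, then averages across biological replicates (error bars
#' = sd across replicates).
#'
#' @param qpcr Long-format data.frame with columns `sample` (treatment
#'   label), `gene`, `replicate`, `ct_target`, `ct_ref`.
#' @param calibrator Sample label of the calibrator (control) group.
#' @return A data.frame `gene`, `sample`, `fold_change`, `sd`, `n`.
#' @export
ddct_table <- function(qpcr, calibrator) {
  need <- c("sample", "gene", "replicate", "ct_target", "ct_ref")
  stopifnot(all(need %in% names(qpcr)))
  if (!calibrator %in% qpcr$sample) stop("calibrator group not found: ",
                                         calibrator)
  qpcr$dct <- qpcr$ct_target - qpcr$ct_ref
  rows <- list()
  for (gene in unique(qpcr$gene)) {
    gq <- qpcr[qpcr$gene == gene, , drop = FALSE]
    cal <- gq$dct[gq$sample == calibrator]
    if (length(cal) == 0) stop("no calibrator measurements for gene ", gene)
    cal_dct <- mean(cal)
    for (s in unique(gq$sample)) {
      fc <- 2^(-(gq$dct[gq$sample == s] - cal_dct))
      rows[[length(rows) + 1]] <- data.frame(
        gene = gene, sample = s, fold_change = mean(fc),
        sd = if (length(fc) > 1) stats::sd(fc) else NA_real_,
        n = length(fc), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
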