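# Water-stress enzyme-panel statistics: replicate summaries, percent change
# vs control, ANOVA + Tukey HSD compact letter display, and Pearson
# correlation of expression with physiology.

#' Summarize an enzyme panel (mean and sd per treatment and analyte)
#'
#' @param panel Long-format data.frame with columns `treatment`,
#'   `replicate`, `analyte`, `value` (and optionally `unit`).
#' @return A data.frame `analyte`, `treatment`, `mean`, `sd`, `n` (sample sd
#'   with n - 1 denominator; `sd` is NA with a single replicate).
#' @export
summarize_panel <- function(panel) {
  stopifnot(all(c("treatment", "analyte", "value") %in% names(panel)))
  rows <- list()
  for (an in unique(panel$analyte)) {
    for (trt in unique(panel$treatment[panel$analyte == an])) {
      v <- panel$value[panel$analyte == an & panel$treatment == trt]
      rows[[length(rows) + 1]] <- data.frame(
        analyte = an, treatment = trt, mean = mean(v),
        sd = if (length(v) > 1) stats::sd(v) else NA_real_,
        n = length(v), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Signed percent change of a treated mean vs a control mean
#'
#' `100 * (treated - control) / control`, the convention used for reporting
#' stress effects against the CK control (e.g. MDA rising from 59.94 to
#' 71.87 nmol/g is +19.90%).
#'
#' @param treated_mean,control_mean Group means; `control_mean` must be
#'   non-zero. Vectorized.
#' @param digits Decimals for display rounding (default 2; use `Inf` for
#'   the raw value).
#' @return Signed percent change.
#' @export
#' @examples
#' percent_change(71.87, 59.94)   # +19.90
#' percent_change(0.035, 0.175)   # -80.00
percent_change <- function(treated_mean, control_mean, digits = 2) {
  if (any(control_mean == 0)) stop("control mean is zero")
  pc <- 100 * (treated_mean - control_mean) / control_mean
  if (is.finite(digits)) round(pc, digits) else pc
}

# Compact letter display by insert-and-absorb over a logical "differs"
# matrix, letters assigned in descending mean order starting at "a".
.letters_from_diff <- function(differs, means) {
  trt <- names(means)
  ord <- order(-means)
  cols <- list(rep(TRUE, length(trt)))  # start with one letter containing all
  for (i in ord) {
    for (j in ord) {
      if (means[j] <= means[i]) next
      if (!differs[trt[i], trt[j]]) next
      # i and j must not share any letter column
      for (ci in seq_along(cols)) {
        if (cols[[ci]][i] && cols[[ci]][j]) {
          newcol <- cols[[ci]]
          newcol[j] <- FALSE
          cols[[ci]][i] <- FALSE
          cols[[length(cols) + 1]] <- newcol
        }
      }
      # absorb duplicated columns
      keep <- !duplicated(vapply(cols, paste, character(1), collapse = ""))
      cols <- cols[keep]
      absorbed <- vapply(seq_along(cols), function(a)
        any(vapply(seq_along(cols), function(b)
          b != a && all(cols[[b]][cols[[a]]]), logical(1))), logical(1))
      cols <- cols[!absorbed]
    }
  }
  # order letter columns by the best (highest-mean) member they contain
  best <- vapply(cols, function(col) min(match(which(col), ord)), numeric(1))
  cols <- cols[order(best)]
  lab <- vapply(seq_along(means), function(i)
    paste(letters[which(vapply(cols, `[`, logical(1), i))], collapse = ""),
    character(1))
  stats::setNames(lab, trt)
}

#' Significance letter groups across treatments (ANOVA + Tukey HSD)
#'
#' One-way ANOVA of `value ~ treatment` for one analyte, followed by Tukey
#' HSD pairwise comparisons at `alpha`; treatments sharing no letter differ
#' significantly. Letters are assigned in descending mean order starting at
#' "a".
#'
#' @param panel Long-format panel (see [summarize_panel()]).
#' @param analyte Analyte to test.
#' @param alpha Significance level (default 0.05).
#' @return A list: `letters` (named character vector treatment -> letter
#'   group), `means`, `anova_p`, `tukey` (the Tukey HSD table).
#' @export
significance_letters <- function(panel, analyte, alpha = 0.05) {
  d <- panel[panel$analyte == analyte, , drop = FALSE]
  if (nrow(d) == 0) stop("no measurements for analyte ", analyte)
  reps <- table(d$treatment)
  if (any(reps < 2)) stop("at least 2 replicates per treatment required")
  d$treatment <- factor(d$treatment)
  means <- tapply(d$value, d$treatment, mean)
  trt <- names(means)
  differs <- matrix(FALSE, length(trt), length(trt),
                    dimnames = list(trt, trt))
  if (all(tapply(d$value, d$treatment, stats::sd) == 0)) {
    warning("zero within-group variance; letters from distinct means",
            call. = FALSE)
    for (i in trt) for (j in trt) differs[i, j] <- means[i] != means[j]
    anova_p <- NA_real_
    tk <- NULL
  } else {
    fit <- stats::aov(value ~ treatment, data = d)
    anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$treatment
    pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
    for (r in seq_along(pairs)) {
      a <- pairs[[r]][1]; b <- pairs[[r]][2]
      if (tk[r, "p adj"] < alpha) {
        differs[a, b] <- TRUE
        differs[b, a] <- TRUE
      }
    }
  }
  list(letters = .letters_from_diff(differs, means), means = means,
       anova_p = anova_p, tukey = tk)
}

#' Pearson correlation of expression with physiological indices
#'
#' Computes Pearson r and the two-sided t-test p-value for every
#' (gene, analyte) pair and every (analyte, analyte) pair over matched
#' sample columns. With fewer than 3 paired observations the result row is
#' emitted with `p` absent and a warning.
#'
#' @param expr Numeric matrix genes x samples (original-scale FPKM).
#' @param phys Numeric matrix analytes x samples with the same column
#'   labels (replicate-level values or treatment means).
#' @param alpha Significance level for the `significant` flag.
#' @param adjust P-value adjustment method passed to [stats::p.adjust()]
#'   (default `"none"`, mirroring unadjusted 0.05-level flags; `"BH"` for
#'   Benjamini-Hochberg).
#' @return A data.frame `var_a`, `var_b`, `kind` (gene-analyte or
#'   analyte-analyte), `r`, `p`, `n`, `significant`.
#' @export
correlate_expression <- function(expr, phys, alpha = 0.05, adjust = "none") {
  stopifnot(is.matrix(expr), is.matrix(phys))
  common <- intersect(colnames(expr), colnames(phys))
  if (length(common) == 0) stop("no matched sample labels")
  expr <- expr[, common, drop = FALSE]
  phys <- phys[, common, drop = FALSE]
  n <- length(common)
  if (n < 3) warning("fewer than 3 paired observations; p-values absent",
                     call. = FALSE)
  one <- function(a, b, na, nb, kind) {
    if (n < 3 || stats::sd(a) == 0 || stats::sd(b) == 0) {
      r <- if (n >= 2 && stats::sd(a) > 0 && stats::sd(b) > 0)
        stats::cor(a, b) else NA_real_
      return(data.frame(var_a = na, var_b = nb, kind = kind, r = r,
                        p = NA_real_, n = n, stringsAsFactors = FALSE))
    }
    ct <- stats::cor.test(a, b, method = "pearson")
    data.frame(var_a = na, var_b = nb, kind = kind,
               r = unname(ct$estimate), p = ct$p.value, n = n,
               stringsAsFactors = FALSE)
  }
  rows <- list()
  for (g in rownames(expr)) {
    for (an in rownames(phys)) {
      rows[[length(rows) + 1]] <- one(expr[g, ], phys[an, ], g, an,
                                      "gene-analyte")
    }
  }
  ans <- rownames(phys)
  if (length(ans) > 1) {
    for (i in seq_len(length(ans) - 1)) {
      for (j in seq.int(i + 1, length(ans))) {
        rows[[length(rows) + 1]] <- one(phys[ans[i], ], phys[ans[j], ],
                                        ans[i], ans[j], "analyte-analyte")
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p <- stats::p.adjust(out$p, method = adjust)
  out$significant <- !is.na(out$p) & out$p < alpha
  rownames(out) <- NULL
  out
}
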