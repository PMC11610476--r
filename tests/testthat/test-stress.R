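test_that("panel summaries use sample sd and flag single replicates", {
  panel <- data.frame(treatment = c("CK", "CK", "CK", "LS"),
                      replicate = c(1, 2, 3, 1),
                      analyte = "SOD",
                      value = c(1, 2, 3, 9))
  s <- summarize_panel(panel)
  ck <- s[s$treatment == "CK", ]
  expect_equal(ck$mean, 2)
  expect_equal(ck$sd, 1)
  expect_true(is.na(s$sd[s$treatment == "LS"]))

  const <- data.frame(treatment = "CK", replicate = 1:3, analyte = "POD",
                      value = rep(7, 3))
  expect_equal(summarize_panel(const)$sd, 0)
})

test_that("percent change reproduces the published stress effects", {
  # MDA rose by 19.90/16.87/14.96% and proline fell by 74.29/80.00/74.86%
  # in LS/MS/SS vs the CK control
  er <- enzyme_reference()
  m <- function(analyte, trt) er$mean[er$analyte == analyte &
                                      er$treatment == trt]
  expect_equal(percent_change(m("MDA", "LS"), m("MDA", "CK")), 19.90)
  expect_equal(percent_change(m("MDA", "MS"), m("MDA", "CK")), 16.87)
  expect_equal(percent_change(m("MDA", "SS"), m("MDA", "CK")), 14.96)
  expect_equal(percent_change(m("proline", "LS"), m("proline", "CK")), -74.29)
  expect_equal(percent_change(m("proline", "MS"), m("proline", "CK")), -80.00)
  expect_equal(percent_change(m("proline", "SS"), m("proline", "CK")), -74.86)
  expect_equal(percent_change(5, 5), 0)
  expect_error(percent_change(1, 0), "zero")
})

test_that("significance letters separate and merge treatments correctly", {
  # identical replicate sets across treatments share one letter
  same <- do.call(rbind, lapply(c("CK", "LS", "MS", "SS"), function(t)
    data.frame(treatment = t, replicate = 1:3, analyte = "CAT",
               value = c(10, 11, 12))))
  sl <- significance_letters(same, "CAT")
  expect_true(all(sl$letters == "a"))

  # two treatments separated by 100 sds differ
  far <- data.frame(treatment = rep(c("CK", "SS"), each = 3),
                    replicate = rep(1:3, 2), analyte = "CAT",
                    value = c(10, 10.1, 9.9, 110, 110.1, 109.9))
  sl2 <- significance_letters(far, "CAT")
  expect_false(any(strsplit(sl2$letters[["CK"]], "")[[1]] %in%
                     strsplit(sl2$letters[["SS"]], "")[[1]]))
  # letters follow descending mean order starting at "a"
  expect_equal(sl2$letters[["SS"]], "a")

  # letter-group consistency: treatments sharing a letter are never
  # significantly different pairwise
  pan <- make_enzyme_panel(seed = 17)
  for (an in unique(pan$analyte)) {
    sl3 <- significance_letters(pan, an)
    trts <- names(sl3$letters)
    for (i in seq_along(trts)) for (j in seq_along(trts)) {
      if (i >= j) next
      shares <- any(strsplit(sl3$letters[[i]], "")[[1]] %in%
                      strsplit(sl3$letters[[j]], "")[[1]])
      row <- paste(sort(c(trts[i], trts[j]), decreasing = TRUE),
                   collapse = "-")
      p <- sl3$tukey[rownames(sl3$tukey) == row, "p adj"]
      if (length(p) == 0) {
        row <- paste(sort(c(trts[i], trts[j])), collapse = "-")
        p <- sl3$tukey[rownames(sl3$tukey) == row, "p adj"]
      }
      if (shares) expect_gte(p, 0.05) else expect_lt(p, 0.05)
    }
  }

  expect_error(significance_letters(same[same$replicate == 1, ], "CAT"),
               "2 replicates")
})

test_that("correlation results behave like Pearson r", {
  x <- matrix(c(1, 2, 3, 4, 5, 6), 1, dimnames = list("g1", paste0("s", 1:6)))
  y2 <- 2 * x; rownames(y2) <- "an"
  res <- correlate_expression(x, y2)
  expect_equal(res$r[1], 1)
  yneg <- -x; rownames(yneg) <- "an"
  expect_equal(correlate_expression(x, yneg)$r[1], -1)

  # affine rescaling of either variable leaves r unchanged
  set.seed(6)
  a <- matrix(rnorm(12), 1, dimnames = list("g", paste0("s", 1:12)))
  b <- matrix(rnorm(12), 1, dimnames = list("an", paste0("s", 1:12)))
  r1 <- correlate_expression(a, b)$r
  r2 <- correlate_expression(a * 3 + 7, b)$r
  expect_equal(r1, r2)

  # n < 3: row emitted, p absent, warning
  small <- matrix(c(1, 2), 1, dimnames = list("g", c("s1", "s2")))
  smallp <- matrix(c(3, 9), 1, dimnames = list("an", c("s1", "s2")))
  expect_warning(res2 <- correlate_expression(small, smallp), "fewer than 3")
  expect_true(is.na(res2$p))
  expect_equal(nrow(res2), 1)

  # analyte-analyte pairs included, symmetric definition
  phys <- rbind(a1 = c(1, 2, 3, 4), a2 = c(2, 4, 6, 8))
  colnames(phys) <- paste0("s", 1:4)
  expr <- matrix(c(4, 3, 2, 1), 1, dimnames = list("g", paste0("s", 1:4)))
  res3 <- correlate_expression(expr, phys)
  aa <- res3[res3$kind == "analyte-analyte", ]
  expect_equal(nrow(aa), 1)
  expect_equal(aa$r, 1)
})
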