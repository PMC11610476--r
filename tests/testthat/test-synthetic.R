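test_that("protein generation is deterministic and plants only the requested architecture", {
  arch <- architecture_presets()$A1a
  expect_identical(make_protein(arch, seed = 5), make_protein(arch, seed = 5))
  expect_false(identical(make_protein(arch, seed = 5),
                         make_protein(arch, seed = 6)))

  # background-only architecture yields no fingers
  bg <- finger_architecture("none", character(), flank = c(60, 0))
  expect_equal(nrow(scan_fingers(make_protein(bg, seed = 1))), 0)

  # the background alphabet never contains C or H outside planted features
  s <- make_protein(finger_architecture("t", "CX2CX12HX3H"), seed = 2)
  f <- scan_fingers(s)
  expect_equal(nrow(f), 1)
  stripped <- paste0(substr(s, 1, f$c1 - 1),
                     substr(s, f$t2 + 1, nchar(s)))
  expect_false(grepl("[CH]", stripped))

  # helix too short for QALGGH is an error
  expect_error(make_protein(finger_architecture("t", "CX2CX5HX3H",
                                                qalggh = TRUE),
                            seed = 1),
               "helix too short")
})

test_that("proteome generation round-trips through the classifier", {
  pp <- make_proteome(c(A1a = 3L, B = 1L, "C1-1" = 6L), seed = 31)
  expect_equal(nrow(pp$proteins), 10)
  cl <- classify_proteome(pp$proteins)
  expect_equal(cl$summary$sets, c(A = 3L, B = 1L, C = 6L))
  expect_equal(recovered_label(cl$records), pp$truth$label)

  # byte-identical determinism
  pp2 <- make_proteome(c(A1a = 3L, B = 1L, "C1-1" = 6L), seed = 31)
  expect_identical(pp$proteins, pp2$proteins)

  # empty composition -> empty proteome
  expect_equal(nrow(make_proteome(stats::setNames(integer(), character()),
                                  seed = 1)$proteins), 0)
})

test_that("TF3A architecture reproduces the two-array nine-finger layout", {
  b <- architecture_presets()$B
  f <- scan_fingers(make_protein(b, seed = 4))
  expect_equal(nrow(f), 9)
  g <- group_arrays(f)
  expect_equal(g$isolated, 1L)
  expect_equal(g$arrays, list(2:4, 5:9))
})

test_that("FPKM generator controls the expressed fraction and truth", {
  sim <- make_fpkm(n_genes = 77, n_below = 34, seed = 3)
  expect_equal(dim(sim$fpkm), c(77L, 4L))
  expect_equal(nrow(filter_expressed(sim$fpkm)), 43)
  expect_equal(sum(is.na(sim$truth$group)), 34)
  expect_true(all(sim$fpkm >= 0))

  # everything below threshold -> filter empties the matrix
  low <- make_fpkm(n_genes = 10, n_below = 10, k = 0, seed = 1)
  expect_equal(nrow(filter_expressed(low$fpkm)), 0)
})

test_that("enzyme panel generator honours the reference truth", {
  ref <- enzyme_reference()
  # sd 0 reproduces the means exactly
  ref0 <- ref; ref0$sd <- 0
  pan0 <- make_enzyme_panel(ref0, seed = 2)
  s0 <- summarize_panel(pan0)
  key <- paste(ref$analyte, ref$treatment)
  skey <- paste(s0$analyte, s0$treatment)
  expect_equal(s0$mean[match(key, skey)], ref$mean)
  expect_true(all(s0$sd == 0))

  refbad <- ref; refbad$sd[1] <- -1
  expect_error(make_enzyme_panel(refbad), "negative sd")

  # estimates fall within 3 sampling sds of the truth at n = 3
  pan <- make_enzyme_panel(seed = 23)
  s <- summarize_panel(pan)
  m <- match(paste(s$analyte, s$treatment), key)
  expect_true(all(abs(s$mean - ref$mean[m]) <= 3 * ref$sd[m] / sqrt(3)))
})
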