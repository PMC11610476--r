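presets <- architecture_presets()

classify_arch <- function(label, seed = 1) {
  classify_protein(label, make_protein(presets[[label]], seed = seed))
}

test_that("set assignment follows the tandem-array layout", {
  # single isolated finger -> C
  expect_equal(classify_arch("C1-1")$set, "C")
  # dispersed multi-finger -> C
  expect_equal(classify_arch("C1-4")$set, "C")
  # one tandem array of 4 -> A
  expect_equal(classify_arch("A1b")$set, "A")
  # nine fingers in two tandem arrays (TF3A) -> B
  b <- classify_arch("B")
  expect_equal(b$set, "B")
  expect_equal(b$n_fingers, 9L)
  expect_equal(b$n_arrays, 2L)
  expect_equal(b$n_isolated, 1L)
  # no fingers -> unclassified, never a set label
  expect_equal(classify_protein("bg", strrep("AGKLMNPQ", 10))$set,
               "unclassified")
})

test_that("set C subgroups follow the H-gap rule", {
  expect_equal(classify_arch("C2")[, c("subgroup", "subset")],
               data.frame(subgroup = "C2", subset = "none"),
               ignore_attr = TRUE)
  expect_equal(classify_arch("C3")$subgroup, "C3")
  mixed <- classify_arch("C1C2mixed")
  expect_equal(mixed$subgroup, "C1")
  expect_equal(mixed$subset, "C1C2mixed")
  for (k in 1:5) {
    r <- classify_arch(paste0("C1-", k))
    expect_equal(r$subgroup, "C1")
    expect_equal(r$subset, paste0("C1-", k))
    expect_equal(r$n_fingers, k)
  }
  # atypical H-gap: single finger with pair2 gap 6-7 classified by clamped
  # majority with a warning
  odd <- paste0("C", "AA", "C", strrep("A", 12), "H", strrep("A", 7), "H")
  expect_warning(r <- classify_protein("odd", odd), "atypical")
  expect_equal(r$subgroup, "C3")
})

test_that("A1 subsets are decided by template spacing and motifs", {
  for (subset in c("A1a", "A1b", "A1c", "A1d")) {
    r <- classify_arch(subset)
    expect_equal(r$subgroup, "A1")
    expect_equal(r$subset, subset)
  }
  expect_true(classify_arch("A1a")$has_satall)
  expect_true(classify_arch("A1d")$has_pcycc)
  expect_false(classify_arch("A1b")$has_satall)
  # A2: tandem pair plus a dispersed finger; A4: single tandem array
  expect_equal(classify_arch("A2")$subgroup, "A2")
  expect_equal(classify_arch("A4")$subgroup, "A4")
})

test_that("diagnostic motifs are searched in their canonical regions", {
  s <- paste0("C", "AA", "C", "QALGGH", strrep("A", 6), "H", "AAA", "H",
              strrep("G", 10))
  f <- scan_fingers(s)
  expect_true(detect_motif(s, "QALGGH", fingers = f)$found)
  # QALGGH outside any helix does not count for the helix region
  s2 <- paste0(canonical_finger(), "QALGGH")
  expect_false(detect_motif(s2, "QALGGH",
                            fingers = scan_fingers(s2))$found)
  expect_true(detect_motif(s2, "QALGGH", region = "anywhere")$found)

  s3 <- paste0(canonical_finger(), "GGG", "SATALLQKAAQMGS")
  expect_true(detect_motif(s3, "SATALL", fingers = scan_fingers(s3))$found)
  expect_false(detect_motif(canonical_finger(), "SATALL",
                            fingers = scan_fingers(canonical_finger()))$found)
  expect_true(detect_motif("AAPCYCCAA", "PCYCC")$found)
})

test_that("proteome classification partitions and counts correctly", {
  empty <- classify_proteome(as_protein_table(character(), character()))
  expect_equal(empty$summary$n, 0)
  expect_length(empty$summary$sets, 0)

  comp <- c(A1a = 3L, B = 1L, "C1-1" = 6L)
  pp <- make_proteome(comp, seed = 5)
  cl <- classify_proteome(pp$proteins)
  expect_equal(cl$summary$sets, c(A = 3L, B = 1L, C = 6L))
  expect_equal(cl$summary$n_tandem_proteins, 4L)
  # partition: every protein in exactly one set; counts sum to input size
  expect_equal(sum(cl$summary$sets), nrow(pp$proteins))
  expect_equal(recovered_label(cl$records), pp$truth$label)
})

test_that("classification is invariant to added non-finger sequence", {
  set.seed(11)
  for (label in c("A1a", "A2", "B", "C1-2", "C2")) {
    s <- make_protein(presets[[label]])
    r1 <- classify_protein("x", s)
    r2 <- classify_protein("x", paste0(strrep("K", 25), s, strrep("K", 25)))
    expect_equal(r1[, c("set", "subgroup", "subset", "n_fingers")],
                 r2[, c("set", "subgroup", "subset", "n_fingers")])
  }
})
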