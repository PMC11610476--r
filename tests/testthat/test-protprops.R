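test_that("molecular weight uses average masses and is additive", {
  expect_equal(molecular_weight("G"), 75.07, tolerance = 1e-3)
  # chain growth adds one residue mass (glycine 57.05)
  expect_equal(molecular_weight("GG") - molecular_weight("G"), 57.0513,
               tolerance = 1e-3)
  # mw(s1 + s2) = mw(s1) + mw(s2) - water
  s1 <- "MKWVTF"; s2 <- "GAVLIP"
  expect_equal(molecular_weight(paste0(s1, s2)),
               molecular_weight(s1) + molecular_weight(s2) - 18.0153,
               tolerance = 1e-6)
  expect_error(molecular_weight(""), "empty")
  # X excluded with a warning
  expect_warning(mx <- molecular_weight("GXG"), "X residues")
  expect_equal(mx, molecular_weight("GG"))
})

test_that("pI matches a closed-form two-group oracle and is monotone in K", {
  # poly-alanine ionizes only at the termini (pK 7.59 / 3.55): solve the
  # two-group charge equation directly as the oracle
  oracle <- stats::uniroot(function(ph)
    1 / (1 + 10^(ph - 7.59)) - 1 / (1 + 10^(3.55 - ph)),
    c(0, 14), tol = 1e-9)$root
  expect_equal(isoelectric_point("AAAAA"), oracle, tolerance = 0.01)

  # adding a basic residue never lowers the pI
  set.seed(3)
  for (i in 1:10) {
    s <- random_test_sequence(40)
    expect_gte(isoelectric_point(paste0(s, "K")) + 0.011,
               isoelectric_point(s))
  }

  # cross-checked reference values (ProtParam model)
  expect_equal(isoelectric_point("MKWVTFISLLLLFSSAYSRGV"), 9.9924,
               tolerance = 0.02)
  expect_equal(isoelectric_point("ACDEFGHIKLMNPQRSTVWY"), 6.7846,
               tolerance = 0.02)
})

test_that("instability index implements the dipeptide-weight sum", {
  # GG: single dipeptide with weight 13.34 -> 10/2 * 13.34
  expect_equal(instability_index("GG"), 10 / 2 * 13.34)
  # poly-A: every dipeptide weight 1 -> 10 * (L - 1) / L
  expect_equal(instability_index("AAAA"), 10 * 3 / 4)
  expect_error(instability_index("G"), "at least 2")
  # cross-checked reference values
  expect_equal(instability_index("MKWVTFISLLLLFSSAYSRGV"), 21.6143,
               tolerance = 1e-3)
  expect_equal(instability_index("ACDEFGHIKLMNPQRSTVWY"), 84.74,
               tolerance = 1e-3)
})

test_that("GRAVY is the mean hydropathy, bounded and permutation-invariant", {
  expect_equal(gravy("I"), 4.5)
  expect_equal(gravy("IR"), 0)
  set.seed(4)
  s <- random_test_sequence(60)
  perm <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
  expect_equal(gravy(s), gravy(perm))
  expect_gte(gravy(s), -4.5)
  expect_lte(gravy(s), 4.5)
})

test_that("composition counts match construction", {
  counts <- c(A = 3L, G = 2L, K = 1L, W = 1L)
  s <- paste(rep(names(counts), counts), collapse = "")
  comp <- aa_composition(s)
  expect_equal(comp[names(counts)], counts)
  expect_equal(sum(comp), nchar(s))
  atoms <- atomic_composition("G")  # glycine + water = C2H5NO2
  expect_equal(atoms, c(C = 2L, H = 5L, N = 1L, O = 2L, S = 0L))
})

test_that("profile_table is per-protein robust and complete", {
  expect_equal(nrow(profile_table(as_protein_table(character(),
                                                   character()))), 0)
  pp <- make_proteome(c(A1a = 2L, "C1-1" = 2L), seed = 9)
  tab <- profile_table(pp$proteins)
  expect_equal(tab$protein_id, pp$proteins$id)
  expect_equal(tab$length, nchar(pp$proteins$sequence))
  expect_true(all(tab$mw > 0))
  expect_true(all(tab$pi > 0 & tab$pi < 14))
  expect_true(all(tab$error == ""))
})
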