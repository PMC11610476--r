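test_that("scanner finds planted canonical and degenerate fingers", {
  expect_equal(nrow(scan_fingers("MAAAAAAAA")), 0)

  s <- paste0("M", "C", "AA", "C", strrep("A", 12), "H", "AAA", "H", "M")
  f <- scan_fingers(s)
  expect_equal(nrow(f), 1)
  expect_equal(f$signature, "CX2CX12HX3H")
  expect_true(f$canonical)
  expect_equal(f$start, 2L)
  expect_equal(f$end, 22L)

  # the wide degenerate window of the A1c/A1d second finger
  s2 <- paste0("C", "AAAA", "C", strrep("A", 20), "H", "AAAA", "H")
  f2 <- scan_fingers(s2)
  expect_equal(nrow(f2), 1)
  expect_equal(f2$signature, "CX4CX20HX4H")

  # degenerate H...C terminal pair
  s3 <- paste0("C", "A", "C", strrep("A", 12), "H", "AAA", "C")
  f3 <- scan_fingers(s3)
  expect_equal(f3$signature, "CX1CX12HX3C")
  expect_false(f3$canonical)
})

test_that("signature serialization round-trips", {
  expect_equal(finger_signature(c(2, 12, 3), c("H", "H")), "CX2CX12HX3H")
  expect_equal(finger_signature(c(1, 12, 3), c("H", "C")), "CX1CX12HX3C")
  for (sig in c("CX2CX12HX3H", "CX4CX20HX4H", "CX1CX12HX6H", "CX2CX13HX3C")) {
    p <- parse_signature(sig)
    expect_equal(finger_signature(p$gaps, p$terminals), sig)
  }
  expect_error(parse_signature("CXXC"), "malformed")
})

test_that("planted multi-finger proteins return exactly their fingers", {
  set.seed(42)
  for (k in 1:6) {
    linkers <- sample(c(3:8, 12:30), max(0, k - 1), replace = TRUE)
    arch <- finger_architecture("t", rep("CX2CX12HX3H", k), linkers)
    f <- scan_fingers(make_protein(arch))
    expect_equal(nrow(f), k)
    expect_true(all(f$signature == "CX2CX12HX3H"))
    expect_true(all(f$start[-1] > f$end[-k]))
  }
})

test_that("tandem arrays merge by linker length", {
  two <- function(linker) {
    s <- paste0(canonical_finger(), strrep("A", linker), canonical_finger())
    group_arrays(scan_fingers(s))
  }
  g5 <- two(5)
  expect_length(g5$arrays, 1)
  expect_equal(g5$arrays[[1]], 1:2)
  expect_equal(g5$linkers, 5)

  g15 <- two(15)
  expect_length(g15$arrays, 0)
  expect_equal(g15$isolated, 1:2)

  # TF3A layout: isolated first finger plus tandem arrays 2-4 and 5-9
  linkers <- c(20, 5, 5, 30, 5, 5, 5, 5)
  s <- paste0(
    strrep("A", 5),
    paste(vapply(seq_len(9), function(i)
      paste0(canonical_finger(),
             if (i < 9) strrep("A", linkers[i]) else ""), character(1)),
      collapse = ""))
  g <- group_arrays(scan_fingers(s))
  expect_equal(g$isolated, 1L)
  expect_equal(g$arrays, list(2:4, 5:9))

  # overlapping fingers are rejected
  f <- scan_fingers(canonical_finger())
  bad <- rbind(f, f)
  expect_error(group_arrays(bad), "overlap")
})

test_that("grouping is invariant to flanking background sequence", {
  arch <- finger_architecture("t", rep("CX2CX12HX3H", 3), c(5, 20))
  set.seed(7)
  base <- make_protein(arch)
  extended <- paste0(strrep("G", 40), base, strrep("G", 40))
  g1 <- group_arrays(scan_fingers(base))
  g2 <- group_arrays(scan_fingers(extended))
  expect_equal(g1$components, g2$components)
  expect_equal(g1$linkers, g2$linkers)
})

test_that("scanner agrees with the brute-force enumeration oracle", {
  set.seed(2024)
  for (rep in 1:200) {
    s <- random_test_sequence(sample(20:200, 1))
    mine <- scan_fingers(s)
    ref <- oracle_scan(s)
    expect_equal(nrow(mine), nrow(ref), info = s)
    if (nrow(ref)) {
      expect_equal(mine$c1, ref$c1, info = s)
      expect_equal(mine$c2, ref$c2, info = s)
      expect_equal(mine$t1, ref$t1, info = s)
      expect_equal(mine$t2, ref$t2, info = s)
    }
  }
})
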