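test_that("chromosome distribution conserves totals in natural order", {
  genes <- data.frame(gene_id = paste0("g", 1:4),
                      chromosome = c("chr1", "chr1", "chr1", "chr2"),
                      start = c(1, 2, 3, 1), stringsAsFactors = FALSE)
  d <- chromosome_distribution(genes)
  expect_equal(d, c(chr1 = 3L, chr2 = 1L))
  expect_equal(sum(d), nrow(genes))
  expect_length(chromosome_distribution(genes[0, ]), 0)
})

test_that("tandem duplicates require adjacency and protein identity", {
  prots <- as_protein_table(
    c("p1", "p2", "p3"),
    c("MKWVTFISLLLLFSSAYSRGVFRR", "MKWVTFISLLLLFSSAYSRGVFRR",
      "GGDENNQQSTPPYYWWAAGGDDEE"))
  genes <- data.frame(
    gene_id = c("g1", "g2", "g3"),
    chromosome = "chr1", start = c(100, 5000, 9000),
    end = c(1000, 6000, 10000),
    protein_id = c("p1", "p2", "p3"), stringsAsFactors = FALSE)
  pairs <- detect_tandem_duplicates(genes, prots)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$gene_a, "g1")
  expect_equal(pairs$gene_b, "g2")
  expect_equal(pairs$identity, 100)
  expect_equal(pairs$intervening_genes, 0L)

  # unrelated random proteins never reach the identity threshold
  set.seed(8)
  rnd <- as_protein_table(c("r1", "r2"),
                          c(random_test_sequence(120),
                            random_test_sequence(120)))
  genes2 <- data.frame(gene_id = c("g1", "g2"), chromosome = "chr1",
                       start = c(1, 500), end = c(400, 900),
                       protein_id = c("r1", "r2"), stringsAsFactors = FALSE)
  expect_equal(nrow(detect_tandem_duplicates(genes2, rnd)), 0)

  # missing protein: gene skipped with a warning
  genes3 <- rbind(genes2,
                  data.frame(gene_id = "g3", chromosome = "chr1",
                             start = 1000, end = 1200, protein_id = "nope"))
  expect_warning(detect_tandem_duplicates(genes3, rnd), "skipped")
})

test_that("planted duplicate pair is the only one found family-wide", {
  pp <- make_proteome(seed = 13)
  gm <- make_gene_models(pp$proteins, seed = 13)
  pairs <- detect_tandem_duplicates(gm$genes, gm$proteins)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$chromosome, "Zj04")
  expect_equal(pairs$gene_a, gm$genes$gene_id[21])
  expect_equal(pairs$gene_b, gm$genes$gene_id[22])
})

test_that("exon/intron structure counts and subset means", {
  genes <- data.frame(gene_id = paste0("g", 1:14),
                      n_exons = c(4L, 1L, rep(4L, 12)),
                      stringsAsFactors = FALSE)
  st <- exon_intron_structure(genes)
  expect_equal(st$per_gene$n_introns[1], 3L)
  expect_equal(st$per_gene$n_introns[2], 0L)

  # mean intron count reported to 1 decimal: {3 x 12, 4} -> 3.1
  subsets <- stats::setNames(c(rep("A1a", 13), NA), genes$gene_id)
  genes$n_exons <- c(rep(4L, 12), 5L, 2L)
  st2 <- exon_intron_structure(genes, subsets)
  expect_equal(st2$per_subset$mean_introns[st2$per_subset$subset == "A1a"],
               3.1)
})
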