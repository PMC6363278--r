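test_that("partition_classes matches the per-base oracle", {
  g <- lad_genome(c(chr1 = 400), bin_size = 100)
  part <- partition_classes(interval_set("chr1", 0, 200),
                            interval_set("chr1", 100, 300), g)
  df <- as.data.frame(part)
  expect_equal(df$start - 1, c(0, 100, 200, 300))
  expect_equal(df$end, c(100, 200, 300, 400))
  expect_equal(as.character(df$label), c("A-only", "A-B", "B-only", "iLAD"))
  # base-by-base comparison against the definitional oracle
  oracle <- label_oracle(0:399, list(c(0, 200)), list(c(100, 300)))
  q <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1:400, 1:400))
  hits <- GenomicRanges::findOverlaps(q, part, select = "first")
  expect_equal(as.character(S4Vectors::mcols(part)$label[hits]), oracle)
})

test_that("degenerate partitions behave", {
  g <- lad_genome(c(chr1 = 1000), bin_size = 100)
  s <- interval_set("chr1", 100, 400)
  same <- partition_classes(s, s, g)
  expect_setequal(as.character(unique(S4Vectors::mcols(same)$label)),
                  c("A-B", "iLAD"))
  none <- partition_classes(GenomicRanges::GRanges(),
                            GenomicRanges::GRanges(), g)
  cs <- coverage_summary(none)
  expect_equal(cs$fraction[cs$class == "iLAD"], 1)
  expect_equal(sum(cs$fraction), 1)
  expect_error(partition_classes(interval_set("chr1", 500, 1200), s, g),
               "beyond")
})

test_that("coverage_summary fractions and run counts", {
  g <- lad_genome(c(chr1 = 400), bin_size = 100)
  part <- partition_classes(interval_set("chr1", 0, 200),
                            interval_set("chr1", 100, 300), g)
  cs <- coverage_summary(part)
  expect_equal(cs$fraction, rep(0.25, 4))
  expect_equal(sum(cs$fraction), 1)
  # adjacent same-class runs merge before counting
  g2 <- lad_genome(c(chr1 = 1000), bin_size = 100)
  p2 <- partition_classes(interval_set("chr1", c(0, 100), c(100, 300)),
                          GenomicRanges::GRanges(), g2)
  cs2 <- coverage_summary(p2)
  expect_equal(cs2$n_domains[cs2$class == "A-only"], 1L)
})

test_that("fate_matrix marginals, identity and error handling", {
  g <- lad_genome(c(chr1 = 1000), bin_size = 100)
  ctrl <- partition_classes(interval_set("chr1", 0, 100),
                            GenomicRanges::GRanges(), g)
  trt <- partition_classes(GenomicRanges::GRanges(),
                           interval_set("chr1", 0, 100), g)
  fm <- fate_matrix(ctrl, trt)
  expect_equal(unclass(fm)["A-only", "B-only"], 100)
  expect_equal(sum(unclass(fm)[seq_len(4), seq_len(4)]), 1000)

  fm_id <- unclass(fate_matrix(ctrl, ctrl))
  expect_equal(sum(fm_id[seq_len(4), seq_len(4)]) - sum(diag(fm_id)), 0)

  # marginals reproduce coverage summaries exactly
  m <- unclass(fm)[seq_len(4), seq_len(4)]
  expect_equal(unname(rowSums(m)), coverage_summary(ctrl)$bp)
  expect_equal(unname(colSums(m)), coverage_summary(trt)$bp)

  g2 <- lad_genome(c(chr1 = 2000), bin_size = 100)
  other <- partition_classes(GenomicRanges::GRanges(),
                             GenomicRanges::GRanges(), g2)
  expect_error(fate_matrix(ctrl, other), "different genomes")
})

test_that("fate_long carries bp and row proportions", {
  g <- lad_genome(c(chr1 = 1000), bin_size = 100)
  ctrl <- partition_classes(interval_set("chr1", 0, 400),
                            GenomicRanges::GRanges(), g)
  long <- fate_long(fate_matrix(ctrl, ctrl))
  expect_equal(nrow(long), 16L)
  expect_equal(sum(long$bp), 1000)
  aa <- long[long$control == "A-only" & long$treated == "A-only", ]
  expect_equal(aa$proportion, 1)
})

test_that("lamin-set extraction inverts partition_classes on merged sets", {
  set.seed(23)
  g <- lad_genome(c(chr1 = 1e6, chr2 = 5e5), bin_size = 100)
  for (k in 1:20) {
    a <- random_set("chr1", 1e6, sample(1:6, 1))
    b <- random_set(sample(c("chr1", "chr2"), 1), 5e5, sample(1:6, 1))
    part <- partition_classes(a, b, g)
    norm <- function(gr) {
      df <- as.data.frame(gr)[, 1:3]
      df$seqnames <- as.character(df$seqnames)
      rownames(df) <- NULL
      df
    }
    expect_equal(norm(lamin_set(part, "A")), norm(a))
    expect_equal(norm(lamin_set(part, "B")), norm(b))
  }
})

test_that("domain_fates applies the majority rule with priority ties", {
  g <- lad_genome(c(chr1 = 1000), bin_size = 100)
  ctrl <- partition_classes(interval_set("chr1", 0, 400),
                            GenomicRanges::GRanges(), g)
  # 300 of 400 bases become B-only: majority B-only
  trt <- partition_classes(GenomicRanges::GRanges(),
                           interval_set("chr1", 0, 300), g)
  df <- domain_fates(ctrl, trt)
  expect_equal(df$treated[df$control == "A-only"], "B-only")
  # exact 50/50 tie resolved by priority (A-B > B-only)
  trt2 <- partition_classes(interval_set("chr1", 0, 200),
                            interval_set("chr1", 0, 400), g)
  df2 <- domain_fates(ctrl, trt2)
  expect_equal(df2$treated[df2$control == "A-only"], "A-B")
})

test_that("lad_sizes measures maximal runs", {
  s <- interval_set("chr1", 0, 10)
  expect_equal(lad_sizes(s), 10)
  g <- lad_genome(c(chr1 = 1000), bin_size = 100)
  part <- partition_classes(interval_set("chr1", c(0, 300), c(200, 500)),
                            interval_set("chr1", 300, 500), g)
  sz <- lad_sizes(part)
  expect_equal(sort(sz[["A-only"]]), 200)
  expect_equal(sz[["A-B"]], 200)
})

test_that("compare_sizes: null and shifted-group behavior", {
  same <- rep(list(c(1e5, 2e5, 3e5, 4e5, 5e5)), 4)
  names(same) <- c("A-B:ctrl", "A-B:trt", "B-only:ctrl", "B-only:trt")
  res <- compare_sizes(same)
  expect_true(all(res$tukey$p_adj > 0.99))
  expect_equal(res$n, vapply(same, length, integer(1)))

  set.seed(99)
  groups <- list(
    "A-B:ctrl" = rlnorm(50, log(1e6), 0.3),
    "A-B:trt" = rlnorm(50, log(1e6), 0.3),
    "A-only:ctrl" = rlnorm(50, log(1e7), 0.3),  # strongly shifted class
    "A-only:trt" = rlnorm(50, log(1e7), 0.3))
  res2 <- compare_sizes(groups)
  shifted <- grepl("A-only", res2$tukey$contrast)
  cross <- shifted & grepl("A-B", res2$tukey$contrast)
  expect_true(all(res2$tukey$p_adj[cross] < 0.01))
  expect_error(compare_sizes(list(a = 1:5)), "2 groups")
  expect_error(compare_sizes(list("a:x" = 1:5, "b:x" = 3)), ">= 2 domains")
})
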