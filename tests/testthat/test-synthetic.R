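test_that("a single-entry plan is realized exactly", {
  g <- lad_genome(c(chr1 = 1e7), 1e4)
  plan <- transition_plan("A-only", "B-only", 1e6, 1)
  tr <- plant_architecture(g, plan, seed = 2)
  cs_ctrl <- coverage_summary(tr$control)
  cs_trt <- coverage_summary(tr$treated)
  expect_equal(cs_ctrl$bp[cs_ctrl$class == "A-only"], 1e6)
  expect_equal(cs_ctrl$bp[cs_ctrl$class == "B-only"], 0)
  expect_equal(cs_trt$bp[cs_trt$class == "B-only"], 1e6)
  expect_equal(cs_trt$bp[cs_trt$class == "A-only"], 0)
  # same bases switch class
  expect_identical(as.data.frame(class_set(tr$control, "A-only"))[, 1:3],
                   as.data.frame(class_set(tr$treated, "B-only"))[, 1:3])
})

test_that("empty plans give all-iLAD partitions and errors are named", {
  g <- lad_genome(c(chr1 = 1e6), 1e4)
  empty <- transition_plan(character(), character(), numeric(), integer())
  tr <- plant_architecture(g, empty, seed = 1)
  expect_equal(coverage_summary(tr$control)$fraction[4], 1)
  expect_equal(coverage_summary(tr$treated)$fraction[4], 1)

  too_big <- transition_plan("A-only", "B-only", 2e6, 1)
  expect_error(plant_architecture(g, too_big, seed = 1), "capacity")
  # fits in total but not in any chromosome once gaps are accounted
  tight <- transition_plan(c("A-only", "B-only"), c("A-only", "B-only"),
                           c(6e5, 5e5), c(1L, 1L))
  expect_error(plant_architecture(lad_genome(c(chr1 = 1e6), 1e4),
                                  tight, seed = 1),
               "capacity")
})

test_that("planting is deterministic and bin-aligned with iLAD separators", {
  g <- lad_genome(c(chr1 = 2e7, chr2 = 2e7), 1e4)
  plan <- transition_plan(c("A-B", "A-only"), c("B-only", "iLAD"),
                          c(4e6, 3e6), c(3L, 2L))
  t1 <- plant_architecture(g, plan, seed = 77)
  t2 <- plant_architecture(g, plan, seed = 77)
  expect_identical(t1$domains, t2$domains)
  expect_true(all(t1$domains$start %% 1e4 == 0))
  expect_true(all(t1$domains$end %% 1e4 == 0))
  for (ch in unique(t1$domains$chrom)) {
    d <- t1$domains[t1$domains$chrom == ch, ]
    d <- d[order(d$start), ]
    if (nrow(d) > 1)
      expect_true(all(d$start[-1] - d$end[-nrow(d)] >= 1e4))
  }
})

test_that("fate matrix of planted truth reproduces random plans exactly", {
  set.seed(13)
  g <- lad_genome(c(chr1 = 3e7, chr2 = 3e7), 1e4)
  for (k in 1:10) {
    n_entry <- sample(2:6, 1)
    pairs <- expand.grid(control = LAD_CLASSES, treated = LAD_CLASSES,
                         stringsAsFactors = FALSE)
    pairs <- pairs[!(pairs$control == "iLAD" & pairs$treated == "iLAD"), ]
    pick <- pairs[sample(nrow(pairs), n_entry), ]
    plan <- transition_plan(pick$control, pick$treated,
                            bp = sample(50:400, n_entry) * 1e4,
                            n_domains = sample(1:3, n_entry, replace = TRUE))
    tr <- plant_architecture(g, plan, seed = k)
    fm <- unclass(fate_matrix(tr$control, tr$treated))
    expect_equal(fm[seq_len(4), seq_len(4)],
                 fate_expected(plan, genome_size(g)))
  }
})

test_that("simulated ChIP counts carry the planted enrichment", {
  g <- lad_genome(c(chr1 = 1.2e8), 1e4)  # 12000 bins
  plan <- transition_plan("A-only", "A-only", 6e7, 5)  # half the genome
  tr <- plant_architecture(g, plan, seed = 21)
  cfg <- sim_config(seed = 21, enrichment_log2 = 2, depth_per_bin = 50)
  cc <- simulate_chip_counts(g, tr$control, "A", cfg)
  bound <- ladscape:::bins_in_set(lamin_set(tr$control, "A"), "chr1",
                                  12000, 1e4)
  expect_gte(sum(bound), 5000)
  ratio <- mean(cc$chip$values$chr1[bound]) / mean(cc$chip$values$chr1[!bound])
  expect_gt(ratio, 3.4)
  expect_lt(ratio, 4.7)
  # input marginal mean within 2% of the configured depth
  expect_lt(abs(mean(cc$input$values$chr1) - 50) / 50, 0.02)
})

test_that("zero enrichment means no in/out difference; seeds reproduce", {
  g <- lad_genome(c(chr1 = 1e8), 1e4)
  plan <- transition_plan("B-only", "B-only", 3e7, 4)
  tr <- plant_architecture(g, plan, seed = 5)
  cfg <- sim_config(seed = 5, enrichment_log2 = 0)
  cc <- simulate_chip_counts(g, tr$control, "B", cfg)
  bound <- ladscape:::bins_in_set(lamin_set(tr$control, "B"), "chr1",
                                  10000, 1e4)
  x <- cc$chip$values$chr1[bound]
  y <- cc$chip$values$chr1[!bound]
  se <- sqrt(var(x) / length(x) + var(y) / length(y))
  expect_lt(abs(mean(x) - mean(y)), 3 * se)

  cc2 <- simulate_chip_counts(g, tr$control, "B", cfg)
  expect_identical(cc$chip$values, cc2$chip$values)
  expect_identical(cc$input$values, cc2$input$values)
})

test_that("bead ensembles realize the class radial targets", {
  g <- lad_genome(c(chr1 = 1.2e7), 1e4)
  plan <- transition_plan("B-only", "B-only", 6e6, 2)
  tr <- plant_architecture(g, plan, seed = 6)
  cfg <- sim_config(seed = 6, radial_bias = c("A-B" = 0.9, "A-only" = 0.7,
                                              "B-only" = 0.9, "iLAD" = 0.5))
  ens <- simulate_structures(g, list(control = tr$control), n_models = 100,
                             cfg = cfg)
  # majority-overlap membership: domain-edge beads are placed by their
  # majority class, so the generator's target contract is stated for them
  stats <- class_distance_stats(ens$control, tr$control,
                                min_overlap = cfg$tad_size / 2)
  m <- stats$summary
  expect_gt(m$mean[m$class == "B-only"], 0.85)
  expect_lt(m$mean[m$class == "B-only"], 0.95)
  expect_lt(abs(m$mean[m$class == "iLAD"] - 0.5), 0.05)
  # beads strictly inside the nucleus, one bead per tile
  one <- simulate_structures(g, list(control = tr$control), n_models = 1,
                             cfg = cfg)
  expect_equal(length(one$control), 1L)
  s <- one$control[[1]]
  expect_true(all(sqrt(s$x^2 + s$y^2 + s$z^2) < 5))
  expect_equal(nrow(s), ceiling(1.2e7 / cfg$tad_size))
})

test_that("equal radial targets give exchangeable classes", {
  g <- lad_genome(c(chr1 = 2.4e7), 1e4)
  plan <- transition_plan(c("A-B", "A-only", "B-only"),
                          c("A-B", "A-only", "B-only"),
                          c(4e6, 4e6, 4e6), c(2L, 2L, 2L))
  tr <- plant_architecture(g, plan, seed = 9)
  cfg <- sim_config(seed = 9, radial_bias = c("A-B" = 0.6, "A-only" = 0.6,
                                              "B-only" = 0.6, "iLAD" = 0.6))
  ens <- simulate_structures(g, list(control = tr$control), n_models = 50,
                             cfg = cfg)
  m <- class_distance_stats(ens$control, tr$control)$summary
  expect_lt(diff(range(m$mean)), 0.03)
  expect_error(sim_config(radial_bias = c("A-B" = 1.2, "A-only" = 0.5,
                                          "B-only" = 0.5, "iLAD" = 0.5)),
               "\\(0, 1\\]")
})

test_that("expression simulation plants the configured effects", {
  g <- lad_genome(c(chr1 = 3e7), 1e4)
  plan <- transition_plan(c("A-only", "B-only"), c("B-only", "B-only"),
                          c(5e6, 5e6), c(2L, 2L))
  tr <- plant_architecture(g, plan, seed = 10)
  cfg <- sim_config(seed = 10,
                    expr_effect = c("A-only>B-only" = -1))
  genes <- simulate_genes(g, tr$control, tr$treated,
                          n_per_transition = 200, seed = 10)
  ex <- simulate_expression(genes, tr$control, tr$treated, cfg)
  sw <- ex$class_control == "A-only" & ex$class_treated == "B-only"
  lfc <- log2(ex$FPKM_treated[sw] / ex$FPKM_control[sw])
  expect_gt(mean(lfc), -1.3)
  expect_lt(mean(lfc), -0.7)
  # zero-effect genes: paired mean FPKM change within 2 SE of 0
  keep <- ex$class_control == "B-only" & ex$class_treated == "B-only"
  delta <- ex$FPKM_treated[keep] - ex$FPKM_control[keep]
  expect_lt(abs(mean(delta)), 2 * sd(delta) / sqrt(length(delta)))
  # determinism
  ex2 <- simulate_expression(genes, tr$control, tr$treated, cfg)
  expect_identical(ex, ex2)
})

test_that("FISH spot tables have two alleles per nucleus at the target", {
  spots <- simulate_fish_spots(c(control = 1.0), n_nuclei = 100, seed = 14)
  expect_equal(nrow(spots), 200L)
  p <- fish_normalized_position(spots)
  expect_true(all(p >= 0.8))  # truncated normal at mean 1, sd 0.05

  spots5 <- simulate_fish_spots(c(control = 0.5), n_nuclei = 500, seed = 15)
  expect_equal(nrow(spots5), 1000L)
  p5 <- fish_normalized_position(spots5)
  expect_gt(mean(p5), 0.45)
  expect_lt(mean(p5), 0.55)
  expect_error(simulate_fish_spots(c(a = 0), 10), "\\(0, 1\\]")
})
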