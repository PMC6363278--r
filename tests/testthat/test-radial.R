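test_that("normalized distance: exact values, errors, scale invariance", {
  expect_equal(normalized_distance(1.5, 2, 0, R = 5), 0.5)
  expect_equal(normalized_distance(0, 0, 0, R = 5), 0)
  expect_error(normalized_distance(3, 4, 0, R = 5), ">= 1")
  expect_error(normalized_distance(1, 1, 1, R = -1), "> 0")
  # scaling coordinates and R together is a no-op
  set.seed(2)
  x <- runif(50, -1, 1); y <- runif(50, -1, 1); z <- runif(50, -1, 1)
  expect_equal(normalized_distance(x, y, z, R = 2),
               normalized_distance(10 * x, 10 * y, 10 * z, R = 20))
})

test_that("bead_structure validates geometry and intervals", {
  ok <- data.frame(bead = 1:2, chrom = "chr1", start = c(0, 10),
                   end = c(10, 20), x = c(0, 1), y = 0, z = 0,
                   radius = 0.1)
  s <- bead_structure(ok, R = 5)
  expect_s3_class(s, "bead_structure")
  bad <- ok; bad$x <- c(0, 5)
  expect_error(bead_structure(bad, R = 5), ">= R")
  ovl <- ok; ovl$start <- c(0, 5)
  expect_error(bead_structure(ovl, R = 5), "overlap")
})

test_that("class-to-bead mapping matches a per-base oracle", {
  g <- lad_genome(c(chr1 = 2e6), 1e4)
  part <- partition_classes(interval_set("chr1", 0, 4e5),
                            interval_set("chr1", 3e5, 8e5), g)
  beads <- data.frame(bead = 1:2, chrom = "chr1",
                      start = c(0, 1e6), end = c(1e6, 2e6),
                      x = c(1, 2), y = 0, z = 0, radius = 0.15)
  s <- bead_structure(beads, R = 5)
  m <- map_classes_to_beads(part, s)
  # bead 1 spans A-only [0,3e5), A-B [3e5,4e5), B-only [4e5,8e5) + iLAD
  expect_true(all(m[1, c("A-only", "A-B", "B-only")]))
  expect_false(m[1, "iLAD"])  # carries lamin classes, so not inter-LAD
  expect_false(any(m[2, c("A-only", "A-B", "B-only")]))
  expect_true(m[2, "iLAD"])
  # oracle: base tallies per class inside each bead interval
  for (lbl in c("A-only", "A-B", "B-only")) {
    cs <- class_set(part, lbl)
    for (b in 1:2) {
      bp <- sum(pmax(0, pmin(GenomicRanges::end(cs), beads$end[b]) -
                       pmax(GenomicRanges::start(cs) - 1, beads$start[b])))
      expect_identical(unname(m[b, lbl]), bp >= 1)
    }
  }
  # min_overlap raises the membership bar
  m2 <- map_classes_to_beads(part, s, min_overlap = 2e5)
  expect_false(m2[1, "A-B"])  # only 1e5 bp of A-B in bead 1
  expect_true(m2[1, "B-only"])
})

test_that("random class placement shows no radial ordering", {
  # 10^4 beads placed identically; classes assigned at random must not
  # differ in mean distance by more than 0.02
  set.seed(55)
  n <- 1e4
  g <- lad_genome(c(chr1 = n * 1e4), 1e4)
  labels <- sample(LAD_CLASSES, n, replace = TRUE)
  runs <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(seq(1, by = 1e4, length.out = n),
                                                  width = 1e4))
  a <- GenomicRanges::reduce(runs[labels %in% c("A-B", "A-only")])
  b <- GenomicRanges::reduce(runs[labels %in% c("A-B", "B-only")])
  part <- partition_classes(a, b, g)
  r <- 5 * rbeta(n, 0.7 * 50, 0.3 * 50)
  beads <- data.frame(bead = seq_len(n), chrom = "chr1",
                      start = seq(0, by = 1e4, length.out = n),
                      end = seq(1e4, by = 1e4, length.out = n),
                      x = r, y = 0, z = 0, radius = 0.1)
  s <- bead_structure(beads, R = 5)
  stats <- class_distance_stats(list(s), part)
  expect_lt(diff(range(stats$summary$mean)), 0.02)
})

test_that("transition stats: planted shifts detected, identical ensembles null", {
  g <- lad_genome(c(chr1 = 1.2e7), 1e4)
  plan <- transition_plan(c("B-only", "A-B"), c("iLAD", "A-B"),
                          c(3e6, 3e6), c(1L, 1L))
  tr <- plant_architecture(g, plan, seed = 61)
  cfg <- sim_config(seed = 61)
  ens <- simulate_structures(g, list(control = tr$control,
                                     treated = tr$treated),
                             n_models = 40, cfg = cfg)
  tds <- transition_distance_stats(ens$control, ens$treated,
                                   tr$control, tr$treated)
  loss <- tds[tds$class_control == "B-only" & tds$class_treated == "iLAD", ]
  expect_equal(loss$direction, "center")  # 0.9 -> 0.5
  expect_lt(loss$p, 0.01)
  stay <- tds[tds$class_control == "A-B" & tds$class_treated == "A-B", ]
  expect_equal(stay$direction, "none")
  empty <- tds[tds$class_control == "A-only", ]
  expect_true(all(empty$n_ctrl == 0))

  # identical ensembles: every populated pair has t = 0, p = 1
  null_tds <- transition_distance_stats(ens$control, ens$control,
                                        tr$control, tr$control)
  pop <- null_tds[null_tds$n_ctrl > 0, ]
  expect_true(all(pop$p == 1))
  expect_true(all(pop$direction == "none"))
})

test_that("probe distances come from the bead containing the midpoint", {
  beads <- data.frame(bead = 1:2, chrom = "chr1", start = c(0, 1e6),
                      end = c(1e6, 2e6), x = 0, y = 0, z = c(2.5, 1),
                      radius = 0.1)
  s1 <- bead_structure(beads, R = 5, model_id = "m1")
  b2 <- beads; b2$z <- c(4, 1)
  s2 <- bead_structure(b2, R = 5, model_id = "m2")
  d <- probe_distance("chr1", 4e5, 6e5, list(s1, s2))
  expect_equal(d, c(0.5, 0.8))
  expect_error(probe_distance("chr1", 3e6, 3.1e6, list(s1)), "no bead")
})

test_that("FISH normalization: circle exact, ellipse worked example", {
  circ <- data.frame(spot_x = 1, spot_y = 1, center_x = 0, center_y = 0,
                     axis_a = 4, axis_b = 4)
  expect_equal(fish_normalized_position(circ), sqrt(2) / 4)
  center <- data.frame(spot_x = 3, spot_y = -2, center_x = 3, center_y = -2,
                       axis_a = 4, axis_b = 2)
  expect_equal(fish_normalized_position(center), 0)
  ell <- data.frame(spot_x = 2, spot_y = 0, center_x = 0, center_y = 0,
                    axis_a = 4, axis_b = 2)
  expect_equal(fish_normalized_position(ell), 0.5, tolerance = 1e-12)
  out <- data.frame(spot_x = 5, spot_y = 0, center_x = 0, center_y = 0,
                    axis_a = 4, axis_b = 2)
  expect_error(fish_normalized_position(out), "outside")
  # circle reduction is exact for random points
  set.seed(8)
  r <- runif(100, 0, 3.9); th <- runif(100, 0, 2 * pi)
  df <- data.frame(spot_x = r * cos(th) + 1, spot_y = r * sin(th) - 2,
                   center_x = 1, center_y = -2, axis_a = 4, axis_b = 4)
  expect_equal(fish_normalized_position(df), r / 4)
})

test_that("fish_compare detects planted shifts and handles edge cases", {
  spots <- simulate_fish_spots(c(control = 0.7, treated = 0.85),
                               n_nuclei = 100, seed = 70)
  cmp <- fish_compare(spots, alpha = 0.01)
  expect_equal(cmp$n1, 200L)
  expect_equal(cmp$n2, 200L)
  expect_lt(cmp$p, 0.01)
  expect_equal(cmp$direction, "periphery")

  flat <- simulate_fish_spots(c(control = 0.6), n_nuclei = 50, seed = 71)
  same <- rbind(flat, transform(flat, condition = "treated"))
  cmp2 <- fish_compare(same)
  expect_equal(cmp2$t, 0)
  expect_equal(cmp2$p, 1)

  odd <- rbind(spots, data.frame(nucleus_id = "x", condition = "control",
                                 probe_id = "probe2", spot_x = 0.1,
                                 spot_y = 0, center_x = 0, center_y = 0,
                                 axis_a = 4, axis_b = 4, theta = 0))
  expect_warning(fish_compare(odd), "skipped")
})

test_that("structure TSV round-trips", {
  g <- lad_genome(c(chr1 = 6e6), 1e4)
  part <- partition_classes(interval_set("chr1", 0, 3e6),
                            GenomicRanges::GRanges(), g)
  ens <- simulate_structures(g, list(control = part), n_models = 3,
                             cfg = sim_config(seed = 5), R_um = 5)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_structures_tsv(ens$control, f)
  back <- read_structures_tsv(f)
  expect_equal(length(back), 3L)
  expect_equal(attr(back[[1]], "R"), 5)
  expect_equal(back[[1]]$x, ens$control[[1]]$x, tolerance = 1e-12)
})
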