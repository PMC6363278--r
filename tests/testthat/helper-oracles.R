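# Independent oracles and small fixture builders shared across tests.

# Brute-force enumeration of all maximal scoring subsequences: candidates
# [i, j] whose cumulative sums satisfy the strict left-minimum /
# right-maximum characterization, kept when not contained in a larger
# candidate. Independent of the stack algorithm used by the package.
bf_max_segments <- function(scores, min_score = -Inf) {
  n <- length(scores)
  c0 <- c(0, cumsum(scores))
  cand <- list()
  for (i in seq_len(n)) {
    mn <- Inf
    mx <- -Inf
    for (j in i:n) {
      mn <- min(mn, c0[j + 1])
      mx <- max(mx, c0[j])
      if (c0[i] < mn && c0[j + 1] > mx)
        cand[[length(cand) + 1]] <- c(i, j, c0[j + 1] - c0[i])
    }
  }
  if (!length(cand))
    return(matrix(numeric(0), ncol = 3,
                  dimnames = list(NULL, c("start", "end", "score"))))
  m <- do.call(rbind, cand)
  keep <- vapply(seq_len(nrow(m)), function(k) {
    !any(m[, 1] <= m[k, 1] & m[, 2] >= m[k, 2] &
           (m[, 1] != m[k, 1] | m[, 2] != m[k, 2]))
  }, logical(1))
  m <- m[keep, , drop = FALSE]
  m <- m[m[, 3] >= min_score - 1e-9, , drop = FALSE]  # same float guard

  colnames(m) <- c("start", "end", "score")
  m[order(m[, 1]), , drop = FALSE]
}

# Per-base class labeling from raw interval lists (no GRanges algebra):
# the definition of the A-B / A-only / B-only / iLAD partition applied
# base by base.
label_oracle <- function(pos0, a_intervals, b_intervals) {
  inside <- function(p, iv) {
    any(vapply(iv, function(x) p >= x[1] && p < x[2], logical(1)))
  }
  vapply(pos0, function(p) {
    in_a <- inside(p, a_intervals)
    in_b <- inside(p, b_intervals)
    if (in_a && in_b) "A-B" else if (in_a) "A-only"
    else if (in_b) "B-only" else "iLAD"
  }, character(1))
}

# Base-counting Jaccard on small integer coordinate sets.
jaccard_oracle <- function(a_intervals, b_intervals, limit) {
  pos <- 0:(limit - 1)
  in_a <- label_oracle(pos, a_intervals, list()) == "A-only"
  in_b <- label_oracle(pos, list(), b_intervals) == "B-only"
  sum(in_a & in_b) / sum(in_a | in_b)
}

# Expected fate matrix implied by a transition plan (everything unplanted
# is iLAD -> iLAD).
fate_expected <- function(plan, genome_bp) {
  m <- matrix(0, 4, 4, dimnames = list(control = LAD_CLASSES,
                                       treated = LAD_CLASSES))
  for (e in seq_len(nrow(plan)))
    m[plan$control[e], plan$treated[e]] <-
      m[plan$control[e], plan$treated[e]] + plan$bp[e]
  m["iLAD", "iLAD"] <- genome_bp - sum(m)
  m
}

# Random merged interval set on a single-chromosome toy genome.
random_set <- function(chrom = "chr1", max_pos = 1000, n = 5) {
  s <- sort(sample.int(max_pos - 1, n))
  e <- pmin(s + sample.int(50, n, replace = TRUE), max_pos)
  interval_set(chrom, s, e)
}

# Tiny ratio track from explicit per-chromosome value vectors.
toy_track <- function(values, bin_size = 1000) {
  sl <- vapply(values, function(v) length(v) * bin_size, numeric(1))
  ratio_track(values, bin_size, sl)
}

# Toy count track builder.
toy_counts <- function(values, bin_size = 1000) {
  sl <- vapply(values, function(v) length(v) * bin_size, numeric(1))
  count_track(values, bin_size, sl)
}

# Small two-chromosome pipeline configuration that keeps the full run fast.
mini_plan <- function() {
  transition_plan(
    control  = c("A-B", "A-B", "A-only", "A-only", "B-only", "B-only", "iLAD"),
    treated  = c("A-B", "B-only", "iLAD", "B-only", "B-only", "A-B", "B-only"),
    bp       = c(3e6, 1.5e6, 1.2e6, 8e5, 1.5e6, 8e5, 6e5),
    n_domains = c(2L, 1L, 1L, 1L, 1L, 1L, 1L))
}

mini_config <- function(seed = 1L) {
  default_run_config(
    seed = seed,
    genome = list(chromosomes = c(chr1 = 1.2e7, chr2 = 1.2e7),
                  bin_size = 1e4),
    plan = mini_plan(),
    caller = list(n_runs = 4, jitter_sd = 0.1, min_score = 3),
    n_models = 20,
    n_genes_per_transition = 10,
    n_nuclei = 30)
}
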