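#' Domain caller parameters
#'
#' The broad-domain caller is governed by two tuning parameters in the
#' spirit of enriched-domain detection for LADs: `BS` (BinSize), the
#' analysis bin size the ratio track is coarsened to before segmentation,
#' and `GP` (GapPenalty), the per-bin penalty paid for bridging a
#' non-enriched bin. Bins with log-ratio >= `tau` score +1, all others
#' (including masked bins) score `-GP`; candidate domains are the disjoint
#' maximal-scoring segments of this score sequence, kept when their score is
#' at least `min_score` enriched-bin equivalents.
#'
#' @param BS analysis bin size in bp.
#' @param GP gap penalty (>= 0).
#' @param tau log2-ratio enrichment threshold.
#' @param min_score minimal segment score retained (default 3).
#' @return object of class `caller_params`.
#' @export
caller_params <- function(BS, GP, tau, min_score = 3) {
  if (GP < 0) stop("GP must be >= 0")
  if (BS <= 0) stop("BS must be > 0")
  structure(list(BS = BS, GP = GP, tau = tau, min_score = min_score),
            class = "caller_params")
}

#' @export
print.caller_params <- function(x, ...) {
  cat(sprintf("<caller_params> BS=%g bp, GP=%.3f, tau=%.4f, min_score=%g\n",
              x$BS, x$GP, x$tau, x$min_score))
  invisible(x)
}

#' Coarsen a ratio track to a larger bin size
#'
#' Each coarse bin takes the mean of its unmasked member bins; a coarse bin
#' is masked only when all members are masked. `BS` equal to the native bin
#' size is the identity.
#'
#' @param track a `ratio_track`.
#' @param BS target bin size, a multiple of the native bin size.
#' @return a `ratio_track` at bin size `BS`.
#' @export
rebin <- function(track, BS) {
  k <- BS / track$bin_size
  if (abs(k - round(k)) > 1e-9)
    stop("BS must be a multiple of the native bin size")
  k <- as.integer(round(k))
  if (k == 1L) return(track)
  vals <- lapply(track$values, function(v) {
    pad <- (k - length(v) %% k) %% k
    mat <- matrix(c(v, rep(NA_real_, pad)), nrow = k)
    cnt <- colSums(!is.na(mat))
    out <- colSums(mat, na.rm = TRUE) / cnt
    out[cnt == 0] <- NA_real_
    out
  })
  ratio_track(vals, BS, track$seqlengths)
}

# Otsu's two-class threshold on continuous values: the histogram cut
# maximizing between-class variance. Deterministic; ties -> lowest cut.
otsu_threshold <- function(vals, n_breaks = 512) {
  h <- graphics::hist(vals, breaks = n_breaks, plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w1 <- cumsum(p)
  m1 <- cumsum(p * mids)
  m_tot <- m1[length(m1)]
  valid <- w1 > 0 & w1 < 1
  sb2 <- rep(-Inf, length(p))
  sb2[valid] <- (m_tot * w1[valid] - m1[valid])^2 /
    (w1[valid] * (1 - w1[valid]))
  k <- which.max(sb2)
  h$breaks[k + 1]  # upper edge of the last class-1 bin
}

# All maximal scoring subsequences of a numeric score vector
# (Ruzzo & Tompa linear-time algorithm). Returns a matrix with columns
# start, end (1-based bin indices) and score.
maximal_scoring_segments <- function(scores) {
  n <- length(scores)
  # stacks for the candidate subsequence list
  s_start <- integer(n); s_end <- integer(n)
  s_L <- numeric(n); s_R <- numeric(n)
  top <- 0L
  cum <- 0
  for (i in seq_len(n)) {
    x <- scores[[i]]
    if (x <= 0) { cum <- cum + x; next }
    # new single-element candidate
    cstart <- i; cend <- i; cL <- cum; cR <- cum + x
    cum <- cum + x
    repeat {
      # find rightmost candidate j with L_j < cL
      j <- top
      while (j >= 1L && s_L[j] >= cL) j <- j - 1L
      if (j == 0L || s_R[j] >= cR) {
        # add as its own candidate (drop nothing)
        top <- top + 1L
        s_start[top] <- cstart; s_end[top] <- cend
        s_L[top] <- cL; s_R[top] <- cR
        break
      }
      # merge candidate j with the new one and retry
      cstart <- s_start[j]
      cL <- s_L[j]
      top <- j - 1L
    }
  }
  if (top == 0L)
    return(matrix(numeric(0), ncol = 3,
                  dimnames = list(NULL, c("start", "end", "score"))))
  cbind(start = s_start[seq_len(top)], end = s_end[seq_len(top)],
        score = s_R[seq_len(top)] - s_L[seq_len(top)])
}

#' Call enriched domains from a ratio track
#'
#' Scores every bin of the (already coarsened) track +1 when its value is at
#' least `params$tau` and `-GP` otherwise (masked bins count as
#' non-enriched), then reports the disjoint maximal-scoring segments of each
#' chromosome's score sequence with score >= `min_score`: no extension,
#' truncation or union of adjacent reported segments can increase any
#' segment's score. Domains are returned in genome coordinates, clipped to
#' chromosome ends, sorted and non-overlapping.
#'
#' @param track a `ratio_track` at the caller's bin size (`rebin()` first).
#' @param params a `caller_params`.
#' @return `GRanges` of called domains with a `score` column.
#' @export
call_domains <- function(track, params) {
  if (abs(params$BS - track$bin_size) > 1e-9)
    stop("track must be rebinned to params$BS before calling")
  chroms <- character(0); starts <- numeric(0); ends <- numeric(0)
  scores <- numeric(0)
  for (ch in names(track$values)) {
    v <- track$values[[ch]]
    if (!length(v)) next
    sc <- ifelse(!is.na(v) & v >= params$tau, 1, -params$GP)
    seg <- maximal_scoring_segments(sc)
    if (nrow(seg)) {
      # epsilon guards against accumulated float error at the boundary
      seg <- seg[seg[, "score"] >= params$min_score - 1e-9, , drop = FALSE]
    }
    if (nrow(seg)) {
      chroms <- c(chroms, rep(ch, nrow(seg)))
      starts <- c(starts, unname((seg[, "start"] - 1) * track$bin_size + 1))
      ends <- c(ends, unname(pmin(seg[, "end"] * track$bin_size,
                                  track$seqlengths[[ch]])))
      scores <- c(scores, unname(seg[, "score"]))
    }
  }
  gr <- GRanges(factor(chroms, levels = names(track$seqlengths)),
                IRanges(starts, ends), score = scores)
  seqlengths(gr) <- unname(track$seqlengths)
  GenomicRanges::sort(gr)
}

#' Auto-estimate caller parameters from a ratio track
#'
#' A transparent heuristic with the same parameter semantics as
#' auto-estimation in enriched-domain detectors: `tau` is a two-class
#' (Otsu) threshold on the unmasked native-bin values, which lands in the
#' gap between the background mode and the enriched mode (a plain median
#' sits inside the background bulk whenever LAD coverage is below 50%, and
#' per-chromosome depth matching gives every chromosome its own background
#' offset — always below zero — so a between-mode threshold is the robust
#' choice); `BS` is the smallest bin size on a doubling ladder at which the
#' fraction of enriched coarse bins (value >= `tau`) changes by less than 1
#' percentage point versus the next coarser step; `GP` is the ratio of
#' non-enriched to enriched coarse bins at the chosen `BS` (the rarer
#' enrichment is, the costlier a bridged gap). An optional seeded Gaussian jitter (`sd = jitter_sd * GP`)
#' perturbs `GP`, which the stability protocol uses to emulate run-to-run
#' technical variability; with `jitter_sd = 0` the estimate is fully
#' deterministic.
#'
#' @param track a `ratio_track` at native resolution.
#' @param max_doublings number of BS doubling steps explored.
#' @param jitter_sd relative SD of the GP jitter (0 = none).
#' @param min_score minimal segment score passed through to the params.
#' @return a `caller_params`.
#' @export
auto_estimate <- function(track, max_doublings = 6, jitter_sd = 0,
                          min_score = 3) {
  vals <- unlist(track$values, use.names = FALSE)
  vals <- vals[!is.na(vals)]
  if (!length(vals)) stop("track is empty (all bins masked)")
  if (diff(range(vals)) < 1e-12)
    stop("degenerate input: track values are constant")
  tau <- otsu_threshold(vals)

  ladder <- track$bin_size * 2^(0:max_doublings)
  enr_frac <- vapply(ladder, function(bs) {
    tr <- rebin(track, bs)
    v <- unlist(tr$values, use.names = FALSE)
    sum(!is.na(v) & v >= tau) / length(v)  # masked bins are non-enriched
  }, numeric(1))
  BS <- ladder[length(ladder)]
  for (i in seq_len(length(ladder) - 1)) {
    if (abs(enr_frac[i] - enr_frac[i + 1]) < 0.01) { BS <- ladder[i]; break }
  }

  tr <- rebin(track, BS)
  v <- unlist(tr$values, use.names = FALSE)
  n_enr <- sum(!is.na(v) & v >= tau)
  n_non <- length(v) - n_enr
  if (n_non == 0 || n_enr == 0)
    stop("degenerate input: no threshold separates enriched from background")
  # penalty scales with how much rarer enrichment is than background:
  # the non-enriched/enriched count ratio (~2-6 on LAD-like coverage)
  # keeps segments from bridging megabase inter-LAD gaps
  GP <- n_non / n_enr
  if (jitter_sd > 0) {
    GP <- GP * (1 + stats::rnorm(1, 0, jitter_sd))
    GP <- max(GP, 1e-3)
  }
  caller_params(BS = BS, GP = GP, tau = tau, min_score = min_score)
}

#' Multi-run stability protocol for domain calling
#'
#' Runs auto-estimation `n_runs` times with seeded jitter on the gap
#' penalty, calls domains with each parameter set, and quantifies technical
#' variability as the "variable subdomains": bases covered by at least one
#' run but not by all runs (union minus intersection of the run coverages).
#' GP and BS are then fixed to their run averages (BS rounded to a multiple
#' of the native bin size) for a final call.
#'
#' @param track a `ratio_track` at native resolution.
#' @param n_runs number of auto-estimation runs (>= 2; default 10).
#' @param seed integer seed driving the jitter.
#' @param jitter_sd relative SD of the per-run GP jitter (default 0.1).
#' @param min_score minimal segment score.
#' @return a `stability_report`: list with per-run parameter table `runs`,
#'   per-run LAD sets `run_sets`, `variable_subdomains` (`GRanges`),
#'   `median_variable_length` (bp), `gp_sd`, final `params` and final LAD
#'   set `lads`.
#' @export
stability_protocol <- function(track, n_runs = 10, seed = 1L,
                               jitter_sd = 0.1, min_score = 3) {
  if (n_runs < 2) stop("n_runs must be >= 2")
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  params <- vector("list", n_runs)
  run_sets <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    p <- auto_estimate(track, jitter_sd = jitter_sd, min_score = min_score)
    params[[r]] <- p
    run_sets[[r]] <- call_domains(rebin(track, p$BS), p)
  }
  runs <- data.frame(run = seq_len(n_runs),
                     BS = vapply(params, `[[`, numeric(1), "BS"),
                     GP = vapply(params, `[[`, numeric(1), "GP"),
                     tau = vapply(params, `[[`, numeric(1), "tau"),
                     n_domains = vapply(run_sets, length, integer(1)),
                     coverage_bp = vapply(run_sets, function(g)
                       sum(as.numeric(width(g))), numeric(1)))
  covs <- lapply(run_sets, as_interval_set)
  uni <- Reduce(GenomicRanges::union, covs)
  inter <- Reduce(GenomicRanges::intersect, covs)
  variable <- GenomicRanges::setdiff(uni, inter)
  med_len <- if (length(variable)) stats::median(width(variable)) else 0

  bs_avg <- mean(runs$BS)
  bs_avg <- max(track$bin_size,
                round(bs_avg / track$bin_size) * track$bin_size)
  p_final <- caller_params(BS = bs_avg, GP = mean(runs$GP),
                           tau = stats::median(runs$tau),
                           min_score = min_score)
  lads <- call_domains(rebin(track, p_final$BS), p_final)
  structure(list(runs = runs, run_sets = run_sets,
                 variable_subdomains = variable,
                 median_variable_length = med_len,
                 gp_sd = stats::sd(runs$GP),
                 params = p_final, lads = lads),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf(paste0("<stability_report> %d runs; GP %.3f (sd %.3f), ",
                     "BS %g bp; %d final domains, %.2f Mb; ",
                     "variable subdomains: %d (median %.3g kb)\n"),
              nrow(x$runs), x$params$GP, x$gp_sd, x$params$BS,
              length(x$lads), sum(as.numeric(width(x$lads))) / 1e6,
              length(x$variable_subdomains),
              x$median_variable_length / 1e3))
  invisible(x)
}
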