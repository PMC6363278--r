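#' Simulation configuration
#'
#' Collects every tunable of the synthetic-data generator. Defaults state
#' the simulated world once: negative-binomial binned ChIP counts with
#' 4-fold (2 log2) in-LAD enrichment at a mean input depth of 50 reads per
#' bin; bead structures in a 5 um nucleus with class radial targets
#' mirroring the expected ordering (inter-LADs most central, lamin-B-bound
#' classes most peripheral); expression effects that downregulate genes
#' gaining lamin B association.
#'
#' @param seed integer; fixes all randomness of simulators that are not
#'   given an explicit seed.
#' @param enrichment_log2 mean in-LAD log2 ChIP/input enrichment.
#' @param depth_per_bin mean input reads per bin (> 0).
#' @param dispersion negative-binomial dispersion (variance = mu + mu^2 *
#'   dispersion); 0 gives Poisson counts.
#' @param radial_bias named vector: target mean normalized radial distance
#'   (in (0, 1]) per LAD class.
#' @param expr_effect named vector of log2 FPKM shifts keyed
#'   `"<control class>><treated class>"`; unlisted transitions have no
#'   planted effect.
#' @param expr_sd SD of the per-gene log2 fold-change noise.
#' @param fpkm_meanlog,fpkm_sdlog lognormal parameters of baseline FPKM.
#' @param tad_size TAD tile size (bp) for bead structures.
#' @param radial_concentration Beta concentration of the radial placement
#'   (larger = tighter around the class target).
#' @param bead_radius_per_mb bead radius in um per Mb of TAD (bead size is
#'   proportional to the linear size of the TAD).
#' @param fish_spread SD of the normalized FISH spot position around its
#'   target.
#' @param R_um nucleus radius in micrometers (default 5).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       enrichment_log2 = 2,
                       depth_per_bin = 50,
                       dispersion = 0.05,
                       radial_bias = c("A-B" = 0.9, "A-only" = 0.7,
                                       "B-only" = 0.9, "iLAD" = 0.5),
                       expr_effect = c("A-only>B-only" = -1,
                                       "iLAD>B-only" = -1,
                                       "iLAD>A-B" = -0.5),
                       expr_sd = 0.3,
                       fpkm_meanlog = log(8), fpkm_sdlog = 0.8,
                       tad_size = 6e5,
                       radial_concentration = 50,
                       bead_radius_per_mb = 0.15,
                       fish_spread = 0.05,
                       R_um = 5) {
  if (depth_per_bin <= 0) stop("depth_per_bin must be > 0")
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (!all(LAD_CLASSES %in% names(radial_bias)))
    stop("radial_bias must name all four LAD classes")
  if (any(radial_bias <= 0 | radial_bias > 1))
    stop("radial_bias targets must lie in (0, 1]")
  if (R_um <= 0) stop("R_um must be > 0")
  structure(list(seed = as.integer(seed), enrichment_log2 = enrichment_log2,
                 depth_per_bin = depth_per_bin, dispersion = dispersion,
                 radial_bias = radial_bias, expr_effect = expr_effect,
                 expr_sd = expr_sd, fpkm_meanlog = fpkm_meanlog,
                 fpkm_sdlog = fpkm_sdlog, tad_size = tad_size,
                 radial_concentration = radial_concentration,
                 bead_radius_per_mb = bead_radius_per_mb,
                 fish_spread = fish_spread, R_um = R_um),
            class = "sim_config")
}

#' Transition plan for planted LAD architectures
#'
#' Each entry plants `n_domains` non-overlapping, bin-aligned domains
#' totalling `bp` base pairs that carry class `control` before treatment
#' and class `treated` after; all unplanted bases are `iLAD` in both
#' conditions.
#'
#' @param control,treated character vectors of LAD class labels.
#' @param bp total base pairs per entry.
#' @param n_domains number of planted domains per entry.
#' @return a `transition_plan` data frame.
#' @export
transition_plan <- function(control, treated, bp, n_domains) {
  df <- data.frame(control = control, treated = treated,
                   bp = as.numeric(bp), n_domains = as.integer(n_domains))
  if (!all(df$control %in% LAD_CLASSES) || !all(df$treated %in% LAD_CLASSES))
    stop("classes must be among: ", paste(LAD_CLASSES, collapse = ", "))
  if (any(df$bp < 0)) stop("bp must be >= 0")
  if (any(df$bp > 0 & df$n_domains < 1))
    stop("entries with bp > 0 need n_domains >= 1")
  class(df) <- c("transition_plan", "data.frame")
  df
}

#' @rdname transition_plan
#' @details `default_transition_plan()` encodes the default simulated
#'   reorganization: joint A-B domains mostly persist with a fraction
#'   losing lamin A to become B-only; most A-only domains lose lamin A and
#'   become inter-LADs while the rest switch to B-only or gain lamin B;
#'   B-only domains mostly persist with roughly a third gaining lamin A;
#'   small de novo A-only and B-only domains appear in former inter-LADs.
#'   On the default 120 Mb toy genome this plants 25 domains (~0.5-5 Mb)
#'   covering 44% of the genome.
#' @export
default_transition_plan <- function() {
  transition_plan(
    control  = c("A-B", "A-B", "A-only", "A-only", "A-only",
                 "B-only", "B-only", "iLAD", "iLAD"),
    treated  = c("A-B", "B-only", "iLAD", "B-only", "A-B",
                 "B-only", "A-B", "A-only", "B-only"),
    bp       = c(16.8e6, 9.6e6, 4.8e6, 2.4e6, 2.4e6,
                 9.6e6, 4.8e6, 1.2e6, 1.2e6),
    n_domains = c(6L, 4L, 3L, 2L, 2L, 4L, 2L, 1L, 1L))
}

#' Plant a LAD architecture with known class fates
#'
#' Realizes a `transition_plan` on a genome: domain sizes are drawn as a
#' random bin-aligned composition of each entry's base-pair budget, domains
#' are placed on chromosomes without overlap and separated by at least one
#' inter-LAD bin, and the control/treated class partitions implied by the
#' plan are returned. The plan is realized exactly in base pairs, so
#' `fate_matrix()` of the two returned partitions reproduces the plan's bp
#' table (all unplanted bases being iLAD -> iLAD).
#'
#' @param genome a `lad_genome`.
#' @param plan a `transition_plan`.
#' @param seed integer seed; the same seed gives an identical architecture.
#' @return list with `control` and `treated` class partitions and a
#'   `domains` data frame (0-based half-open coordinates).
#' @export
plant_architecture <- function(genome, plan, seed = 1L) {
  bs <- genome$bin_size
  plan <- plan[plan$bp > 0 & !(plan$control == "iLAD" & plan$treated == "iLAD"), ,
               drop = FALSE]
  if (sum(plan$bp) > genome_size(genome))
    stop("plan exceeds genome capacity: total bp > genome size")
  if (nrow(plan) && any(plan$bp %% bs != 0))
    stop("entry bp budgets must be multiples of the genome bin size")
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))

  # split each entry's bin budget into n_domains parts of >= 1 bin
  doms <- list()
  for (e in seq_len(nrow(plan))) {
    total_bins <- plan$bp[e] / bs
    k <- plan$n_domains[e]
    if (total_bins < k)
      stop(sprintf("entry %d (%s -> %s): %d domains do not fit in %g bp",
                   e, plan$control[e], plan$treated[e], k, plan$bp[e]))
    sizes <- if (k == 1) total_bins else
      diff(c(0, sort(sample(total_bins - 1, k - 1)), total_bins))
    doms[[e]] <- data.frame(entry = e, control = plan$control[e],
                            treated = plan$treated[e], size_bins = sizes)
  }
  doms <- do.call(rbind, doms)
  if (is.null(doms) || nrow(doms) == 0) {
    empty <- partition_classes(GRanges(), GRanges(), genome)
    return(list(control = empty, treated = empty,
                domains = data.frame(chrom = character(), start = numeric(),
                                     end = numeric(), control = character(),
                                     treated = character(), entry = integer())))
  }
  doms <- doms[sample(nrow(doms)), , drop = FALSE]

  # best-fit placement onto chromosomes, reserving one gap bin per domain
  nb <- n_bins(genome)
  used <- stats::setNames(numeric(length(nb)), names(nb))
  count <- used
  doms$chrom <- NA_character_
  for (i in seq_len(nrow(doms))) {
    need <- doms$size_bins[i]
    slack <- nb - used - count  # one separator bin per already-placed domain
    ok <- names(slack)[slack >= need + 1]  # keep one bin of slack for a gap
    if (!length(ok))
      stop(sprintf("plan exceeds genome capacity at entry %d (%s -> %s)",
                   doms$entry[i], doms$control[i], doms$treated[i]))
    pick <- ok[which.max(slack[ok])]
    doms$chrom[i] <- pick
    used[pick] <- used[pick] + need
    count[pick] <- count[pick] + 1
  }

  # lay out each chromosome: random order, >= 1 iLAD bin between domains
  placed <- list()
  for (ch in names(nb)) {
    sub <- doms[doms$chrom == ch, , drop = FALSE]
    k <- nrow(sub)
    if (k == 0) next
    sub <- sub[sample(k), , drop = FALSE]
    free <- nb[[ch]] - sum(sub$size_bins) - (k - 1)
    extras <- as.vector(stats::rmultinom(1, free, rep(1, k + 1)))
    pos <- extras[1]  # bins before the first domain
    starts <- numeric(k)
    for (j in seq_len(k)) {
      starts[j] <- pos
      pos <- pos + sub$size_bins[j] + 1 + extras[j + 1]
    }
    sub$start <- starts * bs
    sub$end <- (starts + sub$size_bins) * bs
    placed[[ch]] <- sub
  }
  domains <- do.call(rbind, placed)
  rownames(domains) <- NULL

  sets <- function(labels) {
    sel <- domains[domains[[labels$col]] %in% labels$classes, , drop = FALSE]
    if (!nrow(sel)) return(GRanges())
    interval_set(sel$chrom, sel$start, sel$end, genome)
  }
  ctrl <- partition_classes(
    sets(list(col = "control", classes = c("A-B", "A-only"))),
    sets(list(col = "control", classes = c("A-B", "B-only"))), genome)
  trt <- partition_classes(
    sets(list(col = "treated", classes = c("A-B", "A-only"))),
    sets(list(col = "treated", classes = c("A-B", "B-only"))), genome)
  list(control = ctrl, treated = trt,
       domains = domains[, c("chrom", "start", "end", "control",
                             "treated", "entry", "size_bins")])
}

bins_in_set <- function(set, chrom, nbins, bin_size) {
  flag <- logical(nbins)
  sel <- set[seqnames(set) == chrom]
  if (length(sel)) {
    for (k in seq_along(sel)) {
      i0 <- (start(sel)[k] - 1) %/% bin_size + 1
      i1 <- (end(sel)[k] - 1) %/% bin_size + 1
      flag[i0:min(i1, nbins)] <- TRUE
    }
  }
  flag
}

#' Simulate binned ChIP and input count tracks
#'
#' Draws negative-binomial counts per bin: the input track has mean
#' `depth_per_bin` everywhere; the ChIP track has its mean multiplied by
#' `2^enrichment_log2` in bins whose class includes the given lamin (lamin
#' A: `A-B` and `A-only`; lamin B: `A-B` and `B-only`).
#'
#' @param genome a `lad_genome`.
#' @param truth a class partition (bin-aligned ground truth).
#' @param lamin `"A"` or `"B"`.
#' @param cfg a `sim_config`.
#' @param seed seed (defaults to `cfg$seed`); identical seeds give
#'   identical tracks.
#' @return list with `chip` and `input` `count_track`s.
#' @export
simulate_chip_counts <- function(genome, truth, lamin = c("A", "B"),
                                 cfg = sim_config(), seed = cfg$seed) {
  lamin <- match.arg(lamin)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  bound_set <- lamin_set(truth, lamin)
  nb <- n_bins(genome)
  rcounts <- function(n, mu) {
    if (cfg$dispersion > 0)
      stats::rnbinom(n, mu = mu, size = 1 / cfg$dispersion)
    else stats::rpois(n, mu)
  }
  chip <- list(); input <- list()
  for (ch in names(nb)) {
    n <- nb[[ch]]
    bound <- bins_in_set(bound_set, ch, n, genome$bin_size)
    mu_chip <- cfg$depth_per_bin * ifelse(bound, 2^cfg$enrichment_log2, 1)
    chip[[ch]] <- rcounts(n, mu_chip)
    input[[ch]] <- rcounts(n, rep(cfg$depth_per_bin, n))
  }
  list(chip = count_track(chip, genome$bin_size, genome),
       input = count_track(input, genome$bin_size, genome))
}

# majority class of each TAD tile under a partition (ties: A-B > B-only >
# A-only > iLAD, the order used for per-domain fate labels)
tile_classes <- function(tiles, partition) {
  priority <- c("A-B", "B-only", "A-only", "iLAD")
  bp <- vapply(LAD_CLASSES, function(lbl) {
    cs <- class_set(partition, lbl)
    out <- numeric(length(tiles))
    if (length(cs)) {
      hits <- findOverlaps(tiles, cs)
      if (length(hits)) {
        w <- width(pintersect(tiles[queryHits(hits)], cs[subjectHits(hits)]))
        agg <- tapply(w, queryHits(hits), sum)
        out[as.integer(names(agg))] <- as.numeric(agg)
      }
    }
    out
  }, numeric(length(tiles)))
  if (is.null(dim(bp)))
    bp <- matrix(bp, nrow = 1, dimnames = list(NULL, LAD_CLASSES))
  apply(bp[, priority, drop = FALSE], 1, function(x)
    priority[which.max(x)])
}

genome_tiles <- function(genome, tad_size) {
  si <- genome_seqinfo(genome)
  GenomicRanges::tileGenome(si, tilewidth = tad_size,
                            cut.last.tile.in.chrom = TRUE)
}

#' Simulate bead-on-string 3D structure ensembles
#'
#' Tiles the genome into fixed-size TADs (one bead per TAD, bead radius
#' proportional to TAD length) and places each bead in a sphere of radius
#' `R_um`: the radial coordinate is drawn from a Beta distribution rescaled
#' to (0, R) whose mean equals the `radial_bias` target of the bead's
#' majority class under that condition's partition, with uniform random
#' direction. Chain connectivity is not enforced; only radial statistics
#' are meaningful downstream.
#'
#' @param genome a `lad_genome`.
#' @param partitions named list of class partitions, one per condition.
#' @param n_models structures per condition (>= 1).
#' @param cfg a `sim_config` (`radial_bias`, `tad_size`, `R_um`, ...).
#' @param R_um nucleus radius; defaults to `cfg$R_um` (5 um).
#' @param seed seed (defaults to `cfg$seed`).
#' @return named list (per condition) of lists of `bead_structure`s.
#' @export
simulate_structures <- function(genome, partitions, n_models = 100,
                                cfg = sim_config(), R_um = cfg$R_um,
                                seed = cfg$seed) {
  if (n_models < 1) stop("n_models must be >= 1")
  if (any(cfg$radial_bias <= 0 | cfg$radial_bias > 1))
    stop("radial_bias targets must lie in (0, 1]")
  if (R_um <= 0) stop("R_um must be > 0")
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  tiles <- genome_tiles(genome, cfg$tad_size)
  kappa <- cfg$radial_concentration
  out <- list()
  for (cond in names(partitions)) {
    cls <- tile_classes(tiles, partitions[[cond]])
    target <- pmin(cfg$radial_bias[cls], 0.999)
    n <- length(tiles)
    bead_radius <- cfg$bead_radius_per_mb * width(tiles) / 1e6
    models <- vector("list", n_models)
    for (m in seq_len(n_models)) {
      r <- R_um * stats::rbeta(n, target * kappa, (1 - target) * kappa)
      r <- pmin(r, R_um * (1 - 1e-9))
      z <- stats::runif(n, -1, 1)
      phi <- stats::runif(n, 0, 2 * pi)
      rho <- sqrt(pmax(1 - z^2, 0))
      models[[m]] <- bead_structure(
        data.frame(bead = seq_len(n),
                   chrom = as.character(seqnames(tiles)),
                   start = start(tiles) - 1, end = end(tiles),
                   x = r * rho * cos(phi), y = r * rho * sin(phi),
                   z = r * z, radius = bead_radius),
        R = R_um, model_id = sprintf("%s_model_%03d", cond, m))
    }
    out[[cond]] <- models
  }
  out
}

#' Simulate genes with TSSs spread over fate regions
#'
#' Places `n_per_transition` gene transcription start sites uniformly at
#' random (bin-agnostic, base resolution) inside every non-empty fate
#' region (bases with class i in control and class j in treated),
#' guaranteeing populated cells in downstream fate-expression reports.
#'
#' @param genome a `lad_genome`.
#' @param ctrl,trt class partitions.
#' @param n_per_transition genes per fate pair.
#' @param seed integer seed.
#' @return data frame with `gene_id`, `chrom`, `tss` (0-based), `strand`.
#' @export
simulate_genes <- function(genome, ctrl, trt, n_per_transition = 25,
                           seed = 1L) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  rows <- list()
  for (i in LAD_CLASSES) {
    gi <- class_set(ctrl, i)
    if (!length(gi)) next
    for (j in LAD_CLASSES) {
      gj <- class_set(trt, j)
      if (!length(gj)) next
      reg <- GenomicRanges::intersect(gi, gj)
      if (!length(reg)) next
      w <- as.numeric(width(reg))
      pick <- sample.int(length(reg), n_per_transition, replace = TRUE,
                         prob = w)
      offs <- floor(stats::runif(n_per_transition) * w[pick])
      rows[[paste(i, j, sep = ">")]] <- data.frame(
        gene_id = sprintf("g_%s_%s_%03d", gsub("-", "", i), gsub("-", "", j),
                          seq_len(n_per_transition)),
        chrom = as.character(seqnames(reg))[pick],
        tss = (start(reg)[pick] - 1) + offs,
        strand = sample(c("+", "-"), n_per_transition, replace = TRUE))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate an FPKM expression table over a planted architecture
#'
#' Baseline FPKM is lognormal; the treated FPKM applies a log2 fold change
#' drawn around the planted `expr_effect` of the gene's fate transition
#' (`Normal(effect, expr_sd)`), divided by `exp((expr_sd * ln 2)^2 / 2)` so
#' that the noise is mean-preserving: transitions with zero planted effect
#' have expected FPKM change exactly 0.
#'
#' @param genes data frame from `simulate_genes()` (or with the same
#'   columns).
#' @param ctrl,trt class partitions (the planted truth).
#' @param cfg a `sim_config`.
#' @param seed seed (defaults to `cfg$seed`).
#' @return `genes` with added `class_control`, `class_treated`,
#'   `FPKM_control`, `FPKM_treated`.
#' @export
simulate_expression <- function(genes, ctrl, trt, cfg = sim_config(),
                                seed = cfg$seed) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  genes$class_control <- assign_genes(genes, ctrl)
  genes$class_treated <- assign_genes(genes, trt)
  key <- paste(genes$class_control, genes$class_treated, sep = ">")
  eff <- ifelse(key %in% names(cfg$expr_effect),
                cfg$expr_effect[key], 0)
  n <- nrow(genes)
  fpkm0 <- stats::rlnorm(n, cfg$fpkm_meanlog, cfg$fpkm_sdlog)
  lfc <- eff + stats::rnorm(n, 0, cfg$expr_sd)
  correction <- exp((cfg$expr_sd * log(2))^2 / 2)
  genes$FPKM_control <- fpkm0
  genes$FPKM_treated <- fpkm0 * 2^lfc / correction
  genes
}

#' Simulate FISH spot tables
#'
#' Emulates 2D FISH measurements of one probe in several conditions: each
#' nucleus is an axis-aligned ellipse with randomized semi-axes, and two
#' spots (alleles) per nucleus are placed at normalized radial positions
#' drawn from a Normal around the condition's target, truncated to
#' `[0, 1]` (0 = nucleus center, 1 = boundary).
#'
#' @param class_targets named numeric vector: target mean normalized
#'   position per condition, values in (0, 1].
#' @param n_nuclei nuclei per condition (>= 1); two spots each.
#' @param probe_id probe label.
#' @param spread SD of the normalized position around the target.
#' @param axis_range range of ellipse semi-axes (um).
#' @param seed integer seed.
#' @return spot table: one row per spot with nucleus geometry columns.
#' @export
simulate_fish_spots <- function(class_targets, n_nuclei = 100,
                                probe_id = "probe1", spread = 0.05,
                                axis_range = c(3.5, 5.5), seed = 1L) {
  if (any(class_targets <= 0 | class_targets > 1))
    stop("targets must lie in (0, 1]")
  if (n_nuclei < 1) stop("n_nuclei must be >= 1")
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  rtrunc01 <- function(n, mean, sd) {
    x <- stats::rnorm(n, mean, sd)
    bad <- which(x < 0 | x > 1)
    while (length(bad)) {
      x[bad] <- stats::rnorm(length(bad), mean, sd)
      bad <- which(x < 0 | x > 1)
    }
    x
  }
  rows <- list()
  for (cond in names(class_targets)) {
    n_spots <- 2L * n_nuclei
    a <- stats::runif(n_nuclei, axis_range[1], axis_range[2])
    b <- stats::runif(n_nuclei, axis_range[1], axis_range[2])
    cx <- stats::runif(n_nuclei, -20, 20)
    cy <- stats::runif(n_nuclei, -20, 20)
    idx <- rep(seq_len(n_nuclei), each = 2)
    p <- rtrunc01(n_spots, class_targets[[cond]], spread)
    theta <- stats::runif(n_spots, 0, 2 * pi)
    rb <- 1 / sqrt((cos(theta) / a[idx])^2 + (sin(theta) / b[idx])^2)
    rows[[cond]] <- data.frame(
      nucleus_id = sprintf("%s_nuc_%04d", cond, idx),
      condition = cond, probe_id = probe_id,
      spot_x = cx[idx] + p * rb * cos(theta),
      spot_y = cy[idx] + p * rb * sin(theta),
      center_x = cx[idx], center_y = cy[idx],
      axis_a = a[idx], axis_b = b[idx], theta = 0)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
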