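#' Bead-on-string 3D structure
#'
#' One nucleus model: beads (one per TAD) with 3D centers inside a sphere
#' of radius `R` micrometers and bead radii proportional to TAD length.
#' Intervals are stored 0-based half-open, non-overlapping per chromosome.
#'
#' @param beads data frame with columns `bead`, `chrom`, `start`, `end`,
#'   `x`, `y`, `z`, `radius` (coordinates in um).
#' @param R nucleus radius in um (default 5).
#' @param model_id identifier.
#' @return object of class `bead_structure` (a data frame with attributes
#'   `R` and `model_id`).
#' @export
bead_structure <- function(beads, R = 5, model_id = "model_001") {
  need <- c("bead", "chrom", "start", "end", "x", "y", "z", "radius")
  if (!all(need %in% names(beads)))
    stop("beads need columns: ", paste(need, collapse = ", "))
  if (R <= 0) stop("R must be > 0")
  d <- sqrt(beads$x^2 + beads$y^2 + beads$z^2)
  if (any(d >= R))
    stop("bead center(s) at or beyond the nucleus radius (|center| >= R)")
  ov <- unlist(lapply(split(beads, beads$chrom), function(b) {
    b <- b[order(b$start), ]
    if (nrow(b) > 1) any(b$start[-1] < b$end[-nrow(b)]) else FALSE
  }))
  if (any(ov)) stop("bead intervals overlap within a chromosome")
  structure(beads, R = R, model_id = model_id,
            class = c("bead_structure", "data.frame"))
}

structure_R <- function(s) attr(s, "R")

#' Normalized radial distance
#'
#' Euclidean distance of a point from the nucleus center divided by the
#' nucleus radius `R`: 0 at the center, approaching 1 at the periphery.
#' Scale-invariant: scaling coordinates and `R` together changes nothing.
#'
#' @param x,y,z coordinates in um (vectors), or `x` may be a
#'   `bead_structure` (then `R` defaults to its radius attribute).
#' @param R nucleus radius in um.
#' @return numeric vector of d/R values in `[0, 1)`.
#' @export
normalized_distance <- function(x, y = NULL, z = NULL, R = 5) {
  if (inherits(x, "bead_structure")) {
    s <- x
    R <- structure_R(s)
    x <- s$x; y <- s$y; z <- s$z
  }
  if (R <= 0) stop("R must be > 0")
  d <- sqrt(x^2 + y^2 + z^2) / R
  if (any(d >= 1))
    stop("point(s) at or beyond the nucleus radius (d/R >= 1)")
  d
}

#' Map LAD classes onto beads
#'
#' A bead carries a class when at least `min_overlap` base pairs of its
#' genomic interval are labeled with that class; a bead may carry several
#' classes (TADs are larger than some LAD runs). Beads carrying no lamin
#' class form the inter-LAD group: `iLAD` is reported only for beads whose
#' overlap with every lamin class is below `min_overlap`.
#'
#' @param partition a class partition.
#' @param structure a `bead_structure` on the same genome.
#' @param min_overlap minimal overlap in bp (default 1).
#' @return logical matrix, beads x classes.
#' @export
map_classes_to_beads <- function(partition, structure, min_overlap = 1) {
  validate_partition(partition)
  if (!all(structure$chrom %in% seqlevels(partition)))
    stop("bead chromosomes not present in the partition's genome")
  tiles <- GRanges(structure$chrom,
                   IRanges(structure$start + 1, structure$end))
  m <- vapply(LAD_CLASSES, function(lbl) {
    cs <- class_set(partition, lbl)
    bp <- numeric(length(tiles))
    if (length(cs)) {
      hits <- findOverlaps(tiles, cs)
      if (length(hits)) {
        w <- width(pintersect(tiles[queryHits(hits)], cs[subjectHits(hits)]))
        agg <- tapply(w, queryHits(hits), sum)
        bp[as.integer(names(agg))] <- as.numeric(agg)
      }
    }
    bp >= min_overlap
  }, logical(length(tiles)))
  if (is.null(dim(m)))
    m <- matrix(m, nrow = 1, dimnames = list(NULL, LAD_CLASSES))
  # a bead is inter-LAD only when it carries no lamin class at all
  m[, "iLAD"] <- !(m[, "A-B"] | m[, "A-only"] | m[, "B-only"])
  rownames(m) <- structure$bead
  m
}

pool_class_distances <- function(structures, partition, min_overlap = 1) {
  stopifnot(length(structures) >= 1)
  maps <- map_classes_to_beads(partition, structures[[1]], min_overlap)
  out <- stats::setNames(vector("list", length(LAD_CLASSES)), LAD_CLASSES)
  for (lbl in LAD_CLASSES) out[[lbl]] <- vector("list", length(structures))
  for (k in seq_along(structures)) {
    s <- structures[[k]]
    d <- normalized_distance(s)
    for (lbl in LAD_CLASSES)
      out[[lbl]][[k]] <- d[maps[, lbl]]
  }
  lapply(out, function(x) unlist(x, use.names = FALSE))
}

#' Radial distance statistics per LAD class
#'
#' Pools normalized bead-center distances across all structures of an
#' ensemble, per LAD class (bead-class mapping via
#' [map_classes_to_beads()]), and reports summary statistics plus all
#' pairwise unpaired (Welch) t-tests between classes.
#'
#' @param structures list of `bead_structure`s (one ensemble/condition).
#' @param partition the condition's class partition.
#' @param min_overlap minimal bead/class overlap in bp.
#' @return list with `summary` (per-class n/mean/median/sd) and `pairwise`
#'   (data frame of class pairs with t and p; `NA` when a class is empty).
#' @export
class_distance_stats <- function(structures, partition, min_overlap = 1) {
  pooled <- pool_class_distances(structures, partition, min_overlap)
  summary <- do.call(rbind, lapply(LAD_CLASSES, function(lbl) {
    d <- pooled[[lbl]]
    data.frame(class = lbl, n = length(d),
               mean = if (length(d)) mean(d) else NA_real_,
               median = if (length(d)) stats::median(d) else NA_real_,
               sd = if (length(d) > 1) stats::sd(d) else NA_real_)
  }))
  pairs <- utils::combn(LAD_CLASSES, 2)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    a <- pooled[[pairs[1, k]]]; b <- pooled[[pairs[2, k]]]
    t_val <- NA_real_; p_val <- NA_real_
    if (length(a) >= 2 && length(b) >= 2) {
      res <- tryCatch(stats::t.test(a, b), error = function(e) NULL)
      if (!is.null(res)) { t_val <- unname(res$statistic); p_val <- res$p.value }
    }
    data.frame(class1 = pairs[1, k], class2 = pairs[2, k],
               n1 = length(a), n2 = length(b),
               delta_mean = if (length(a) && length(b))
                 mean(a) - mean(b) else NA_real_,
               t = t_val, p = p_val)
  }))
  list(summary = summary, pairwise = pairwise, distances = pooled)
}

fate_regions <- function(ctrl, trt) {
  out <- list()
  for (i in LAD_CLASSES) {
    gi <- class_set(ctrl, i)
    for (j in LAD_CLASSES) {
      gj <- class_set(trt, j)
      reg <- if (length(gi) && length(gj))
        GenomicRanges::intersect(gi, gj) else GRanges()
      out[[paste(i, j, sep = ">")]] <- reg
    }
  }
  out
}

region_distances <- function(structures, region, min_overlap = 1) {
  if (!length(region) || !length(structures)) return(numeric(0))
  s1 <- structures[[1]]
  tiles <- GRanges(s1$chrom, IRanges(s1$start + 1, s1$end))
  bp <- numeric(length(tiles))
  hits <- findOverlaps(tiles, region)
  if (length(hits)) {
    w <- width(pintersect(tiles[queryHits(hits)], region[subjectHits(hits)]))
    agg <- tapply(w, queryHits(hits), sum)
    bp[as.integer(names(agg))] <- as.numeric(agg)
  }
  keep <- bp >= min_overlap
  if (!any(keep)) return(numeric(0))
  unlist(lapply(structures, function(s) normalized_distance(s)[keep]),
         use.names = FALSE)
}

#' Radial repositioning statistics per LAD fate
#'
#' For every (control class -> treated class) fate pair, collects the
#' normalized distances of beads overlapping the fate's genomic region
#' (>= `min_overlap` bp) in the control ensemble and in the treated
#' ensemble, compares them with an unpaired Welch t-test and reports the
#' direction of the shift: `"periphery"` when the treated mean is
#' significantly larger, `"center"` when smaller, `"none"` otherwise.
#'
#' @param structures_ctrl,structures_trt structure ensembles.
#' @param ctrl,trt class partitions defining the fate regions.
#' @param alpha significance level for the direction call (default 0.01).
#' @param min_overlap minimal bead/region overlap in bp.
#' @return data frame with one row per fate pair (pairs with no beads are
#'   reported with `n = 0` and no test).
#' @export
transition_distance_stats <- function(structures_ctrl, structures_trt,
                                      ctrl, trt, alpha = 0.01,
                                      min_overlap = 1) {
  if (!same_partition_genome(ctrl, trt))
    stop("partitions are defined on different genomes")
  regions <- fate_regions(ctrl, trt)
  rows <- lapply(names(regions), function(key) {
    reg <- regions[[key]]
    dc <- region_distances(structures_ctrl, reg, min_overlap)
    dt <- region_distances(structures_trt, reg, min_overlap)
    t_val <- NA_real_; p_val <- NA_real_; dir <- "none"
    if (length(dc) >= 2 && length(dt) >= 2) {
      res <- tryCatch(stats::t.test(dt, dc), error = function(e) NULL)
      if (!is.null(res)) {
        t_val <- unname(res$statistic); p_val <- res$p.value
        if (!is.na(p_val) && p_val < alpha)
          dir <- if (mean(dt) > mean(dc)) "periphery" else "center"
      }
    }
    parts <- strsplit(key, ">", fixed = TRUE)[[1]]
    data.frame(class_control = parts[1], class_treated = parts[2],
               region_bp = sum(as.numeric(width(reg))),
               n_ctrl = length(dc), n_trt = length(dt),
               mean_ctrl = if (length(dc)) mean(dc) else NA_real_,
               mean_trt = if (length(dt)) mean(dt) else NA_real_,
               t = t_val, p = p_val, direction = dir)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Radial distance distribution of a probe locus
#'
#' Locates the bead containing the probe's midpoint in every structure and
#' returns one normalized distance per model — the model-side analogue of
#' a FISH measurement.
#'
#' @param chrom,start,end probe interval (0-based half-open bp).
#' @param structures list of `bead_structure`s.
#' @return numeric vector, one d/R per structure.
#' @export
probe_distance <- function(chrom, start, end, structures) {
  mid <- floor((start + end) / 2)
  vapply(structures, function(s) {
    hit <- which(s$chrom == chrom & s$start <= mid & mid < s$end)
    if (!length(hit))
      stop(sprintf("probe midpoint %s:%d is covered by no bead", chrom, mid))
    normalized_distance(s)[hit[1]]
  }, numeric(1))
}

#' Normalized 2D FISH spot position
#'
#' Distance of a spot from the nucleus center divided by the distance from
#' the center to the nucleus boundary along the ray through the spot. For
#' an ellipse with semi-axes (a, b) (optionally rotated by `theta`), this
#' is `sqrt((vx/a)^2 + (vy/b)^2)` with `v` the spot vector in the ellipse
#' frame — exactly `|spot - center| / r` for a circle. 0 = center, 1 =
#' boundary (the DAPI border in imaging terms).
#'
#' @param spots data frame with `spot_x`, `spot_y`, `center_x`, `center_y`,
#'   `axis_a`, `axis_b` and optional `theta` (radians).
#' @return numeric vector in `[0, 1]`.
#' @export
fish_normalized_position <- function(spots) {
  vx <- spots$spot_x - spots$center_x
  vy <- spots$spot_y - spots$center_y
  th <- if ("theta" %in% names(spots)) spots$theta else 0
  ux <- cos(th) * vx + sin(th) * vy
  uy <- -sin(th) * vx + cos(th) * vy
  p <- sqrt((ux / spots$axis_a)^2 + (uy / spots$axis_b)^2)
  if (any(p > 1 + 1e-9))
    stop("spot(s) outside the nucleus boundary")
  pmin(p, 1)
}

#' Compare FISH spot positions between conditions
#'
#' Per probe: mean and SD of normalized positions in each condition, an
#' unpaired Welch t-test between conditions, and the direction of the
#' shift. Probes present in only one condition are skipped with a warning.
#'
#' @param spots spot table with a `condition` column (exactly two
#'   conditions) and the geometry columns of
#'   [fish_normalized_position()].
#' @param alpha significance level for the direction call.
#' @return data frame with one row per probe.
#' @export
fish_compare <- function(spots, alpha = 0.01) {
  conds <- unique(spots$condition)
  if (length(conds) != 2)
    stop("spot table must contain exactly two conditions")
  spots$norm_pos <- fish_normalized_position(spots)
  rows <- list()
  for (pr in unique(spots$probe_id)) {
    sub <- spots[spots$probe_id == pr, ]
    a <- sub$norm_pos[sub$condition == conds[1]]
    b <- sub$norm_pos[sub$condition == conds[2]]
    if (length(a) < 2 || length(b) < 2) {
      warning(sprintf("probe %s missing (or < 2 spots) in one condition; skipped",
                      pr))
      next
    }
    res <- stats::t.test(b, a)
    dir <- "none"
    if (res$p.value < alpha)
      dir <- if (mean(b) > mean(a)) "periphery" else "center"
    rows[[pr]] <- data.frame(
      probe_id = pr, condition1 = conds[1], condition2 = conds[2],
      n1 = length(a), n2 = length(b),
      mean1 = mean(a), sd1 = stats::sd(a),
      mean2 = mean(b), sd2 = stats::sd(b),
      t = unname(res$statistic), p = res$p.value, direction = dir)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read/write bead structures as TSV
#'
#' The canonical plain-text structure exchange format: tab-separated
#' columns `model`, `bead`, `chrom`, `start`, `end`, `x`, `y`, `z`,
#' `radius`, with the nucleus radius recorded in a `#R_um=` header line.
#'
#' @param structures list of `bead_structure`s.
#' @param file path.
#' @return `read_structures_tsv()` returns a list of `bead_structure`s.
#' @export
write_structures_tsv <- function(structures, file) {
  R <- structure_R(structures[[1]])
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("#R_um=%g", R), con)
  df <- do.call(rbind, lapply(structures, function(s) {
    cbind(model = attr(s, "model_id"), as.data.frame(s))
  }))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_structures_tsv
#' @export
read_structures_tsv <- function(file) {
  first <- readLines(file, n = 1)
  R <- if (startsWith(first, "#R_um="))
    as.numeric(sub("#R_um=", "", first)) else 5
  df <- utils::read.delim(file, comment.char = "#",
                          stringsAsFactors = FALSE)
  lapply(split(df, df$model), function(sub) {
    bead_structure(sub[, setdiff(names(sub), "model")], R = R,
                   model_id = sub$model[1])
  })
}

#' Convert a CMM marker table into a bead structure
#'
#' @param markers data frame from [read_cmm()].
#' @param R nucleus radius in um.
#' @param model_id identifier.
#' @return a `bead_structure`.
#' @export
cmm_to_structure <- function(markers, R = 5, model_id = "cmm_model") {
  if (any(is.na(markers$start))) {
    # markers without genomic annotation get empty placeholder intervals
    markers$start <- (seq_len(nrow(markers)) - 1) * 2
    markers$end <- markers$start + 1
    markers$chrom <- ifelse(markers$chrom == "unknown", "chrU", markers$chrom)
  }
  bead_structure(markers[, c("bead", "chrom", "start", "end",
                             "x", "y", "z", "radius")],
                 R = R, model_id = model_id)
}
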