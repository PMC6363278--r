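#' Partition the genome into LAD classes
#'
#' Labels every base of the genome by joint lamin A / lamin B occupancy:
#' covered by both LAD sets -> `A-B`; by the lamin A set only -> `A-only`;
#' by the lamin B set only -> `B-only`; by neither -> `iLAD`. The result is
#' a `GRanges` that tiles each chromosome exactly (no gaps, no overlaps)
#' with a `label` metadata column; adjacent runs always carry different
#' labels.
#'
#' @param lads_A,lads_B `GRanges` LAD coverage sets for lamin A and lamin B.
#' @param genome a `lad_genome`.
#' @return a class partition (`GRanges` with `label`).
#' @examples
#' g <- lad_genome(c(chr1 = 400), bin_size = 100)
#' p <- partition_classes(interval_set("chr1", 0, 200),
#'                        interval_set("chr1", 100, 300), g)
#' @export
partition_classes <- function(lads_A, lads_B, genome) {
  a <- as_interval_set(bind_genome(lads_A, genome))
  b <- as_interval_set(bind_genome(lads_B, genome))
  check_within_genome(a, genome, "lamin A LADs")
  check_within_genome(b, genome, "lamin B LADs")
  si <- genome_seqinfo(genome)
  full <- GRanges(seqlevels(si), IRanges(1, seqlengths(si)), seqinfo = si)
  ab <- GenomicRanges::intersect(a, b)
  a_only <- GenomicRanges::setdiff(a, b)
  b_only <- GenomicRanges::setdiff(b, a)
  ilad <- GenomicRanges::setdiff(GenomicRanges::setdiff(full, a), b)
  pieces <- list(`A-B` = ab, `A-only` = a_only, `B-only` = b_only,
                 iLAD = ilad)
  grl <- lapply(names(pieces), function(lbl) {
    g <- pieces[[lbl]]
    mcols(g)$label <- rep(lbl, length(g))
    g
  })
  part <- GenomicRanges::sort(do.call(c, grl))
  mcols(part)$label <- factor(mcols(part)$label, levels = LAD_CLASSES)
  validate_partition(part)
  part
}

validate_partition <- function(part) {
  if (is.null(mcols(part)$label)) stop("partition lacks a label column")
  sl <- seqlengths(part)
  if (any(is.na(sl))) stop("partition lacks seqlengths")
  cov_bp <- sum(as.numeric(width(part)))
  if (cov_bp != sum(as.numeric(sl)))
    stop("partition does not tile the genome")
  if (length(GenomicRanges::reduce(part)) !=
      length(GenomicRanges::reduce(GRanges(seqlevels(part),
                                           IRanges(1, sl[seqlevels(part)])))))
    stop("partition has gaps")
  invisible(TRUE)
}

same_partition_genome <- function(p1, p2) {
  identical(seqlengths(p1)[sort(seqlevels(p1))],
            seqlengths(p2)[sort(seqlevels(p2))])
}

#' Extract class or lamin coverage sets from a partition
#'
#' `class_set()` returns the merged coverage of one class label;
#' `lamin_set()` returns a lamin-level LAD set: lamin A = `A-B` union
#' `A-only`, lamin B = `A-B` union `B-only` (the sets a per-lamin ChIP
#' caller would produce).
#'
#' @param partition a class partition.
#' @param label one of `LAD_CLASSES`.
#' @param lamin `"A"` or `"B"`.
#' @return merged `GRanges`.
#' @export
class_set <- function(partition, label) {
  label <- match.arg(label, LAD_CLASSES)
  as_interval_set(partition[mcols(partition)$label == label])
}

#' @rdname class_set
#' @export
lamin_set <- function(partition, lamin = c("A", "B")) {
  lamin <- match.arg(lamin)
  own <- if (lamin == "A") "A-only" else "B-only"
  as_interval_set(c(class_set(partition, "A-B"),
                    class_set(partition, own)))
}

#' Base-pair fate matrix between two class partitions
#'
#' Entry (i, j) is the number of base pairs labeled class i in the control
#' partition and class j in the treated partition — the data behind an
#' alluvial fate diagram. Marginals reproduce the per-class coverages of
#' each partition and the grand total equals genome size.
#'
#' @param ctrl,trt class partitions on the same genome.
#' @return a `fate_matrix`: 4x4 numeric matrix (bp) with attribute
#'   `proportions` (rows renormalized to 1; `NaN` for empty classes).
#' @export
fate_matrix <- function(ctrl, trt) {
  validate_partition(ctrl); validate_partition(trt)
  if (!same_partition_genome(ctrl, trt))
    stop("partitions are defined on different genomes")
  m <- matrix(0, 4, 4, dimnames = list(control = LAD_CLASSES,
                                       treated = LAD_CLASSES))
  # both partitions tile the genome, so one overlap join gives every cell
  hits <- findOverlaps(ctrl, trt)
  w <- as.numeric(width(pintersect(ctrl[queryHits(hits)],
                                   trt[subjectHits(hits)])))
  li <- factor(mcols(ctrl)$label[queryHits(hits)], LAD_CLASSES)
  lj <- factor(mcols(trt)$label[subjectHits(hits)], LAD_CLASSES)
  agg <- tapply(w, list(li, lj), sum)
  m[!is.na(agg)] <- agg[!is.na(agg)]
  rs <- rowSums(m)
  attr(m, "proportions") <- sweep(m, 1, rs, "/")
  class(m) <- c("fate_matrix", class(m))
  m
}

#' @export
print.fate_matrix <- function(x, ...) {
  cat("<fate_matrix> base pairs (control rows -> treated columns)\n")
  print(unclass(x)[seq_len(4), seq_len(4)])
  invisible(x)
}

#' Long-format view of a fate matrix
#'
#' One row per (control class, treated class) flow with base pairs and
#' row proportions — the layout alluvial plotting tools consume.
#'
#' @param m a `fate_matrix`.
#' @return data frame with columns `control`, `treated`, `bp`, `proportion`.
#' @export
fate_long <- function(m) {
  pr <- attr(m, "proportions")
  df <- expand.grid(control = LAD_CLASSES, treated = LAD_CLASSES,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$bp <- as.numeric(unclass(m)[cbind(df$control, df$treated)])
  df$proportion <- as.numeric(pr[cbind(df$control, df$treated)])
  df[order(df$control, df$treated), , drop = FALSE]
}

#' Per-domain fate classification (majority-overlap view)
#'
#' A secondary, domain-weighted view of fate: each maximal run of a class
#' in the control partition is assigned the treated class covering at least
#' half of it; ties are resolved by the priority order `A-B` > `B-only` >
#' `A-only` > `iLAD`.
#'
#' @param ctrl,trt class partitions on the same genome.
#' @return data frame with one row per control-class run.
#' @export
domain_fates <- function(ctrl, trt) {
  validate_partition(ctrl); validate_partition(trt)
  if (!same_partition_genome(ctrl, trt))
    stop("partitions are defined on different genomes")
  priority <- c("A-B", "B-only", "A-only", "iLAD")
  rows <- list()
  for (i in LAD_CLASSES) {
    runs <- class_set(ctrl, i)
    if (!length(runs)) next
    ov <- vapply(seq_along(runs), function(k) {
      bp <- vapply(LAD_CLASSES, function(j) {
        gj <- class_set(trt, j)
        if (!length(gj)) return(0)
        sum(as.numeric(width(GenomicRanges::intersect(runs[k], gj))))
      }, numeric(1))
      best <- bp[priority]
      winners <- names(best)[best == max(best)]
      winners[1]
    }, character(1))
    rows[[i]] <- data.frame(chrom = as.character(seqnames(runs)),
                            start = start(runs) - 1, end = end(runs),
                            control = i, treated = ov)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Domain sizes per class
#'
#' Sizes (bp) of the maximal same-class runs of a partition, or widths of a
#' plain LAD interval set. Adjacent same-class runs are merged before
#' measuring, so a class run counts once.
#'
#' @param x a class partition or a `GRanges` LAD set.
#' @return for a partition, a named list of numeric vectors (one per
#'   class); for a `GRanges`, a numeric vector of widths.
#' @export
lad_sizes <- function(x) {
  if (!is.null(mcols(x)$label)) {
    out <- lapply(LAD_CLASSES, function(lbl) as.numeric(width(class_set(x, lbl))))
    names(out) <- LAD_CLASSES
    out
  } else {
    as.numeric(width(as_interval_set(x)))
  }
}

#' Two-way ANOVA with Tukey HSD on log domain sizes
#'
#' Compares LAD size distributions across classes and conditions: a two-way
#' ANOVA on log10 size with factors `class` and `condition` (plus
#' interaction when both factors vary), followed by Tukey's HSD post-hoc
#' test on all group pairs.
#'
#' @param groups named list of numeric size vectors (bp); names of the form
#'   `"<class>:<condition>"` (a missing `:` treats the whole name as the
#'   class with a single condition).
#' @return list with `anova` (the summary table), `tukey` (data frame of
#'   pairwise contrasts on `class:condition` groups) and `n` per group.
#' @export
compare_sizes <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(lengths(groups) < 2))
    stop("each group needs >= 2 domains for the ANOVA")
  nm <- strsplit(names(groups), ":", fixed = TRUE)
  df <- data.frame(
    size = unlist(groups, use.names = FALSE),
    class = factor(rep(vapply(nm, `[[`, "", 1), lengths(groups))),
    condition = factor(rep(vapply(nm, function(x)
      if (length(x) > 1) x[[2]] else "all", character(1)), lengths(groups))))
  df$logsize <- log10(df$size)
  two_way <- nlevels(df$class) > 1 && nlevels(df$condition) > 1
  form <- if (two_way) logsize ~ class * condition else
    if (nlevels(df$class) > 1) logsize ~ class else logsize ~ condition
  fit <- stats::aov(form, data = df)
  df$group <- factor(paste(df$class, df$condition, sep = ":"))
  fit_groups <- stats::aov(logsize ~ group, data = df)
  tk <- stats::TukeyHSD(fit_groups)$group
  tukey <- data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                      p_adj = tk[, "p adj"], row.names = NULL)
  list(anova = summary(fit), tukey = tukey,
       n = vapply(groups, length, integer(1)))
}

#' Coverage summary of a class partition
#'
#' Base pairs, genome fraction and number of maximal runs per class;
#' fractions sum to 1 over the four labels.
#'
#' @param partition a class partition.
#' @return data frame with one row per class.
#' @export
coverage_summary <- function(partition) {
  validate_partition(partition)
  gsize <- sum(as.numeric(seqlengths(partition)))
  rows <- lapply(LAD_CLASSES, function(lbl) {
    runs <- class_set(partition, lbl)
    bp <- sum(as.numeric(width(runs)))
    data.frame(class = lbl, bp = bp, fraction = bp / gsize,
               n_domains = length(runs))
  })
  do.call(rbind, rows)
}
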