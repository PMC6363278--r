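#' Assign genes to LAD classes by TSS overlap
#'
#' A gene belongs to the class whose run contains its transcription start
#' site. TSS coordinates are 0-based; with half-open runs, a TSS equal to a
#' run's end coordinate falls in the next run. For minus-strand genes the
#' TSS is the annotated interval end minus one (BED convention) — callers
#' supply the `tss` column already resolved.
#'
#' @param genes data frame with `gene_id`, `chrom`, `tss` (0-based bp).
#' @param partition a class partition.
#' @return character vector of class labels, one per gene.
#' @export
assign_genes <- function(genes, partition) {
  validate_partition(partition)
  sl <- seqlengths(partition)
  bad <- !(genes$chrom %in% seqlevels(partition)) |
    genes$tss < 0 | genes$tss >= sl[genes$chrom]
  if (any(bad))
    stop("TSS outside the genome for gene(s): ",
         paste(utils::head(genes$gene_id[bad], 5), collapse = ", "))
  q <- GRanges(genes$chrom, IRanges(genes$tss + 1, genes$tss + 1))
  hits <- findOverlaps(q, partition, select = "first")
  as.character(mcols(partition)$label[hits])
}

#' Resolve TSS coordinates from BED-like gene intervals
#'
#' @param chrom,start,end 0-based half-open gene intervals.
#' @param strand `"+"` or `"-"`; minus-strand TSS = `end - 1`.
#' @return 0-based TSS positions.
#' @export
tss_from_interval <- function(chrom, start, end, strand) {
  ifelse(strand == "-", end - 1, start)
}

#' Stable-expression filter
#'
#' Flags genes whose absolute FPKM change between conditions is strictly
#' below `threshold` (default 0.05 FPKM) as stably expressed.
#'
#' @param genes data frame with `FPKM_control` and `FPKM_treated`.
#' @param threshold strict cutoff on `|FPKM_treated - FPKM_control|`.
#' @return logical vector, `TRUE` = stable.
#' @export
stable_filter <- function(genes, threshold = 0.05) {
  if (any(is.na(genes$FPKM_control)) || any(is.na(genes$FPKM_treated)))
    stop("both FPKM columns must be present and non-missing")
  abs(genes$FPKM_treated - genes$FPKM_control) < threshold
}

#' Two-group expression comparison
#'
#' Welch's unequal-variance t-test for unpaired groups (the default; set
#' `var_equal = TRUE` for the classical pooled test) or the classical
#' paired t-test, two-sided. `NA` values are removed before testing and
#' reported group sizes reflect that.
#'
#' @param x,y numeric FPKM vectors.
#' @param paired paired test (`x` and `y` aligned per gene)?
#' @param var_equal pool variances in the unpaired test?
#' @return list with `t`, `p`, `n1`, `n2`, `mean1`, `mean2`.
#' @export
compare_groups <- function(x, y, paired = FALSE, var_equal = FALSE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  min_n <- if (paired) 2 else 2
  if (length(x) < min_n || length(y) < min_n)
    stop("need at least 2 observations per group")
  res <- tryCatch(
    stats::t.test(x, y, paired = paired, var.equal = var_equal),
    error = function(e)
      stop("degenerate input for t-test: ", conditionMessage(e),
           call. = FALSE))
  list(t = unname(res$statistic), p = res$p.value,
       n1 = length(x), n2 = length(y),
       mean1 = mean(x), mean2 = mean(y))
}

#' Expression report over LAD fate cells
#'
#' Groups genes by their (control class, treated class) fate at the TSS and
#' compares treated versus control FPKM within each cell with an unpaired
#' t-test (Welch by default). Cells with fewer than 2 genes, or with
#' degenerate (constant, identical) FPKMs, are reported without a test.
#' An optional Benjamini-Hochberg adjusted column can be added; it is off
#' by default since the convention is to read raw P against `alpha`.
#'
#' @param genes data frame with `gene_id`, `chrom`, `tss`, `FPKM_control`,
#'   `FPKM_treated`.
#' @param ctrl,trt class partitions on the same genome.
#' @param alpha significance convention echoed in the `significant` column
#'   (default 0.01).
#' @param var_equal pool variances?
#' @param adjust add BH-adjusted p-values?
#' @return data frame with one row per fate cell (16 rows).
#' @export
fate_expression_report <- function(genes, ctrl, trt, alpha = 0.01,
                                   var_equal = FALSE, adjust = FALSE) {
  if (!same_partition_genome(ctrl, trt))
    stop("partitions are defined on different genomes")
  cls_c <- assign_genes(genes, ctrl)
  cls_t <- assign_genes(genes, trt)
  rows <- list()
  for (i in LAD_CLASSES) {
    for (j in LAD_CLASSES) {
      sel <- genes[cls_c == i & cls_t == j, , drop = FALSE]
      n <- nrow(sel)
      t_val <- NA_real_; p_val <- NA_real_
      if (n >= 2) {
        ok <- tryCatch({
          res <- stats::t.test(sel$FPKM_treated, sel$FPKM_control,
                               var.equal = var_equal)
          t_val <- unname(res$statistic); p_val <- res$p.value
          TRUE
        }, error = function(e) FALSE)
        if (!ok) { t_val <- NA_real_; p_val <- NA_real_ }
      }
      rows[[paste(i, j)]] <- data.frame(
        class_control = i, class_treated = j, n = n,
        mean_fpkm_control = if (n) mean(sel$FPKM_control) else NA_real_,
        mean_fpkm_treated = if (n) mean(sel$FPKM_treated) else NA_real_,
        median_fpkm_control = if (n) stats::median(sel$FPKM_control) else NA_real_,
        median_fpkm_treated = if (n) stats::median(sel$FPKM_treated) else NA_real_,
        t = t_val, p = p_val)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (adjust) out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out$significant <- !is.na(out$p) & out$p < alpha
  out
}
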