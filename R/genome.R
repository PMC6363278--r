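#' @importFrom GenomicRanges GRanges reduce intersect union setdiff width
#'   seqnames start end findOverlaps pintersect tileGenome sort
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
#' @importFrom GenomeInfoDb seqlengths seqlevels seqinfo Seqinfo
#'   seqlengths<- seqlevels<-
NULL

#' LAD class labels
#'
#' The four genome labels used throughout: regions bound by both lamins
#' (`A-B`), by lamin A only (`A-only`), by lamin B only (`B-only`), and
#' inter-LAD regions bound by neither (`iLAD`).
#'
#' @export
LAD_CLASSES <- c("A-B", "A-only", "B-only", "iLAD")

#' Define a (toy) genome
#'
#' A genome is a set of named chromosomes with lengths and a fixed analysis
#' bin size. All binned tracks, planted domains and partitions in this
#' package refer to such a genome. Defaults give a desk-scale stand-in for a
#' mammalian genome: 4 chromosomes of 30 Mb at 10 kb bins, large enough to
#' host LADs in the ~0.5-15 Mb range.
#'
#' @param chromosomes named integer vector of chromosome lengths in bp.
#' @param bin_size analysis bin size in bp; every length must be divisible
#'   by it.
#' @return An object of class `lad_genome`.
#' @examples
#' g <- lad_genome()
#' genome_size(g)
#' @export
lad_genome <- function(chromosomes = c(chr1 = 3e7, chr2 = 3e7,
                                       chr3 = 3e7, chr4 = 3e7),
                       bin_size = 1e4) {
  chromosomes <- round(chromosomes)
  if (is.null(names(chromosomes)) || anyDuplicated(names(chromosomes)) ||
      any(!nzchar(names(chromosomes))))
    stop("chromosome names must be unique and non-empty")
  if (any(chromosomes <= 0)) stop("chromosome lengths must be > 0")
  if (bin_size <= 0) stop("bin_size must be > 0")
  if (any(chromosomes %% bin_size != 0))
    stop("chromosome lengths must be divisible by bin_size")
  structure(list(seqlengths = chromosomes, bin_size = bin_size),
            class = "lad_genome")
}

#' @rdname lad_genome
#' @param genome a `lad_genome`.
#' @export
genome_size <- function(genome) sum(genome$seqlengths)

#' @export
print.lad_genome <- function(x, ...) {
  cat(sprintf("<lad_genome> %d chromosome(s), %.1f Mb total, %d bp bins\n",
              length(x$seqlengths), sum(x$seqlengths) / 1e6, x$bin_size))
  invisible(x)
}

genome_seqinfo <- function(genome) {
  Seqinfo(seqnames = names(genome$seqlengths),
          seqlengths = unname(genome$seqlengths))
}

n_bins <- function(genome) {
  nb <- genome$seqlengths %/% genome$bin_size
  stats::setNames(as.integer(nb), names(genome$seqlengths))
}

#' Build a merged genomic interval set
#'
#' Interval sets (LAD sets, coverage sets) are represented as sorted, merged
#' `GRanges` in 0-based half-open (BED) coordinates externally; internally
#' `GRanges` uses 1-based closed coordinates, and all readers/writers of this
#' package convert at the boundary.
#'
#' @param chrom,start,end vectors describing intervals; `start`/`end` are
#'   0-based half-open.
#' @param genome optional `lad_genome` to attach seqlengths (enables bound
#'   checks downstream).
#' @return merged, sorted `GRanges`.
#' @examples
#' interval_set("chr1", 0, 100)
#' @export
interval_set <- function(chrom, start, end, genome = NULL) {
  if (any(end <= start)) stop("intervals must satisfy end > start")
  gr <- GRanges(chrom, IRanges(start + 1, end))
  if (!is.null(genome)) {
    gr <- bind_genome(gr, genome)
    check_within_genome(gr, genome)
  }
  as_interval_set(gr)
}

#' @rdname interval_set
#' @param gr a `GRanges`.
#' @export
as_interval_set <- function(gr) {
  GenomicRanges::sort(reduce(gr))
}

bind_genome <- function(gr, genome) {
  si <- genome_seqinfo(genome)
  seqlevels(gr) <- seqlevels(si)
  # out-of-bound ranges surface as errors via check_within_genome(), not
  # as GRanges warnings
  suppressWarnings(seqlengths(gr) <- seqlengths(si))
  gr
}

check_within_genome <- function(gr, genome, what = "intervals") {
  sl <- genome$seqlengths
  bad_chr <- setdiff(as.character(unique(seqnames(gr))), names(sl))
  if (length(bad_chr))
    stop(sprintf("%s on unknown chromosome(s): %s", what,
                 paste(bad_chr, collapse = ", ")))
  ends <- end(gr)
  lim <- sl[as.character(seqnames(gr))]
  if (any(ends > lim) || any(start(gr) < 1))
    stop(sprintf("%s extend beyond chromosome ends", what))
  invisible(TRUE)
}

#' Jaccard index of genome coverage
#'
#' The base-pair Jaccard index of two coverage sets: intersection size over
#' union size. A ratio of 1 indicates perfect overlap; 0 indicates disjoint
#' coverage. Inputs are merged before computation, so overlapping intervals
#' within one set are not double counted.
#'
#' @param set1,set2 `GRanges` coverage sets.
#' @return numeric scalar in `[0, 1]`.
#' @examples
#' a <- interval_set("chr1", 0, 100)
#' b <- interval_set("chr1", 50, 150)
#' jaccard(a, b)  # 50 / 150
#' @export
jaccard <- function(set1, set2) {
  # plain-vector kernel: the Jaccard property suites call this thousands
  # of times and per-call S4 set-algebra overhead dominates otherwise
  a <- list(chr = as.character(seqnames(set1)),
            s = start(set1), e = end(set1))
  b <- list(chr = as.character(seqnames(set2)),
            s = start(set2), e = end(set2))
  w1 <- w2 <- wi <- 0
  for (ch in union(a$chr, b$chr)) {
    ma <- merge_closed(a$s[a$chr == ch], a$e[a$chr == ch])
    mb <- merge_closed(b$s[b$chr == ch], b$e[b$chr == ch])
    w1 <- w1 + sum(ma$e - ma$s + 1)
    w2 <- w2 + sum(mb$e - mb$s + 1)
    if (length(ma$s) && length(mb$s)) {
      ov <- outer(ma$e, mb$e, pmin) - outer(ma$s, mb$s, pmax) + 1
      wi <- wi + sum(ov[ov > 0])
    }
  }
  uni <- w1 + w2 - wi
  if (uni == 0)
    stop("Jaccard index undefined: both sets are empty")
  wi / uni
}

# merge possibly overlapping 1-based closed intervals into disjoint runs
merge_closed <- function(s, e) {
  if (!length(s)) return(list(s = numeric(0), e = numeric(0)))
  ord <- order(s, e)
  s <- s[ord]; e <- e[ord]
  cm <- cummax(e)
  # bookended runs ([1,100][101,200]) merge, matching reduce() semantics
  new_run <- c(TRUE, s[-1] > cm[-length(cm)] + 1)
  idx <- which(new_run)
  list(s = s[idx], e = cm[c(idx[-1] - 1, length(e))])
}
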