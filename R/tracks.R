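#' Binned count and log-ratio tracks
#'
#' A `count_track` holds non-negative integer read counts per fixed-size bin
#' per chromosome; a `ratio_track` holds real-valued log2(ChIP/input) bin
#' values with `NA` marking masked bins (no usable input signal). Both are
#' light list structures (`bin_size`, `seqlengths`, named list `values`)
#' so that the domain caller can work on plain numeric vectors. The last bin
#' of a chromosome may be partial when the length is not a multiple of the
#' bin size.
#'
#' @param values named list (one numeric vector per chromosome).
#' @param bin_size bin size in bp.
#' @param genome a `lad_genome`, or a named vector of chromosome lengths.
#' @return `count_track` / `ratio_track` object.
#' @name tracks
NULL

track_seqlengths <- function(genome) {
  if (inherits(genome, "lad_genome")) genome$seqlengths else genome
}

new_track <- function(values, bin_size, genome, class) {
  stopifnot(is.list(values))
  sl <- track_seqlengths(genome)
  if (!setequal(names(values), names(sl)))
    stop("track chromosomes do not match genome")
  values <- values[names(sl)]
  nb <- stats::setNames(as.integer(ceiling(sl / bin_size)), names(sl))
  for (ch in names(sl)) {
    if (length(values[[ch]]) != nb[[ch]])
      stop(sprintf("chromosome %s: expected %d bins, got %d",
                   ch, nb[[ch]], length(values[[ch]])))
  }
  structure(list(bin_size = bin_size, seqlengths = sl, values = values),
            class = class)
}

#' @rdname tracks
#' @export
count_track <- function(values, bin_size, genome) {
  values <- lapply(values, function(v) {
    if (any(is.na(v)) || any(v < 0)) stop("counts must be non-negative")
    as.integer(round(v))
  })
  new_track(values, bin_size, genome, c("count_track", "lad_track"))
}

#' @rdname tracks
#' @export
ratio_track <- function(values, bin_size, genome) {
  values <- lapply(values, function(v) {
    v <- as.numeric(v)
    if (any(!is.finite(v) & !is.na(v)))
      stop("ratio values must be finite or NA (masked)")
    v
  })
  new_track(values, bin_size, genome, c("ratio_track", "lad_track"))
}

#' @export
print.lad_track <- function(x, ...) {
  tot <- sum(vapply(x$values, length, 1L))
  cat(sprintf("<%s> %d chromosome(s), %d bins of %d bp\n",
              class(x)[1], length(x$values), tot, as.integer(x$bin_size)))
  invisible(x)
}

total_counts <- function(track) {
  vapply(track$values, function(v) sum(as.numeric(v)), numeric(1))
}

#' Match sequencing depth between ChIP and input tracks
#'
#' Equalizes ChIP and input read depth separately on every chromosome by
#' down-sampling the deeper track: on each chromosome the binned counts of
#' whichever track has more total reads are down-sampled without replacement
#' (multivariate hypergeometric draw, i.e. per-read sampling) until both
#' totals match exactly; the shallower track is returned unchanged.
#' Equal totals leave both tracks untouched, so the operation is idempotent.
#'
#' @param chip,input `count_track`s on the same genome and bin size.
#' @param seed integer seed for the down-sampling draw.
#' @return list with elements `chip` and `input`.
#' @export
match_depth <- function(chip, input, seed = 1L) {
  if (!identical(chip$seqlengths, input$seqlengths) ||
      chip$bin_size != input$bin_size)
    stop("chip and input tracks must share genome and bin size")
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  for (ch in names(chip$seqlengths)) {
    tc <- sum(as.numeric(chip$values[[ch]]))
    ti <- sum(as.numeric(input$values[[ch]]))
    if (tc > ti) {
      chip$values[[ch]] <- downsample_counts(chip$values[[ch]], ti)
    } else if (ti > tc) {
      input$values[[ch]] <- downsample_counts(input$values[[ch]], tc)
    }
  }
  list(chip = chip, input = input)
}

# exact down-sampling of binned counts to a fixed total: sequential
# conditional hypergeometric draws (equivalent to sampling `target` of the
# original reads uniformly without replacement)
downsample_counts <- function(counts, target) {
  total <- sum(as.numeric(counts))
  stopifnot(target <= total)
  remaining_pick <- target
  remaining_pool <- total
  out <- integer(length(counts))
  for (i in seq_along(counts)) {
    ni <- counts[[i]]
    if (remaining_pick <= 0 || ni == 0) {
      out[[i]] <- 0L
    } else {
      k <- stats::rhyper(1, ni, remaining_pool - ni, remaining_pick)
      out[[i]] <- as.integer(k)
      remaining_pick <- remaining_pick - k
    }
    remaining_pool <- remaining_pool - ni
  }
  out
}

#' Build a binned log2(ChIP/input) ratio track
#'
#' Computes, for every bin, `log2(chip / (input * T_chip / T_input))` where
#' `T_chip`/`T_input` are genome-wide totals: the input is normalized to the
#' ratio of total ChIP reads over total input reads, which makes the result
#' invariant to uniform depth rescaling of either track. Bins with zero
#' input (no denominator) are masked (`NA`); bins with zero ChIP but
#' positive input are also masked rather than set to `-Inf`, and masked bins
#' are treated as non-enriched by the domain caller.
#'
#' @param chip,input `count_track`s on the same genome.
#' @param bin_size output bin size (default: the tracks' native size, which
#'   is 1000 bp in the canonical workflow); if coarser than the native bin
#'   size, counts are summed into the larger bins first.
#' @return a `ratio_track`.
#' @export
build_ratio_track <- function(chip, input, bin_size = chip$bin_size) {
  if (!identical(chip$seqlengths, input$seqlengths) ||
      chip$bin_size != input$bin_size)
    stop("chip and input tracks must share genome and bin size")
  if (bin_size != chip$bin_size) {
    chip <- rebin_counts(chip, bin_size)
    input <- rebin_counts(input, bin_size)
  }
  t_chip <- sum(total_counts(chip))
  t_input <- sum(total_counts(input))
  if (t_input == 0) stop("input track has zero total counts")
  if (t_chip == 0) stop("chip track has zero total counts")
  sf <- t_chip / t_input
  vals <- lapply(names(chip$values), function(ch) {
    c_ <- as.numeric(chip$values[[ch]])
    i_ <- as.numeric(input$values[[ch]])
    v <- log2(c_ / (i_ * sf))
    v[i_ == 0 | c_ == 0] <- NA_real_
    v
  })
  names(vals) <- names(chip$values)
  ratio_track(vals, bin_size, chip$seqlengths)
}

# sum fine count bins into coarser bins (bin_size must be a multiple)
rebin_counts <- function(track, bin_size) {
  k <- bin_size / track$bin_size
  if (k != round(k)) stop("bin_size must be a multiple of the native bin size")
  k <- as.integer(k)
  vals <- lapply(track$values, function(v) {
    pad <- (k - length(v) %% k) %% k
    as.integer(colSums(matrix(c(v, rep(0L, pad)), nrow = k)))
  })
  count_track(vals, bin_size, track$seqlengths)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (!is.null(state))
    assign(".Random.seed", state, envir = globalenv())
}
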