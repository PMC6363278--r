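#' Interval and track file input/output
#'
#' Thin wrappers around `rtracklayer` for the plain-text formats used by the
#' pipeline. All BED-family coordinates on disk are 0-based half-open;
#' `GRanges` in memory are 1-based closed, and conversion happens here.
#'
#' @param file path.
#' @param gr a `GRanges`.
#' @param merge merge overlapping/bookended intervals into a coverage set on
#'   read (the representation LAD consumers require).
#' @param genome optional `lad_genome` for bound checks / seqlengths.
#' @name lad_io
NULL

# locate the first malformed line so parse errors are actionable
first_bad_line <- function(file, min_fields = 3) {
  lines <- readLines(file, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(trimws(ln)) || startsWith(ln, "#") ||
        startsWith(ln, "track") || startsWith(ln, "browser")) next
    f <- strsplit(ln, "\t| +")[[1]]
    if (length(f) < min_fields ||
        is.na(suppressWarnings(as.numeric(f[2]))) ||
        is.na(suppressWarnings(as.numeric(f[3]))))
      return(i)
  }
  NA_integer_
}

#' @rdname lad_io
#' @export
read_bed <- function(file, genome = NULL, merge = TRUE) {
  if (length(readLines(file, warn = FALSE)) == 0)
    return(GRanges())
  gr <- tryCatch(rtracklayer::import(file, format = "BED"),
                 error = function(e) {
                   bad <- first_bad_line(file)
                   stop(sprintf("BED parse error in %s at line %s: %s",
                                file, ifelse(is.na(bad), "?", bad),
                                conditionMessage(e)), call. = FALSE)
                 })
  gr <- GRanges(seqnames(gr), IRanges::ranges(gr))
  if (!is.null(genome)) {
    gr <- bind_genome(gr, genome)
    check_within_genome(gr, genome, "BED intervals")
  }
  if (merge) as_interval_set(gr) else GenomicRanges::sort(gr)
}

#' @rdname lad_io
#' @export
write_bed <- function(gr, file) {
  rtracklayer::export(gr, file, format = "BED")
  invisible(file)
}

#' @rdname lad_io
#' @param track a `count_track` or `ratio_track` (masked bins are omitted
#'   from the file and come back as `NA` on read).
#' @export
write_bedgraph <- function(track, file) {
  chroms <- character(0); starts <- numeric(0); ends <- numeric(0)
  vals <- numeric(0)
  for (ch in names(track$values)) {
    v <- track$values[[ch]]
    keep <- which(!is.na(v))
    if (!length(keep)) next
    chroms <- c(chroms, rep(ch, length(keep)))
    starts <- c(starts, (keep - 1) * track$bin_size + 1)
    ends <- c(ends, pmin(keep * track$bin_size, track$seqlengths[[ch]]))
    vals <- c(vals, as.numeric(v[keep]))
  }
  gr <- GRanges(factor(chroms, levels = names(track$seqlengths)),
                IRanges(starts, ends), score = vals)
  rtracklayer::export(gr, file, format = "bedGraph")
  invisible(file)
}

#' @rdname lad_io
#' @param bin_size bin size of the track stored in the file.
#' @param integer_counts read values as integer counts (`count_track`)
#'   instead of a `ratio_track`.
#' @export
read_bedgraph <- function(file, genome, bin_size = genome$bin_size,
                          integer_counts = FALSE) {
  sl <- track_seqlengths(genome)
  empty <- length(readLines(file, warn = FALSE)) == 0
  gr <- if (empty) GRanges() else
    tryCatch(rtracklayer::import(file, format = "bedGraph"),
             error = function(e) {
               bad <- first_bad_line(file, min_fields = 4)
               stop(sprintf("bedGraph parse error in %s at line %s: %s",
                            file, ifelse(is.na(bad), "?", bad),
                            conditionMessage(e)), call. = FALSE)
             })
  vals <- lapply(names(sl), function(ch) {
    n <- as.integer(ceiling(sl[[ch]] / bin_size))
    v <- rep(NA_real_, n)
    sel <- gr[seqnames(gr) == ch]
    if (length(sel)) {
      for (k in seq_along(sel)) {
        i0 <- (start(sel)[k] - 1) %/% bin_size + 1
        i1 <- (end(sel)[k] - 1) %/% bin_size + 1
        v[i0:i1] <- sel$score[k]
      }
    }
    v
  })
  names(vals) <- names(sl)
  if (integer_counts) {
    vals <- lapply(vals, function(v) { v[is.na(v)] <- 0; v })
    count_track(vals, bin_size, sl)
  } else {
    ratio_track(vals, bin_size, sl)
  }
}

#' @rdname lad_io
#' @details `write_gtrack()`/`read_gtrack()` handle a minimal GTrack-like
#'   tabular dialect (tab-separated `seqid  start  end  value` with a
#'   `##gtrack` header, 0-based half-open) used for value-annotated
#'   segments.
#' @param df data frame with columns `seqid`, `start`, `end`, `value`.
#' @export
write_gtrack <- function(df, file) {
  stopifnot(all(c("seqid", "start", "end", "value") %in% names(df)))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("##gtrack version: 1.0",
               "###seqid\tstart\tend\tvalue"), con)
  utils::write.table(df[, c("seqid", "start", "end", "value")], con,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(file)
}

#' @rdname lad_io
#' @export
read_gtrack <- function(file) {
  lines <- readLines(file, warn = FALSE)
  body <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  if (!length(body))
    return(data.frame(seqid = character(), start = numeric(),
                      end = numeric(), value = numeric()))
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 4))
    stop(sprintf("GTrack parse error in %s at line %d: expected 4 fields",
                 file, body[which(nf != 4)[1]]))
  df <- data.frame(
    seqid = vapply(fields, `[[`, "", 1),
    start = as.numeric(vapply(fields, `[[`, "", 2)),
    end = as.numeric(vapply(fields, `[[`, "", 3)),
    value = as.numeric(vapply(fields, `[[`, "", 4)))
  if (any(is.na(df$start)) || any(is.na(df$end)))
    stop(sprintf("GTrack parse error in %s at line %d: non-numeric coordinate",
                 file, body[which(is.na(df$start) | is.na(df$end))[1]]))
  df
}

#' Read bead markers from a CMM-like XML file
#'
#' Chrom3D-style model exports use a Chimera marker (CMM) XML dialect: a
#' `marker_set` element holding `marker` elements with `x`, `y`, `z` and
#' `radius` attributes (micrometers). Chromosome/interval annotation, when
#' present, is carried in `chrID`, `beadStart` and `beadEnd` attributes.
#'
#' @param file path to the XML file.
#' @return data frame with one row per marker.
#' @export
read_cmm <- function(file) {
  doc <- xml2::read_xml(file)
  markers <- xml2::xml_find_all(doc, ".//marker")
  if (!length(markers)) stop("no <marker> elements found in ", file)
  num_attr <- function(a) as.numeric(xml2::xml_attr(markers, a))
  chr_attr <- xml2::xml_attr(markers, "chrID")
  data.frame(
    bead = seq_along(markers),
    chrom = ifelse(is.na(chr_attr), "unknown", chr_attr),
    start = ifelse(is.na(num_attr("beadStart")), NA_real_, num_attr("beadStart")),
    end = ifelse(is.na(num_attr("beadEnd")), NA_real_, num_attr("beadEnd")),
    x = num_attr("x"), y = num_attr("y"), z = num_attr("z"),
    radius = num_attr("radius"))
}
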