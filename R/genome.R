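#' Define a genome layout
#'
#' A genome layout is the ordered set of chromosome names and lengths against
#' which all interval sets, tracks and contact matrices are validated.
#'
#' @param lengths Named numeric vector of chromosome lengths in bp. Names must
#'   be unique, lengths strictly positive.
#' @return An object of class `genome_layout` (a named numeric vector).
#' @examples
#' genome_layout(c(chr1 = 1e6, chr2 = 5e5))
#' @export
genome_layout <- function(lengths) {
  if (is.null(names(lengths)) || anyNA(names(lengths)) ||
      any(names(lengths) == ""))
    stop("chromosome lengths must be named")
  if (anyDuplicated(names(lengths)))
    stop("duplicate chromosome names")
  lengths <- stats::setNames(as.numeric(lengths), names(lengths))
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("chromosome lengths must be positive and finite")
  structure(lengths, class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("<genome_layout> ", length(x), " chromosomes, ",
      format(sum(x), big.mark = ","), " bp total\n", sep = "")
  invisible(x)
}

#' Construct a validated interval set
#'
#' Intervals are plain data frames in 0-based half-open coordinates
#' (`start` inclusive, `end` exclusive), the BED convention.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer-like coordinates, `0 <= start < end`.
#' @param id Optional interval identifiers (unique if supplied).
#' @param strand Optional strand, one of `"+", "-", "."`.
#' @param layout Optional [genome_layout()] to validate chromosome names and
#'   bounds against.
#' @return A data frame with columns `chrom`, `start`, `end` and, when
#'   supplied, `id` and `strand`.
#' @export
intervals <- function(chrom, start, end, id = NULL, strand = NULL,
                      layout = NULL) {
  x <- data.frame(chrom = as.character(chrom),
                  start = as.numeric(start), end = as.numeric(end),
                  stringsAsFactors = FALSE)
  if (!is.null(id)) x$id <- as.character(id)
  if (!is.null(strand)) x$strand <- as.character(strand)
  validate_intervals(x, layout)
}

#' Validate an interval data frame
#'
#' @param x Data frame with at least `chrom`, `start`, `end`.
#' @param layout Optional [genome_layout()].
#' @return `x`, invisibly unchanged, or an error.
#' @export
validate_intervals <- function(x, layout = NULL) {
  req <- c("chrom", "start", "end")
  if (!all(req %in% names(x)))
    stop("interval set must have columns chrom, start, end")
  if (nrow(x)) {
    if (any(!is.finite(x$start)) || any(!is.finite(x$end)))
      stop("non-finite coordinates")
    if (any(x$start < 0)) stop("negative start coordinate")
    if (any(x$start >= x$end))
      stop("invalid interval: start >= end (0-based half-open expected)")
    if (!is.null(strand <- x$strand))
      if (!all(strand %in% c("+", "-", ".")))
        stop("strand must be one of '+', '-', '.'")
    if (!is.null(layout)) {
      bad <- setdiff(unique(x$chrom), names(layout))
      if (length(bad))
        stop("chromosomes absent from layout: ", paste(bad, collapse = ", "))
      lim <- unclass(layout)[x$chrom]
      if (any(x$end > lim)) stop("interval beyond chromosome end")
    }
  }
  x
}

# interval data.frame (0-based half-open) -> GRanges (1-based closed)
.as_gr <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = if (!is.null(x$strand)) x$strand else "*")
}

#' Construct a binned 1D signal track
#'
#' Holds one chromosome's binned values (e.g. compartment PC1 or insulation
#' score). Bin `i` covers `[start_offset + (i-1)*bin_size,
#' start_offset + i*bin_size)`. Missing values are `NA`, never zero.
#'
#' @param chrom Chromosome name.
#' @param bin_size Bin width in bp, > 0.
#' @param values Numeric vector of per-bin values (`NA` allowed).
#' @param start_offset Genomic position of the first bin start (bp).
#' @return An object of class `signal_track`.
#' @export
signal_track <- function(chrom, bin_size, values, start_offset = 0) {
  stopifnot(length(chrom) == 1L, bin_size > 0, start_offset >= 0)
  structure(list(chrom = as.character(chrom), bin_size = as.numeric(bin_size),
                 start_offset = as.numeric(start_offset),
                 values = as.numeric(values)),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat("<signal_track> ", x$chrom, ": ", length(x$values), " bins of ",
      x$bin_size, " bp (", sum(is.na(x$values)), " missing)\n", sep = "")
  invisible(x)
}

# bin index of a genomic position on a track (NA when off-track)
.track_bin <- function(track, pos) {
  i <- floor((pos - track$start_offset) / track$bin_size) + 1
  i[i < 1 | i > length(track$values)] <- NA_real_
  as.integer(i)
}

# track value at genomic positions; NA off-track or when chrom mismatches
track_value_at <- function(track, chrom, pos) {
  v <- rep(NA_real_, length(pos))
  on <- chrom == track$chrom
  i <- .track_bin(track, pos[on])
  v[on][!is.na(i)] <- track$values[i[!is.na(i)]]
  v
}

#' Construct a dense Hi-C contact matrix
#'
#' @param chrom Chromosome name.
#' @param start_bp Genomic start of the matrix span (bp, 0-based).
#' @param resolution Bin size in bp.
#' @param mat Square, symmetric, non-negative numeric matrix.
#' @return An object of class `contact_matrix`.
#' @export
contact_matrix <- function(chrom, start_bp, resolution, mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) stop("contact matrix must be square")
  if (any(mat < 0, na.rm = TRUE)) stop("contact matrix must be non-negative")
  if (max(abs(mat - t(mat)), na.rm = TRUE) > 1e-9)
    stop("contact matrix must be symmetric")
  structure(list(chrom = as.character(chrom), start_bp = as.numeric(start_bp),
                 resolution = as.numeric(resolution), mat = mat),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("<contact_matrix> ", x$chrom, ":", format(x$start_bp, big.mark = ","),
      "-", format(x$start_bp + nrow(x$mat) * x$resolution, big.mark = ","),
      " @ ", x$resolution, " bp (", nrow(x$mat), " bins)\n", sep = "")
  invisible(x)
}
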