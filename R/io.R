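# Plain-text genomic format I/O. All BED-family files are 0-based half-open;
# all readers fail with the offending line number, all writers order rows by
# (chrom, start) so write-then-read round trips are stable.

.read_lines_fields <- function(path, min_fields, what) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (!length(lines)) return(list(fields = list(), lineno = integer()))
  fields <- strsplit(lines, "[ \t]+")
  n <- lengths(fields)
  if (any(n < min_fields))
    stop(sprintf("%s parse error at line %d: expected >= %d fields, got %d",
                 what, which(n < min_fields)[1], min_fields,
                 n[which(n < min_fields)[1]]))
  list(fields = fields, lineno = seq_along(lines))
}

.num_or_stop <- function(x, what, lineno) {
  v <- suppressWarnings(as.numeric(x))
  if (anyNA(v))
    stop(sprintf("%s parse error at line %d: non-numeric coordinate",
                 what, lineno[which(is.na(v))[1]]))
  v
}

#' Read a BED file
#'
#' Supports BED3-BED6. Columns beyond the sixth are ignored.
#'
#' @param path Path to a plain-text BED file.
#' @param layout Optional [genome_layout()] for validation.
#' @return Interval data frame (0-based half-open), sorted by (chrom, start),
#'   with `id`, `score`, `strand` columns when present in the file.
#' @export
read_bed <- function(path, layout = NULL) {
  p <- .read_lines_fields(path, 3L, "BED")
  if (!length(p$fields))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric()))
  get <- function(i) vapply(p$fields, function(f)
    if (length(f) >= i) f[i] else NA_character_, "")
  x <- data.frame(chrom = get(1),
                  start = .num_or_stop(get(2), "BED", p$lineno),
                  end = .num_or_stop(get(3), "BED", p$lineno),
                  stringsAsFactors = FALSE)
  if (any(x$start >= x$end))
    stop(sprintf("BED validation error at line %d: start >= end",
                 p$lineno[which(x$start >= x$end)[1]]))
  id <- get(4); if (!all(is.na(id))) x$id <- id
  sc <- get(5); if (!all(is.na(sc))) x$score <- suppressWarnings(as.numeric(sc))
  st <- get(6); if (!all(is.na(st))) x$strand <- st
  x <- x[order(x$chrom, x$start), , drop = FALSE]
  rownames(x) <- NULL
  validate_intervals(x, layout)
}

#' Write a BED file
#'
#' @param x Interval data frame; optional `id`, `score`, `strand` columns are
#'   written as BED columns 4-6.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  x <- validate_intervals(x)
  x <- x[order(x$chrom, x$start), , drop = FALSE]
  cols <- list(x$chrom, format(x$start, scientific = FALSE, trim = TRUE),
               format(x$end, scientific = FALSE, trim = TRUE))
  if (!is.null(x$id) || !is.null(x$score) || !is.null(x$strand))
    cols <- c(cols, list(if (is.null(x$id)) rep(".", nrow(x)) else x$id))
  if (!is.null(x$score) || !is.null(x$strand))
    cols <- c(cols, list(if (is.null(x$score)) rep(0, nrow(x)) else x$score))
  if (!is.null(x$strand)) cols <- c(cols, list(x$strand))
  utils::write.table(do.call(cbind, lapply(cols, as.character)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a BEDPE loop file
#'
#' @param path Path to a BEDPE file (two anchors, optional name/score).
#' @return Data frame with columns `chrom1,start1,end1,chrom2,start2,end2`
#'   plus `id` and `score` when present.
#' @export
read_bedpe <- function(path) {
  p <- .read_lines_fields(path, 6L, "BEDPE")
  if (!length(p$fields))
    return(data.frame(chrom1 = character(), start1 = numeric(),
                      end1 = numeric(), chrom2 = character(),
                      start2 = numeric(), end2 = numeric()))
  get <- function(i) vapply(p$fields, function(f)
    if (length(f) >= i) f[i] else NA_character_, "")
  x <- data.frame(chrom1 = get(1),
                  start1 = .num_or_stop(get(2), "BEDPE", p$lineno),
                  end1 = .num_or_stop(get(3), "BEDPE", p$lineno),
                  chrom2 = get(4),
                  start2 = .num_or_stop(get(5), "BEDPE", p$lineno),
                  end2 = .num_or_stop(get(6), "BEDPE", p$lineno),
                  stringsAsFactors = FALSE)
  bad <- x$start1 >= x$end1 | x$start2 >= x$end2
  if (any(bad))
    stop(sprintf("BEDPE validation error at line %d: start >= end",
                 p$lineno[which(bad)[1]]))
  id <- get(7); if (!all(is.na(id))) x$id <- id
  sc <- get(8); if (!all(is.na(sc))) x$score <- suppressWarnings(as.numeric(sc))
  x <- x[order(x$chrom1, x$start1, x$start2), , drop = FALSE]
  rownames(x) <- NULL
  x
}

#' Write a BEDPE loop file
#'
#' @param x Loop data frame as returned by [read_bedpe()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(x, path) {
  x <- x[order(x$chrom1, x$start1, x$start2), , drop = FALSE]
  cols <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  out <- x[, cols]
  if (!is.null(x$id) || !is.null(x$score))
    out$id <- if (is.null(x$id)) "." else x$id
  if (!is.null(x$score)) out$score <- x$score
  for (cc in c("start1", "end1", "start2", "end2"))
    out[[cc]] <- format(out[[cc]], scientific = FALSE, trim = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph track
#'
#' All intervals must share one chromosome and lie on a regular bin grid;
#' uncovered bins become `NA`.
#'
#' @param path Path to a bedGraph file (`chrom start end value`).
#' @return A [signal_track()].
#' @export
read_bedgraph <- function(path) {
  p <- .read_lines_fields(path, 4L, "bedGraph")
  if (!length(p$fields)) stop("empty bedGraph")
  get <- function(i) vapply(p$fields, `[`, "", i)
  chrom <- unique(get(1))
  if (length(chrom) > 1)
    stop("bedGraph track spans multiple chromosomes; one track per chromosome")
  start <- .num_or_stop(get(2), "bedGraph", p$lineno)
  end <- .num_or_stop(get(3), "bedGraph", p$lineno)
  val <- .num_or_stop(get(4), "bedGraph", p$lineno)
  bin <- unique(end - start)
  if (length(bin) > 1) stop("bedGraph bins are not of constant width")
  off <- min(start)
  if (any((start - off) %% bin != 0)) stop("bedGraph bins are off-grid")
  n <- (max(end) - off) / bin
  values <- rep(NA_real_, n)
  values[(start - off) / bin + 1] <- val
  signal_track(chrom, bin, values, start_offset = off)
}

#' Write a bedGraph track
#'
#' Missing bins are omitted from the file (bedGraph has no NA encoding).
#'
#' @param track A [signal_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  i <- which(!is.na(track$values))
  start <- track$start_offset + (i - 1) * track$bin_size
  out <- cbind(track$chrom,
               format(start, scientific = FALSE, trim = TRUE),
               format(start + track$bin_size, scientific = FALSE, trim = TRUE),
               format(track$values[i], digits = 10))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a dense contact matrix from triplet text
#'
#' Format: a first line `#{"chrom":...,"start_bp":...,"resolution":...,"n":...}`
#' followed by `bin_i bin_j value` triplets (1-based, upper triangle or full).
#'
#' @param path Input path.
#' @return A [contact_matrix()].
#' @export
read_contact_matrix <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "#"))
    stop("contact matrix file must start with a '#' JSON header line")
  hdr <- jsonlite::fromJSON(sub("^#", "", lines[1]))
  body <- lines[-1][nzchar(lines[-1])]
  f <- strsplit(body, "[ \t]+")
  if (any(lengths(f) < 3)) stop("contact matrix triplet with < 3 fields")
  i <- as.integer(vapply(f, `[`, "", 1))
  j <- as.integer(vapply(f, `[`, "", 2))
  v <- as.numeric(vapply(f, `[`, "", 3))
  n <- as.integer(hdr$n)
  m <- matrix(0, n, n)
  m[cbind(i, j)] <- v
  m[cbind(j, i)] <- v
  contact_matrix(hdr$chrom, hdr$start_bp, hdr$resolution, m)
}

#' Write a dense contact matrix as triplet text
#'
#' Only the non-zero upper triangle (including the diagonal) is written.
#'
#' @param m A [contact_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contact_matrix <- function(m, path) {
  hdr <- jsonlite::toJSON(list(chrom = m$chrom, start_bp = m$start_bp,
                               resolution = m$resolution, n = nrow(m$mat)),
                          auto_unbox = TRUE, digits = NA)
  idx <- which(upper.tri(m$mat, diag = TRUE) & m$mat != 0, arr.ind = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", hdr), con)
  if (nrow(idx))
    writeLines(paste(idx[, 1], idx[, 2],
                     format(m$mat[idx], digits = 10, trim = TRUE)), con)
  invisible(path)
}

#' Read a genome layout from a two-column TSV
#'
#' @param path Path to a `chrom length` TSV (no header).
#' @return A [genome_layout()].
#' @export
read_genome_layout <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  genome_layout(stats::setNames(as.numeric(x[[2]]), x[[1]]))
}

#' Write a genome layout as a two-column TSV
#'
#' @param layout A [genome_layout()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_layout <- function(layout, path) {
  utils::write.table(
    data.frame(names(layout), format(unclass(layout), scientific = FALSE,
                                     trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# header-carrying TSV helpers used for all tabular interchange
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
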