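## core_io: genomic file formats and the internal coordinate convention.
##
## Every coordinate exchanged between hmsplice functions is 0-based,
## half-open (BED convention). Conversion to 1-based inclusive coordinates
## is a display-only formatting step (`to_display_1based`).

#' Validate genomic intervals
#'
#' Checks the `0 <= start < end` invariant and the strand alphabet used
#' throughout the package.
#'
#' @param chrom,start,end,strand vectors of equal length (strand optional).
#' @param what label used in error messages.
#' @return invisibly `TRUE`; errors otherwise.
#' @keywords internal
check_intervals <- function(chrom, start, end, strand = NULL,
                            what = "interval") {
  bad <- which(!(start >= 0 & start < end))
  if (length(bad) > 0L) {
    stop(sprintf("invalid interval (%s): start >= end or start < 0 at row %d",
                 what, bad[1L]))
  }
  if (!is.null(strand)) {
    ok <- strand %in% c("+", "-")
    if (!all(ok)) {
      stop(sprintf("invalid strand '%s' (%s): must be '+' or '-'",
                   strand[which(!ok)[1L]], what))
    }
  }
  invisible(TRUE)
}

#' Convert internal 0-based half-open coordinates for display
#'
#' @param start,end integer vectors in the internal convention.
#' @return a data.frame with 1-based inclusive `start`, `end` columns, as a
#'   genome browser would print them.
#' @export
to_display_1based <- function(start, end) {
  data.frame(start = start + 1L, end = end)
}

read_lines_checked <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  # file() decompresses gzip transparently
  con <- file(path, open = "rt")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

split_fields <- function(lines) strsplit(lines, "\t", fixed = TRUE)

#' Read a BED file (3-6 columns)
#'
#' Parses a BED3-BED6 file into a data.frame of intervals with the internal
#' 0-based half-open convention. Rows lacking a strand column default to
#' `"+"` with a warning.
#'
#' @param path path to a BED file (plain or gzip).
#' @return data.frame with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path) {
  lines <- read_lines_checked(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      score = double(), strand = character()))
  }
  fields <- split_fields(lines)
  nf <- lengths(fields)
  if (any(nf < 3L | nf > 12L)) {
    idx <- which(nf < 3L | nf > 12L)[1L]
    stop(sprintf("malformed BED line %d: expected 3-6 fields, got %d",
                 idx, nf[idx]))
  }
  get_col <- function(i, default = NA_character_) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else default,
           character(1))
  }
  chrom <- get_col(1)
  start <- suppressWarnings(as.integer(get_col(2)))
  end <- suppressWarnings(as.integer(get_col(3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0L)
    stop(sprintf("malformed BED line %d: non-numeric coordinates", bad[1L]))
  if (any(start >= end))
    stop(sprintf("invalid interval at BED line %d: start >= end",
                 which(start >= end)[1L]))
  name <- get_col(4)
  score <- suppressWarnings(as.double(get_col(5)))
  strand <- get_col(6)
  missing_strand <- is.na(strand) | !(strand %in% c("+", "-"))
  if (any(missing_strand)) {
    warning(sprintf("%d BED row(s) without a valid strand; defaulting to '+'",
                    sum(missing_strand)))
    strand[missing_strand] <- "+"
  }
  out <- data.frame(chrom = chrom, start = start, end = end,
                    name = name, score = score, strand = strand)
  check_intervals(out$chrom, out$start, out$end, out$strand, what = "BED")
  out
}

#' Write intervals as BED6
#'
#' @param x data.frame with `chrom`, `start`, `end` and optionally `name`,
#'   `score`, `strand` columns.
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_bed <- function(x, path) {
  name <- if ("name" %in% names(x)) x$name else "."
  score <- if ("score" %in% names(x)) x$score else 0
  strand <- if ("strand" %in% names(x)) x$strand else "+"
  score <- ifelse(is.na(score), 0, score)
  lines <- paste(x$chrom, format_int(x$start), format_int(x$end),
                 name, format_num(score), strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read an ENCODE narrowPeak file
#'
#' Parses the 10-column narrowPeak dialect. The peak height is taken from
#' the `signalValue` column (column 7). A summit offset of `-1` (not called)
#' is replaced by the interval midpoint.
#'
#' @param path path to a narrowPeak file (plain or gzip).
#' @return data.frame with columns `chrom`, `start`, `end`, `name`,
#'   `summit_offset`, `signal`.
#' @export
read_narrowpeak <- function(path) {
  lines <- read_lines_checked(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      summit_offset = integer(), signal = double()))
  }
  fields <- split_fields(lines)
  nf <- lengths(fields)
  if (any(nf != 10L)) {
    stop(sprintf("malformed narrowPeak line %d: expected 10 columns, got %d",
                 which(nf != 10L)[1L], nf[which(nf != 10L)[1L]]))
  }
  m <- do.call(rbind, fields)
  start <- as.integer(m[, 2])
  end <- as.integer(m[, 3])
  if (any(is.na(start) | is.na(end) | start >= end))
    stop(sprintf("invalid interval at narrowPeak line %d",
                 which(is.na(start) | is.na(end) | start >= end)[1L]))
  signal <- as.double(m[, 7])
  if (any(is.na(signal) | signal < 0))
    stop(sprintf("invalid signalValue at narrowPeak line %d",
                 which(is.na(signal) | signal < 0)[1L]))
  summit <- as.integer(m[, 10])
  mid <- as.integer((end - start) %/% 2L)
  summit[summit < 0L] <- mid[summit < 0L]
  if (any(summit >= end - start))
    stop(sprintf("summit offset outside peak at narrowPeak line %d",
                 which(summit >= end - start)[1L]))
  data.frame(chrom = m[, 1], start = start, end = end, name = m[, 4],
             summit_offset = summit, signal = signal)
}

#' Write peaks in ENCODE narrowPeak format
#'
#' @param x data.frame with `chrom`, `start`, `end`, `summit_offset`,
#'   `signal` and optionally `name` columns.
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_narrowpeak <- function(x, path) {
  name <- if ("name" %in% names(x)) x$name else
    paste0("peak_", seq_len(nrow(x)))
  lines <- paste(x$chrom, format_int(x$start), format_int(x$end), name,
                 "0", ".", format_num(x$signal), "-1", "-1",
                 format_int(x$summit_offset), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph coverage track
#'
#' Builds a queryable per-base read-count track from a 4-column bedGraph.
#' Intervals must be non-overlapping (an overlap is treated as a generator
#' or upstream bug, not summed). Positions absent from the file have
#' coverage 0.
#'
#' @param path path to a bedGraph file (plain or gzip).
#' @param library_size total mapped reads of the originating library
#'   (positive; used for depth normalization downstream).
#' @return an object of class `coverage_track`.
#' @export
read_coverage <- function(path, library_size) {
  lines <- read_lines_checked(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (length(lines) == 0L) {
    return(coverage_track(data.frame(chrom = character(), start = integer(),
                                     end = integer(), value = double()),
                          library_size))
  }
  fields <- split_fields(lines)
  nf <- lengths(fields)
  if (any(nf != 4L))
    stop(sprintf("malformed bedGraph line %d: expected 4 columns",
                 which(nf != 4L)[1L]))
  m <- do.call(rbind, fields)
  df <- data.frame(chrom = m[, 1],
                   start = as.integer(m[, 2]),
                   end = as.integer(m[, 3]),
                   value = as.double(m[, 4]))
  if (anyNA(df$start) || anyNA(df$end) || anyNA(df$value))
    stop("malformed bedGraph: non-numeric field")
  if (any(df$value < 0))
    stop(sprintf("negative coverage value at bedGraph line %d",
                 which(df$value < 0)[1L]))
  coverage_track(df, library_size)
}

#' Construct a coverage track from an interval table
#'
#' @param df data.frame with `chrom`, `start`, `end`, `value` (per-base
#'   read count over the interval).
#' @param library_size positive total mapped reads.
#' @return `coverage_track` object: per-chromosome sorted interval tables
#'   plus a cumulative-reads index for O(log n) range-sum queries.
#' @export
coverage_track <- function(df, library_size) {
  stopifnot(is.numeric(library_size), length(library_size) == 1L,
            library_size > 0)
  check_intervals(df$chrom, df$start, df$end, what = "bedGraph")
  if (any(df$value < 0)) stop("negative coverage value")
  by_chrom <- split(df[c("start", "end", "value")], df$chrom)
  by_chrom <- lapply(by_chrom, function(d) {
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) > 1L && any(d$start[-1L] < d$end[-nrow(d)]))
      stop("overlapping coverage intervals")
    # cumulative reads strictly before each interval start
    d$cum <- c(0, cumsum(d$value * (d$end - d$start)))[seq_len(nrow(d))]
    d
  })
  structure(list(intervals = by_chrom, library_size = library_size),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  n <- sum(vapply(x$intervals, nrow, integer(1)))
  cat(sprintf("coverage_track: %d intervals on %d chromosome(s), library %g\n",
              n, length(x$intervals), x$library_size))
  invisible(x)
}

# Integral of the track on one chromosome up to positions `pos`
# (reads in [-Inf, pos)). Vectorized.
cov_integral <- function(d, pos) {
  if (nrow(d) == 0L) return(rep(0, length(pos)))
  idx <- findInterval(pos, d$start)
  out <- numeric(length(pos))
  hit <- idx > 0L
  if (any(hit)) {
    i <- idx[hit]
    inside <- pmin(pos[hit], d$end[i]) - d$start[i]
    inside[inside < 0] <- 0
    out[hit] <- d$cum[i] + d$value[i] * inside
  }
  out
}

#' Sum read counts over genomic ranges
#'
#' @param track a `coverage_track`.
#' @param chrom,start,end vectors describing query ranges (0-based
#'   half-open).
#' @return numeric vector of read counts (value x overlapped width, summed);
#'   0 for ranges outside the covered region.
#' @export
coverage_sum <- function(track, chrom, start, end) {
  stopifnot(inherits(track, "coverage_track"))
  if (any(end < start)) stop("coverage query with end < start")
  out <- numeric(length(start))
  for (ch in unique(chrom)) {
    d <- track$intervals[[ch]]
    sel <- chrom == ch
    if (is.null(d)) next
    out[sel] <- cov_integral(d, end[sel]) - cov_integral(d, start[sel])
  }
  out
}

#' Write a coverage track as bedGraph
#'
#' @param track a `coverage_track`.
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  chroms <- names(track$intervals)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (ch in chroms) {
    d <- track$intervals[[ch]]
    writeLines(paste(ch, format_int(d$start), format_int(d$end),
                     format_num(d$value), sep = "\t"), con)
  }
  invisible(path)
}

# Fixed-format numeric rendering so that write -> read round-trips
# bit-exactly at 6 decimal places.
format_num <- function(x) {
  out <- formatC(x, format = "f", digits = 6)
  sub("^(-?\\d+)\\.0{6}$", "\\1", out)
}
format_int <- function(x) formatC(x, format = "d")

#' Write an internal table as TSV
#'
#' All numeric columns are rendered with 6 fixed decimal places so that
#' [read_tsv()] reproduces them bit-exactly.
#'
#' @param x data.frame.
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_tsv <- function(x, path) {
  y <- x
  for (j in seq_along(y)) {
    if (is.double(y[[j]])) y[[j]] <- format_num(y[[j]])
  }
  write.table(y, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path input path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}
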