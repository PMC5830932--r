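# Genomic intervals are plain data frames with 0-based half-open coordinates
# (columns chrom, start, end and optionally name, score, strand, summit).
# GenomicRanges does the heavy interval lifting internally; the conversion
# adds 1 to `start` because IRanges is 1-based closed.

#' Construct a genomic-interval data frame
#'
#' @param chrom character chromosome names.
#' @param start,end 0-based half-open coordinates, `start < end`.
#' @param name,score,strand optional annotation columns.
#' @return a `data.frame` with one row per interval.
#' @export
genomic_intervals <- function(chrom, start, end, name = NA_character_,
                              score = NA_real_, strand = ".") {
  if (length(chrom) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), score = numeric(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), name = as.character(name),
                   score = as.numeric(score), strand = as.character(strand),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(df) {
  if (nrow(df) == 0L) return(invisible(df))
  if (any(is.na(df$chrom)) || any(!nzchar(df$chrom))) {
    stopf("interval validation: empty chrom name")
  }
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad)) {
    stopf("interval validation: start >= end (or start < 0) at row %d", bad[1])
  }
  invisible(df)
}

as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

granges_to_df <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

#' Read genomic intervals from a BED-family file
#'
#' Supports BED3, BED6, narrowPeak and bedGraph. Coordinates are kept
#' 0-based half-open, as in the files. For narrowPeak the summit is retained
#' as an absolute coordinate in a `summit` column (`start + peak offset`).
#'
#' @param path file path.
#' @param format one of `"BED3"`, `"BED6"`, `"narrowPeak"`, `"bedGraph"`.
#' @return interval data frame in file order.
#' @export
read_intervals <- function(path, format = c("BED3", "BED6", "narrowPeak",
                                            "bedGraph")) {
  format <- match.arg(format)
  ncols <- switch(format, BED3 = 3L, BED6 = 6L, narrowPeak = 10L,
                  bedGraph = 4L)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(genomic_intervals(character(), integer(), integer()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < ncols)
  if (length(bad)) {
    stopf("parse error in %s line %d: expected >= %d fields, got %d",
          path, bad[1], ncols, nf[bad[1]])
  }
  mat <- t(vapply(fields, function(f) f[seq_len(ncols)], character(ncols)))
  start <- suppressWarnings(as.integer(mat[, 2]))
  end <- suppressWarnings(as.integer(mat[, 3]))
  if (anyNA(start) || anyNA(end)) {
    stopf("parse error in %s line %d: non-numeric coordinate", path,
          which(is.na(start) | is.na(end))[1])
  }
  df <- data.frame(chrom = mat[, 1], start = start, end = end,
                   stringsAsFactors = FALSE)
  if (format %in% c("BED6", "narrowPeak")) {
    df$name <- mat[, 4]
    df$score <- suppressWarnings(as.numeric(mat[, 5]))
    df$strand <- mat[, 6]
  } else if (format == "bedGraph") {
    df$score <- suppressWarnings(as.numeric(mat[, 4]))
  }
  if (format == "narrowPeak") {
    offset <- suppressWarnings(as.integer(mat[, 10]))
    df$summit <- ifelse(!is.na(offset) & offset >= 0L, df$start + offset,
                        NA_integer_)
  }
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad)) {
    stopf("validation error in %s line %d: start >= end", path, bad[1])
  }
  df
}

#' Write intervals as BED6
#'
#' @param df interval data frame.
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  out <- data.frame(
    chrom = df$chrom, start = df$start, end = df$end,
    name = if ("name" %in% names(df)) ifelse(is.na(df$name), ".", df$name) else ".",
    score = if ("score" %in% names(df)) ifelse(is.na(df$score), 0, df$score) else 0,
    strand = if ("strand" %in% names(df)) ifelse(is.na(df$strand), ".", df$strand) else "."
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

# Midpoints of intervals (floor of the centre), 0-based.
interval_midpoint <- function(df) {
  as.integer(floor((df$start + df$end) / 2))
}

# For each query interval, does it share >= min_overlap_bp bases with any
# subject interval?
overlaps_any <- function(query, subject, min_overlap_bp = 1L) {
  if (nrow(query) == 0L) return(logical(0))
  if (nrow(subject) == 0L) return(rep(FALSE, nrow(query)))
  hits <- GenomicRanges::findOverlaps(as_granges(query), as_granges(subject),
                                      minoverlap = as.integer(min_overlap_bp))
  out <- rep(FALSE, nrow(query))
  out[unique(S4Vectors::queryHits(hits))] <- TRUE
  out
}

# Are the point positions (0-based) inside any interval of `subject`?
points_in_intervals <- function(chrom, pos, subject) {
  if (length(pos) == 0L) return(logical(0))
  if (nrow(subject) == 0L) return(rep(FALSE, length(pos)))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, width = 1L))
  hits <- GenomicRanges::findOverlaps(q, as_granges(subject))
  out <- rep(FALSE, length(pos))
  out[unique(S4Vectors::queryHits(hits))] <- TRUE
  out
}
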