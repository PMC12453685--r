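#' Read a BED3/BED4 file of genomic elements
#'
#' Parses a tab-separated BED file into a table of 0-based half-open
#' intervals. Lines starting with `#`, `track` or `browser` are skipped.
#'
#' @param path path to a BED file with at least three tab-separated columns.
#' @param named when `TRUE` (default) a 4th column, if present, becomes the
#'   `name` column.
#' @return a `data.table` with columns `chrom`, `start`, `end` and (when
#'   available) `name`, in file order. An empty file yields an empty table.
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200\tE1", f)
#' read_bed(f)
#' @export
read_bed <- function(path, named = TRUE) {
  if (!file.exists(path)) stop_usage("BED file not found: %s", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(data.table::data.table(chrom = character(), start = numeric(),
                                  end = numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop_data("BED parse error at line %d of %s: fewer than 3 columns",
              lineno[which(nf < 3L)[1]], path)
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- is.na(start) | is.na(end) | start < 0 | end <= start |
    !nzchar(chrom)
  if (any(bad)) {
    stop_data("BED parse error at line %d of %s: invalid interval",
              lineno[which(bad)[1]], path)
  }
  out <- data.table::data.table(chrom = chrom, start = start, end = end)
  if (named && any(nf >= 4L)) {
    out$name <- vapply(fields, function(f) if (length(f) >= 4L) f[[4L]]
                       else NA_character_, "")
  }
  out
}

#' Construct a table of genomic intervals
#'
#' @param chrom,start,end,name vectors defining 0-based half-open intervals.
#' @return a validated `data.table` of intervals.
#' @export
bed_intervals <- function(chrom, start, end, name = NULL) {
  out <- data.table::data.table(chrom = as.character(chrom),
                                start = as.numeric(start),
                                end = as.numeric(end))
  if (!is.null(name)) out$name <- as.character(name)
  if (nrow(out) > 0L) {
    if (any(!nzchar(out$chrom))) stop_usage("empty chromosome name")
    if (any(out$start < 0)) stop_usage("negative interval start")
    if (any(out$end <= out$start)) stop_usage("interval end must exceed start")
  }
  out
}

#' Write intervals as BED
#' @param x interval table from [read_bed()] or [bed_intervals()].
#' @param path output path (or `""` for stdout).
#' @export
write_bed <- function(x, path) {
  cols <- c("chrom", "start", "end", if ("name" %in% names(x)) "name")
  lines <- do.call(paste, c(lapply(cols, function(cl) {
    v <- x[[cl]]
    if (is.numeric(v)) format(v, scientific = FALSE, trim = TRUE) else v
  }), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
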