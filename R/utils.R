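# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_usage <- function(fmt, ...) {
  stop(structure(class = c("ps_usage_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = NULL)))
}

stop_data <- function(fmt, ...) {
  stop(structure(class = c("ps_data_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = NULL)))
}

#' Natural (numeric-aware) chromosome ranking
#'
#' Orders chromosome names so that chr2 sorts before chr10. When an explicit
#' `chrom_order` (e.g. the order of a chrom-sizes file) is supplied it takes
#' precedence; names absent from it are ranked after, among themselves in
#' natural order.
#'
#' @param chroms character vector of chromosome names.
#' @param chrom_order optional character vector giving the authoritative order.
#' @return integer ranks, usable for comparisons.
#' @keywords internal
chrom_rank <- function(chroms, chrom_order = NULL) {
  if (!is.null(chrom_order)) {
    lev <- c(chrom_order,
             .natural_sort(setdiff(unique(chroms), chrom_order)))
  } else {
    lev <- .natural_sort(unique(chroms))
  }
  match(chroms, lev)
}

.natural_sort <- function(x) {
  if (length(x) == 0L) return(x)
  num <- suppressWarnings(as.numeric(sub("^chr", "", x)))
  ord <- order(is.na(num), num, x)
  x[ord]
}

# Parse "chr1:100-200" (commas tolerated) or pass through a list/one-row
# data.frame with chrom/start/end.
parse_range <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    m <- regmatches(x, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", x))[[1]]
    if (length(m) != 4L) {
      stop_usage("cannot parse range '%s' (expected chrom:start-end)", x)
    }
    return(list(chrom = m[2],
                start = as.numeric(gsub(",", "", m[3])),
                end   = as.numeric(gsub(",", "", m[4]))))
  }
  if (is.data.frame(x)) {
    if (nrow(x) != 1L) stop_usage("range data.frame must have exactly one row")
    x <- as.list(x)
  }
  if (is.list(x) && all(c("chrom", "start", "end") %in% names(x))) {
    return(list(chrom = as.character(x$chrom),
                start = as.numeric(x$start), end = as.numeric(x$end)))
  }
  stop_usage("invalid range specification")
}

# GRanges from a chrom/start/end table (0-based half-open -> 1-based closed)
as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end))
}
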