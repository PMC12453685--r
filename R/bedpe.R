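#' Construct a BEDPE table of pairwise interactions
#'
#' A BEDPE row stores one 2D interaction between two 1D "feet" (anchors).
#' Feet are canonicalized so that foot1 is the upstream (lower-coordinate)
#' foot; interchromosomal rows are ordered by chromosome rank (chrom-sizes
#' order when supplied, natural chromosome order otherwise).
#'
#' @param chrom1,start1,end1 first foot (0-based half-open).
#' @param chrom2,start2,end2 second foot.
#' @param tag optional character tags (e.g. cluster membership, 7th column).
#' @param score optional numeric values (e.g. query output).
#' @param chrom_order optional chromosome order for canonicalization.
#' @return a canonicalized `data.table` with columns `chrom1,start1,end1,
#'   chrom2,start2,end2` plus `tag`/`score` when given.
#' @export
bedpe <- function(chrom1, start1, end1, chrom2, start2, end2,
                  tag = NULL, score = NULL, chrom_order = NULL) {
  out <- data.table::data.table(
    chrom1 = as.character(chrom1), start1 = as.numeric(start1),
    end1 = as.numeric(end1),
    chrom2 = as.character(chrom2), start2 = as.numeric(start2),
    end2 = as.numeric(end2))
  if (!is.null(tag)) out$tag <- as.character(tag)
  if (!is.null(score)) out$score <- as.numeric(score)
  if (nrow(out) > 0L) {
    bad <- out$start1 < 0 | out$start2 < 0 |
      out$end1 <= out$start1 | out$end2 <= out$start2
    if (any(bad)) stop_usage("invalid BEDPE feet at row %d", which(bad)[1])
  }
  canonicalize_bedpe(out, chrom_order = chrom_order)
}

#' Canonicalize BEDPE foot order
#'
#' Swaps feet so that `(chrom1, start1) <= (chrom2, start2)`; this defines
#' foot1 as the "upstream" and foot2 as the "downstream" foot used by the
#' intersection classifier. Never drops rows.
#'
#' @param x BEDPE table.
#' @param chrom_order optional chromosome order (chrom-sizes file order).
#' @return the table with feet swapped where needed.
#' @export
canonicalize_bedpe <- function(x, chrom_order = NULL) {
  if (nrow(x) == 0L) return(x)
  x <- data.table::copy(data.table::as.data.table(x))
  n <- nrow(x)
  r <- chrom_rank(c(x$chrom1, x$chrom2), chrom_order)
  r1 <- r[seq_len(n)]
  r2 <- r[n + seq_len(n)]
  swap <- r2 < r1 |
    (r1 == r2 & (x$start2 < x$start1 |
                   (x$start2 == x$start1 & x$end2 < x$end1)))
  if (any(swap)) {
    tmp <- x[swap, c("chrom1", "start1", "end1")]
    data.table::set(x, which(swap), c("chrom1", "start1", "end1"),
                    x[swap, c("chrom2", "start2", "end2")])
    data.table::set(x, which(swap), c("chrom2", "start2", "end2"), tmp)
  }
  x
}

# deterministic BEDPE sort used by every producer
sort_bedpe <- function(x, chrom_order = NULL) {
  if (nrow(x) == 0L) return(x)
  n <- nrow(x)
  r <- chrom_rank(c(x$chrom1, x$chrom2), chrom_order)
  ord <- order(r[seq_len(n)], x$start1, r[n + seq_len(n)], x$start2,
               x$end1, x$end2)
  x[ord]
}

#' Read a BEDPE file
#'
#' Reads a 6+-column tab-separated BEDPE. Columns 1-3 become foot1 and 4-6
#' foot2; extra columns are interpreted according to `schema`. Feet are
#' canonicalized on read (rows are never dropped).
#'
#' @param path BEDPE file (`"-"` for stdin); `#`/`track` lines are skipped.
#' @param schema names for columns 7, 8, ... . The default `c("tag","score")`
#'   reads a 7th column as a membership tag and an 8th as a numeric score;
#'   use `"score"` for query output whose 7th column is the appended value.
#' @param chrom_order optional chromosome order for canonicalization.
#' @return a canonical BEDPE `data.table`.
#' @export
read_bedpe <- function(path, schema = c("tag", "score"), chrom_order = NULL) {
  con_lines <- if (identical(path, "-")) readLines(file("stdin")) else {
    if (!file.exists(path)) stop_usage("BEDPE file not found: %s", path)
    readLines(path)
  }
  keep <- !grepl("^(#|track\\b|browser\\b)", con_lines) &
    nzchar(trimws(con_lines))
  lineno <- which(keep)
  lines <- con_lines[keep]
  if (length(lines) == 0L) {
    return(bedpe(character(), numeric(), numeric(),
                 character(), numeric(), numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6L)) {
    stop_data("BEDPE parse error at line %d of %s: fewer than 6 columns",
              lineno[which(nf < 6L)[1]], path)
  }
  col <- function(k) vapply(fields, function(f)
    if (length(f) >= k) f[[k]] else NA_character_, "")
  out <- data.table::data.table(
    chrom1 = col(1), start1 = as.numeric(col(2)), end1 = as.numeric(col(3)),
    chrom2 = col(4), start2 = as.numeric(col(5)), end2 = as.numeric(col(6)))
  bad <- is.na(out$start1) | is.na(out$start2) | is.na(out$end1) |
    is.na(out$end2) | out$end1 <= out$start1 | out$end2 <= out$start2
  if (any(bad)) {
    stop_data("BEDPE parse error at line %d of %s: invalid feet",
              lineno[which(bad)[1]], path)
  }
  for (k in seq_along(schema)) {
    if (any(nf >= 6L + k)) {
      v <- col(6L + k)
      out[[schema[k]]] <- if (schema[k] == "score") as.numeric(v) else v
    }
  }
  canonicalize_bedpe(out, chrom_order = chrom_order)
}

#' Write a BEDPE file
#'
#' Writes tab-separated BEDPE, tag column (when present) as column 7 and
#' score as the following column, matching what [read_bedpe()] expects.
#' Row order is preserved, so `read_bedpe(write_bedpe(x))` round-trips.
#'
#' @param x BEDPE table.
#' @param path output path, or `""` for stdout.
#' @param float_digits decimal places used to format the score column.
#' @export
write_bedpe <- function(x, path, float_digits = 6L) {
  fmt_pos <- function(v) format(v, scientific = FALSE, trim = TRUE)
  cols <- list(x$chrom1, fmt_pos(x$start1), fmt_pos(x$end1),
               x$chrom2, fmt_pos(x$start2), fmt_pos(x$end2))
  if (!is.null(x$tag)) cols <- c(cols, list(x$tag))
  if (!is.null(x$score)) {
    cols <- c(cols, list(sprintf(paste0("%.", float_digits, "f"), x$score)))
  }
  lines <- if (nrow(x) == 0L) character() else do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
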