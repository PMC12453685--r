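#' Numeric contact window for plotting
#'
#' Returns the dense normalized window used by contact-map renderings,
#' either for an explicit range (intra- or interchromosomal) or centered
#' on a named gene. With a second matrix the window is the two-sample
#' delta. The grid is a plain numeric matrix and can be written as TSV.
#'
#' @param m a [contact_matrix()].
#' @param range window range (`"chr:start-end"` or chrom/start/end list);
#'   alternatively give `gene` + `genes`.
#' @param range2 optional second range for rectangular (e.g. trans)
#'   windows; defaults to `range`.
#' @param gene gene name to center on; the window is the gene span padded
#'   by `max(pad_factor * gene length, pad_min)` on each side, clipped to
#'   the chromosome.
#' @param genes gene BED (with a `name` column) used to resolve `gene`.
#' @param spec numeric space.
#' @param m2,spec2 optional second sample (delta window).
#' @param pad_factor,pad_min gene-centering padding control.
#' @return as [fetch_window()]: `values` grid plus bin coordinates.
#' @export
contact_window <- function(m, range = NULL, range2 = NULL, gene = NULL,
                           genes = NULL, spec = default_mode(m$meta),
                           m2 = NULL, spec2 = if (!is.null(m2))
                             default_mode(m2$meta),
                           pad_factor = 10, pad_min = 2e5) {
  if (is.null(range)) {
    if (is.null(gene) || is.null(genes)) {
      stop_usage("provide a range, or a gene plus a gene BED")
    }
    range <- gene_range(gene, genes, m$meta, pad_factor, pad_min)
  }
  if (is.null(range2)) range2 <- range
  if (is.null(m2)) {
    fetch_window(m, range, range2, spec)
  } else {
    delta_matrix(m, m2, range, range2, spec, spec2)
  }
}

# padded window around a named gene, clipped to the chromosome
gene_range <- function(gene, genes, meta, pad_factor = 10, pad_min = 2e5) {
  g <- data.table::as.data.table(genes)
  if (!"name" %in% names(g)) stop_usage("gene BED needs a name column")
  hit <- g[g$name == gene]
  if (nrow(hit) == 0L) stop_data("gene '%s' not found", gene)
  hit <- hit[1]
  pad <- max(pad_factor * (hit$end - hit$start), pad_min)
  list(chrom = hit$chrom,
       start = max(0, hit$start - pad),
       end = min(meta$chrom_sizes[[hit$chrom]], hit$end + pad))
}

#' Virtual 4C profile from a contact matrix
#'
#' Extracts the normalized interaction profile of one viewpoint against
#' every bin of a range: `profile[b] = value(viewpoint bin, b)` with
#' symmetric completion, i.e. the viewpoint's row of the dense window.
#'
#' @param m a [contact_matrix()].
#' @param viewpoint coordinate of interest: `"chr:pos"`, or a list with
#'   `chrom` and `pos` (bp).
#' @param range profile range; must contain the viewpoint.
#' @param spec numeric space.
#' @return a `data.table` with `chrom`, `bin`, `start`, `end`, `value`.
#' @export
virtual_4c <- function(m, viewpoint, range, spec = default_mode(m$meta)) {
  vp <- if (is.character(viewpoint) && length(viewpoint) == 1L) {
    parts <- strsplit(viewpoint, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop_usage("viewpoint must be chrom:pos")
    list(chrom = parts[1], pos = as.numeric(gsub(",", "", parts[2])))
  } else viewpoint
  r <- parse_range(range)
  res <- m$meta$resolution
  vbin <- as.integer(floor(vp$pos / res))
  w <- fetch_window(m, range, range, spec)
  if (vp$chrom != r$chrom || !vbin %in% w$bins1) {
    stop_usage("viewpoint %s:%g lies outside the range", vp$chrom, vp$pos)
  }
  data.table::data.table(chrom = r$chrom, bin = w$bins2,
                         start = w$bins2 * res, end = (w$bins2 + 1) * res,
                         value = w$values[match(vbin, w$bins1), ])
}

#' Aggregate peak analysis (APA)
#'
#' Centers a `(2w+1) x (2w+1)` pixel block on every loop (the bins
#' containing each foot's midpoint), skewers the blocks into an
#' elementwise mean pile-up, and scores the center enrichment as the
#' center value divided by the mean of the lower-left corner block (the
#' short-distance corner), size `floor(w/2)`. Loops whose block would
#' cross the diagonal or a chromosome edge, interchromosomal loops, and
#' loops closer than `min_dist_bins` are skipped and counted.
#'
#' @param records BEDPE loop set.
#' @param m a [contact_matrix()].
#' @param spec numeric space.
#' @param window_bins half-width `w` of the block, in bins.
#' @param min_dist_bins additional minimum diagonal distance, in bins.
#' @param m2,spec2 optional second sample: the pile-up becomes
#'   `apa(m) - apa(m2)` on the identical loop set.
#' @param corner_bins corner-block size for the score; default
#'   `max(1, floor(w/2))`.
#' @return an object of class `apa_result`: `matrix`, `n_used`,
#'   `n_skipped`, `dist_hist` (pair distances in bins), `apa_score`.
#' @export
apa <- function(records, m, spec = default_mode(m$meta), window_bins = 10L,
                min_dist_bins = 0L, m2 = NULL,
                spec2 = if (!is.null(m2)) default_mode(m2$meta),
                corner_bins = NULL) {
  w <- as.integer(window_bins)
  if (w < 1L) stop_usage("window_bins must be >= 1")
  if (is.null(corner_bins)) corner_bins <- max(1L, w %/% 2L)
  x <- data.table::as.data.table(records)
  res <- m$meta$resolution
  side <- 2L * w + 1L
  acc <- matrix(0, side, side)
  acc2 <- if (!is.null(m2)) matrix(0, side, side)
  n_used <- 0L
  dists <- integer(0)
  for (i in seq_len(nrow(x))) {
    if (x$chrom1[i] != x$chrom2[i]) next
    nb <- matrix_n_bins(m$meta, x$chrom1[i])
    c1 <- floor(floor((x$start1[i] + x$end1[i]) / 2) / res)
    c2 <- floor(floor((x$start2[i] + x$end2[i]) / 2) / res)
    d <- abs(c2 - c1)
    if (d < min_dist_bins) next
    if (c2 - c1 <= 2L * w) next          # block would cross the diagonal
    if (c1 - w < 0L || c2 + w > nb - 1L) next  # chromosome edge
    blk <- window_bins(m, x$chrom1[i], c(c1 - w, c1 + w),
                       x$chrom2[i], c(c2 - w, c2 + w), spec)$values
    acc <- acc + blk
    if (!is.null(m2)) {
      acc2 <- acc2 + window_bins(m2, x$chrom1[i], c(c1 - w, c1 + w),
                                 x$chrom2[i], c(c2 - w, c2 + w),
                                 spec2)$values
    }
    n_used <- n_used + 1L
    dists <- c(dists, d)
  }
  if (n_used == 0L) stop_data("no usable loops for APA")
  mat <- acc / n_used
  if (!is.null(m2)) mat <- mat - acc2 / n_used
  cs <- corner_bins
  corner <- mat[(side - cs + 1L):side, 1L:cs, drop = FALSE]
  center <- mat[w + 1L, w + 1L]
  hist <- data.table::as.data.table(table(dist_bins = dists))
  hist$dist_bins <- as.integer(hist$dist_bins)
  data.table::setnames(hist, "N", "count")
  structure(list(matrix = mat, n_used = n_used,
                 n_skipped = nrow(x) - n_used,
                 dist_hist = hist,
                 apa_score = center / mean(corner)),
            class = "apa_result")
}

#' @export
print.apa_result <- function(x, ...) {
  cat(sprintf("<apa_result> %dx%d pile-up of %d loops (%d skipped), APA score %.3f\n",
              nrow(x$matrix), ncol(x$matrix), x$n_used, x$n_skipped,
              x$apa_score))
  invisible(x)
}

#' Write a numeric grid (contact window or APA matrix) as TSV
#' @param grid a matrix, or a list with a `values` matrix.
#' @param path output path.
#' @export
write_grid <- function(grid, path) {
  mat <- if (is.list(grid) && !is.data.frame(grid)) grid$values else grid
  utils::write.table(mat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
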