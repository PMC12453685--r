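# scope handling shared by the extract operations: a scope is a range
# ("chr:lo-hi" / list) or a TAD-style interval table; returns a data.table
# of chrom / bin_lo / bin_hi windows
scope_windows <- function(m, scope) {
  res <- m$meta$resolution
  tab <- if (is.data.frame(scope)) {
    data.table::as.data.table(scope)
  } else {
    r <- parse_range(scope)
    data.table::data.table(chrom = r$chrom, start = r$start, end = r$end)
  }
  out <- tab[, list(chrom = chrom,
                    bin_lo = pmax(0L, as.integer(floor(start / res))),
                    bin_hi = as.integer(floor((end - 1) / res)))]
  out$bin_hi <- pmin(out$bin_hi, matrix_n_bins(m$meta, out$chrom) - 1L)
  out[out$bin_hi >= out$bin_lo]
}

# intrachromosomal pixels of m whose feet both fall inside one scope
# window, at least min_dist bins off the diagonal, deduplicated, with
# inherent scores attached
scored_pixels <- function(m, model, scope, min_dist = 2L) {
  win <- scope_windows(m, scope)
  px <- m$pixels[m$pixels$chrom1 == m$pixels$chrom2]
  parts <- lapply(seq_len(nrow(win)), function(i) {
    px[px$chrom1 == win$chrom[i] &
         px$bin1 >= win$bin_lo[i] & px$bin1 <= win$bin_hi[i] &
         px$bin2 >= win$bin_lo[i] & px$bin2 <= win$bin_hi[i]]
  })
  sel <- unique(data.table::rbindlist(parts))
  # the diagonal itself is never scoreable (distance 0)
  sel <- sel[sel$bin2 - sel$bin1 >= max(min_dist, 1L)]
  if (nrow(sel) == 0L) {
    sel$value <- numeric(0); sel$inherent <- numeric(0)
    return(sel)
  }
  spec <- norm_spec(model$mode)
  sel$value <- normalize_value(sel$count, m$meta, spec)
  sel$inherent <- inherent_score(model, sel$value,
                                 (sel$bin2 - sel$bin1) * m$meta$resolution)
  sel
}

# pixel table -> BEDPE rows with score + bin bookkeeping columns
pixels_to_loops <- function(sel, res, mode) {
  out <- data.table::data.table(
    chrom1 = sel$chrom1, start1 = sel$bin1 * res, end1 = (sel$bin1 + 1) * res,
    chrom2 = sel$chrom2, start2 = sel$bin2 * res, end2 = (sel$bin2 + 1) * res,
    score = sel$inherent, bin1 = sel$bin1, bin2 = sel$bin2,
    n_bins = 1L, mode = mode)
  data.table::setorder(out, chrom1, start1, start2)
  out
}

#' Extract single-bin loops by inherent-score thresholding
#'
#' Every intrachromosomal pixel inside the scope whose diagonal distance is
#' at least `min_dist` bins and whose inherent score reaches `threshold`
#' becomes one resolution-sized BEDPE row with the score appended.
#'
#' @param m a [contact_matrix()].
#' @param model an [inherent_model()] fitted on (or constructed for) `m`.
#' @param scope a range (`"chr:start-end"`) or a TAD interval table; with a
#'   TAD table the result is the deduplicated union of per-TAD extractions.
#' @param threshold inherent-score cutoff in `[0, 1]`.
#' @param min_dist minimum diagonal distance in bins (default 2: the
#'   diagonal and first off-diagonal are dominated by self-ligation).
#' @return a BEDPE `data.table` with `score`, `bin1`, `bin2`, `n_bins`,
#'   `mode` columns, sorted by coordinates.
#' @export
extract_single <- function(m, model, scope, threshold, min_dist = 2L) {
  if (threshold < 0 || threshold > 1) {
    stop_usage("threshold must lie in [0, 1]")
  }
  sel <- scored_pixels(m, model, scope, min_dist)
  sel <- sel[sel$inherent >= threshold]
  pixels_to_loops(sel, m$meta$resolution, "single")
}

#' Agglomerate supra-threshold bins into globbed loops
#'
#' Merges single-bin loops into connected components under the adjacency
#' "Chebyshev bin distance <= radius + 1", so `radius` counts the maximum
#' number of gap bins between conjoined structures (radius 0 = touching,
#' 8-neighbour). Each component becomes one BEDPE row whose feet are the
#' per-axis bounding spans, with `score` the maximum member score and
#' `n_bins` the component size. Components whose bounding feet overlap
#' (near-diagonal structures) are kept and flagged in a `note` column.
#'
#' @param loops output of [extract_single()] (or any table with `chrom1`,
#'   `bin1`, `bin2`, `score`).
#' @param radius non-negative integer gap tolerance, in bins.
#' @param resolution bin size in bp; inferred from the rows when omitted.
#' @return a BEDPE `data.table`, one row per component.
#' @export
glob_loops <- function(loops, radius = 0L, resolution = NULL) {
  if (radius < 0) stop_usage("radius must be >= 0")
  x <- data.table::as.data.table(loops)
  if (nrow(x) == 0L) return(x)
  if (is.null(resolution)) resolution <- x$end1[1] - x$start1[1]
  x$.comp <- glob_components(x$chrom1, x$bin1, x$bin2, radius)
  out <- x[, list(
    chrom1 = chrom1[1], start1 = min(bin1) * resolution,
    end1 = (max(bin1) + 1) * resolution,
    chrom2 = chrom2[1], start2 = min(bin2) * resolution,
    end2 = (max(bin2) + 1) * resolution,
    score = max(score), n_bins = .N, mode = "glob"), by = ".comp"]
  out$.comp <- NULL
  out$note <- ifelse(out$chrom1 == out$chrom2 & out$start2 < out$end1,
                     "feet_overlap", "")
  data.table::setorder(out, chrom1, start1, start2)
  out
}

# connected-component labels for bins under Chebyshev distance <= radius+1
glob_components <- function(chrom, bin1, bin2, radius) {
  n <- length(bin1)
  labels <- integer(n)
  reach <- radius + 1L
  offset <- 0L
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    dt <- data.table::data.table(i = seq_along(idx),
                                 b1 = bin1[idx], b2 = bin2[idx])
    # candidate pairs via a coarse grid of cell size `reach`: any pair at
    # Chebyshev distance <= reach sits in the same or an adjacent cell
    dt$c1 <- dt$b1 %/% reach
    dt$c2 <- dt$b2 %/% reach
    shifts <- expand.grid(d1 = -1:1, d2 = -1:1)
    edges <- data.table::rbindlist(lapply(seq_len(nrow(shifts)), function(s) {
      a <- dt[, list(i, c1 = c1 + shifts$d1[s], c2 = c2 + shifts$d2[s],
                     b1, b2)]
      mrg <- merge(a, dt, by = c("c1", "c2"), allow.cartesian = TRUE,
                   suffixes = c(".a", ".b"))
      mrg <- mrg[mrg$i.a < mrg$i.b &
                   abs(mrg$b1.a - mrg$b1.b) <= reach &
                   abs(mrg$b2.a - mrg$b2.b) <= reach]
      mrg[, c("i.a", "i.b")]
    }))
    g <- igraph::graph_from_data_frame(
      unique(edges), directed = FALSE,
      vertices = data.frame(name = seq_along(idx)))
    comp <- igraph::components(g)$membership
    labels[idx] <- offset + comp[as.character(seq_along(idx))]
    offset <- max(labels)
  }
  labels
}

#' Detect flare anchor bins
#'
#' A flare is a long, narrow off-diagonal projection of elevated signal
#' emanating from one highly interacting element. Per 1D bin in scope, the
#' marginal is the sum of inherent scores of its off-band pixels; anchors
#' are bins whose marginal exceeds `mean + flare_z * SD` of the scope
#' marginals (strictly, so a flat landscape yields no anchors). Operating
#' on inherent scores rather than raw counts keeps deep loci from
#' dominating.
#'
#' @inheritParams extract_single
#' @param flare_z anchor threshold in marginal standard deviations.
#' @return a `data.table` of anchor bins (`chrom`, `bin`, `start`, `end`,
#'   `marginal`); the anchor set grows monotonically as `flare_z`
#'   decreases.
#' @export
detect_flares <- function(m, model, scope, flare_z = 3, min_dist = 2L) {
  win <- scope_windows(m, scope)
  sel <- scored_pixels(m, model, scope, min_dist)
  bins <- unique(data.table::rbindlist(lapply(seq_len(nrow(win)), function(i)
    data.table::data.table(chrom = win$chrom[i],
                           bin = win$bin_lo[i]:win$bin_hi[i]))))
  marg <- data.table::rbindlist(list(
    sel[, list(chrom = chrom1, bin = bin1, s = inherent)],
    sel[, list(chrom = chrom1, bin = bin2, s = inherent)]))
  agg <- marg[, list(marginal = sum(s)), by = c("chrom", "bin")]
  bins <- merge(bins, agg, by = c("chrom", "bin"), all.x = TRUE)
  bins$marginal[is.na(bins$marginal)] <- 0
  mu <- mean(bins$marginal)
  sd <- stats::sd(bins$marginal)
  if (is.na(sd)) sd <- 0
  out <- bins[bins$marginal > mu + flare_z * sd]
  res <- m$meta$resolution
  out$start <- out$bin * res
  out$end <- (out$bin + 1) * res
  data.table::setorder(out, chrom, bin)
  out
}

#' Report flare crossings
#'
#' A crossing is a pixel where two flares intersect: both of its bins are
#' flare anchors, it lies at least `min_dist` bins off the diagonal, and
#' (by default) its inherent score also reaches `threshold`.
#'
#' @inheritParams extract_single
#' @param anchors anchor table from [detect_flares()].
#' @param pixel_threshold require the crossing pixel itself to pass
#'   `threshold`; `FALSE` reports every nonzero anchor-by-anchor pixel.
#' @return a BEDPE `data.table` with `mode = "flare"`.
#' @export
flare_crossings <- function(m, model, anchors, threshold, min_dist = 2L,
                            pixel_threshold = TRUE) {
  if (threshold < 0 || threshold > 1) {
    stop_usage("threshold must lie in [0, 1]")
  }
  px <- m$pixels[m$pixels$chrom1 == m$pixels$chrom2]
  px <- px[px$bin2 - px$bin1 >= min_dist]
  key1 <- paste(px$chrom1, px$bin1)
  key2 <- paste(px$chrom2, px$bin2)
  akey <- paste(anchors$chrom, anchors$bin)
  sel <- px[key1 %in% akey & key2 %in% akey & px$count > 0]
  if (nrow(sel) == 0L) {
    sel$value <- numeric(0); sel$inherent <- numeric(0)
    return(pixels_to_loops(sel, m$meta$resolution, "flare"))
  }
  sel$value <- normalize_value(sel$count, m$meta, norm_spec(model$mode))
  sel$inherent <- inherent_score(model, sel$value,
                                 (sel$bin2 - sel$bin1) * m$meta$resolution)
  if (pixel_threshold) sel <- sel[sel$inherent >= threshold]
  pixels_to_loops(sel, m$meta$resolution, "flare")
}
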