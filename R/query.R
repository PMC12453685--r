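#' Annotate BEDPE rows with contact-matrix values
#'
#' For each BEDPE row, the query window is the rectangle of matrix bins
#' covered by foot1 x foot2 (optionally expanded by `expand` bins per
#' side). One of four arithmetic formulas reduces the window to a value
#' appended as the `score` column:
#' \describe{
#'   \item{center}{the pixel at the bins containing each foot's midpoint}
#'   \item{max}{the largest pixel in the window}
#'   \item{sum}{the sum over all window pixels}
#'   \item{mean}{the sum divided by the full window pixel count (zeros
#'     included; `mean_nonzero = TRUE` divides by the nonzero count)}
#' }
#' With a second matrix the appended value is the per-sample difference
#' `formula(m) - formula(m2)` on the identical window (or the formula of
#' the pixelwise difference grid when `delta_pixelwise = TRUE`). With
#' `fix = FALSE` and formula `max` or `center`, the feet are replaced by
#' the single resolution-sized bin realizing the formula (ties broken by
#' smallest `(bin1, bin2)` in row-major order); under a delta the case
#' sample `m` anchors the relocation.
#'
#' @param records BEDPE table.
#' @param m a [contact_matrix()].
#' @param spec numeric space for `m`; default the sample's own default.
#' @param formula one of `"center"`, `"max"`, `"sum"`, `"mean"`.
#' @param fix keep input coordinates (`TRUE`, default) or update them from
#'   the formula (`max`/`center` only).
#' @param expand widen each foot by this many bins on both sides (clipped
#'   to the chromosome with a warning).
#' @param m2,spec2 optional second sample for delta values.
#' @param delta_pixelwise subtract grids before applying the formula.
#' @param mean_nonzero divide `mean` by the nonzero pixel count.
#' @return the records with a `score` column (and updated feet when
#'   `fix = FALSE`), in input row order.
#' @export
query_values <- function(records, m, spec = default_mode(m$meta),
                         formula = c("max", "center", "sum", "mean"),
                         fix = TRUE, expand = 0L, m2 = NULL,
                         spec2 = if (!is.null(m2)) default_mode(m2$meta),
                         delta_pixelwise = FALSE, mean_nonzero = FALSE) {
  formula <- match.arg(formula)
  if (!fix && !formula %in% c("max", "center")) {
    stop_usage("fix = FALSE requires formula max or center (no defining bin)")
  }
  if (expand < 0) stop_usage("expand must be >= 0")
  x <- data.table::copy(data.table::as.data.table(records))
  res <- m$meta$resolution
  if (!is.null(m2) && m2$meta$resolution != res) {
    stop_usage("delta query requires equal resolutions")
  }
  n <- nrow(x)
  val <- numeric(n)
  if (n == 0L) { x$score <- numeric(0); return(x) }
  clipped <- FALSE
  new_feet <- vector("list", n)
  for (i in seq_len(n)) {
    nb1 <- matrix_n_bins(m$meta, x$chrom1[i])
    nb2 <- matrix_n_bins(m$meta, x$chrom2[i])
    b1 <- c(floor(x$start1[i] / res), floor((x$end1[i] - 1) / res)) +
      c(-expand, expand)
    b2 <- c(floor(x$start2[i] / res), floor((x$end2[i] - 1) / res)) +
      c(-expand, expand)
    cb1 <- c(max(0, b1[1]), min(nb1 - 1, b1[2]))
    cb2 <- c(max(0, b2[1]), min(nb2 - 1, b2[2]))
    if (!identical(b1, cb1) || !identical(b2, cb2)) clipped <- TRUE
    w <- window_bins(m, x$chrom1[i], cb1, x$chrom2[i], cb2, spec)
    g <- w$values
    if (!is.null(m2)) {
      w2 <- window_bins(m2, x$chrom1[i], cb1, x$chrom2[i], cb2, spec2)
      if (delta_pixelwise) g <- g - w2$values
    }
    # midpoint bins of the (unexpanded) feet, for the center formula
    c1 <- floor(floor((x$start1[i] + x$end1[i]) / 2) / res)
    c2 <- floor(floor((x$start2[i] + x$end2[i]) / 2) / res)
    eval_grid <- function(g) {
      switch(formula,
        center = g[match(c1, w$bins1), match(c2, w$bins2)],
        max = max(g),
        sum = sum(g),
        mean = if (mean_nonzero) {
          nz <- sum(g != 0)
          if (nz == 0L) 0 else sum(g) / nz
        } else sum(g) / length(g))
    }
    val[i] <- if (!is.null(m2) && !delta_pixelwise) {
      eval_grid(g) - eval_grid(w2$values)
    } else eval_grid(g)
    if (!fix) {
      if (formula == "max") {
        # row-major first maximum: scan rows, then columns
        tg <- t(g)
        k <- which(tg == max(tg))[1] - 1L
        ri <- k %/% ncol(g) + 1L
        ci <- k %% ncol(g) + 1L
        new_feet[[i]] <- c(w$bins1[ri], w$bins2[ci])
      } else {
        new_feet[[i]] <- c(c1, c2)
      }
    }
  }
  if (clipped) warning("window expansion clipped at chromosome ends")
  if (!fix) {
    nf <- do.call(rbind, new_feet)
    x$start1 <- nf[, 1] * res; x$end1 <- (nf[, 1] + 1) * res
    x$start2 <- nf[, 2] * res; x$end2 <- (nf[, 2] + 1) * res
  }
  x$score <- val
  x
}
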