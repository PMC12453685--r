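#' Construct an inherent distance-decay model directly
#'
#' The inherent model maps a contact value at genomic distance `d` into a
#' 0-1 score that is independent of distance: 0 is the standard contact
#' level of non-interacting active elements (the background curve `B`) and
#' 1 the standard level of interacting regulatory elements (the top curve
#' `T`). Both curves are power laws `k * d^(-alpha)` in base-pair distance.
#' Normally the model is fitted from data with [fit_inherent()]; this
#' constructor builds one from known parameters (e.g. the planted truth of
#' a synthetic matrix).
#'
#' @param k_bg,alpha_bg intercept and decay exponent of the background curve.
#' @param k_top,alpha_top intercept and decay exponent of the top curve.
#' @param resolution bin size in bp the model was fitted at.
#' @param eps positive log-floor applied to values before scoring.
#' @param mode numeric space the model expects values in.
#' @param quantile_lo,quantile_hi anchor quantiles (metadata).
#' @param table optional per-distance fit table.
#' @return an object of class `inherent_model`.
#' @export
inherent_model <- function(k_bg, alpha_bg, k_top, alpha_top, resolution,
                           eps = 1e-9, mode = "none",
                           quantile_lo = 0.5, quantile_hi = 0.99,
                           table = NULL) {
  if (k_bg <= 0 || k_top <= 0) stop_usage("power-law intercepts must be > 0")
  structure(list(k_bg = k_bg, alpha_bg = alpha_bg, k_top = k_top,
                 alpha_top = alpha_top, resolution = resolution,
                 eps = eps, mode = mode, quantile_lo = quantile_lo,
                 quantile_hi = quantile_hi, table = table),
            class = "inherent_model")
}

#' @export
print.inherent_model <- function(x, ...) {
  cat(sprintf(paste0("<inherent_model> B(d) = %.4g * d^-%.4g, ",
                     "T(d) = %.4g * d^-%.4g  (%g bp bins, %s space)\n"),
              x$k_bg, x$alpha_bg, x$k_top, x$alpha_top, x$resolution, x$mode))
  invisible(x)
}

#' Background and top curves of an inherent model
#' @param model an [inherent_model()].
#' @param d genomic distance(s) in bp, > 0.
#' @return the standard non-interacting (`inherent_background`) or
#'   interacting (`inherent_top`) contact level at `d`.
#' @export
inherent_background <- function(model, d) model$k_bg * d^(-model$alpha_bg)

#' @rdname inherent_background
#' @export
inherent_top <- function(model, d) model$k_top * d^(-model$alpha_top)

# log-spaced selection of integer bin distances: all of 1..20, then
# log-spaced individual distances out to d_max
select_distances <- function(d_max, dense_until = 20L, n_log = 40L) {
  d <- seq_len(min(dense_until, d_max))
  if (d_max > dense_until) {
    extra <- unique(round(exp(seq(log(dense_until + 1), log(d_max),
                                  length.out = n_log))))
    d <- sort(unique(c(d, extra)))
  }
  d
}

#' Fit the per-sample inherent distance-decay model
#'
#' For a log-spaced selection of bin distances, the `quantile_lo` and
#' `quantile_hi` quantiles of the nonzero pixel values at that exact
#' distance (pooled over chromosomes) define the empirical background and
#' top levels; each curve is then replaced by a least-squares power-law fit
#' `log v = log k - alpha * log d` over distances with at least
#' `min_pixels` supporting pixels. The fit is deterministic given the
#' matrix.
#'
#' @param m a [contact_matrix()].
#' @param chroms optional chromosome subset to pool; default all.
#' @param spec numeric space fitted in (scores must later be computed on
#'   values in the same space); default raw counts.
#' @param quantile_lo,quantile_hi anchor quantiles for the background and
#'   top curves.
#' @param min_pixels minimum nonzero pixels per distance for it to enter
#'   the fit; chromosomes with fewer than `min_pixels` total are excluded
#'   with a warning.
#' @param min_nonzero_frac minimum fraction of possible pixels at a
#'   distance that must be nonzero for that distance to enter the fit.
#'   Where the matrix is sparser, quantiles of the nonzero counts are
#'   dominated by zero-truncation and count discreteness (the conditional
#'   median saturates at 1) and would flatten the decay curve.
#' @param require_gap when `TRUE` (default) a fit whose top curve does not
#'   strictly exceed its background curve at every fitted distance is an
#'   error (such a model cannot score); set `FALSE` to retrieve decay
#'   parameters from degenerate inputs.
#' @param per_chrom fit one model per chromosome instead of pooling.
#' @return an [inherent_model()] (or a named list of them when
#'   `per_chrom = TRUE`).
#' @export
fit_inherent <- function(m, chroms = NULL, spec = norm_spec("none"),
                         quantile_lo = 0.5, quantile_hi = 0.99,
                         min_pixels = 50L, min_nonzero_frac = 0.8,
                         require_gap = TRUE, per_chrom = FALSE) {
  res <- m$meta$resolution
  if (!res %in% c(1000, 5000)) {
    warning(sprintf("inherent model is intended for 1 kb / 5 kb bins; fitting at %g bp%s",
                    res, if (res > 25000) " (coarser than 25 kb)" else ""))
  }
  px <- m$pixels[m$pixels$chrom1 == m$pixels$chrom2]
  if (!is.null(chroms)) px <- px[px$chrom1 %in% chroms]
  if (per_chrom) {
    out <- lapply(unique(px$chrom1), function(cc) {
      fit_inherent(m, chroms = cc, spec = spec, quantile_lo = quantile_lo,
                   quantile_hi = quantile_hi, min_pixels = min_pixels,
                   min_nonzero_frac = min_nonzero_frac,
                   require_gap = require_gap)
    })
    names(out) <- unique(px$chrom1)
    return(out)
  }
  n_by_chrom <- table(px$chrom1)
  thin <- names(n_by_chrom)[n_by_chrom < min_pixels]
  if (length(thin) > 0L) {
    warning(sprintf("excluding %s from inherent fit (< %d pixels)",
                    paste(thin, collapse = ", "), min_pixels))
    px <- px[!px$chrom1 %in% thin]
  }
  px <- px[px$count > 0 & px$bin2 > px$bin1]
  if (nrow(px) == 0L) stop_data("no usable pixels for inherent fit")
  v <- normalize_value(px$count, m$meta, spec)
  dist_bins <- px$bin2 - px$bin1
  d_sel <- select_distances(max(dist_bins))
  # possible (zero + nonzero) pixels at each distance, over fitted chroms
  nb <- matrix_n_bins(m$meta, unique(px$chrom1))
  n_possible <- vapply(d_sel, function(d) sum(pmax(0L, nb - d)), 0)
  tab <- data.table::rbindlist(lapply(seq_along(d_sel), function(k) {
    d <- d_sel[k]
    vd <- v[dist_bins == d]
    if (length(vd) < min_pixels) return(NULL)
    if (length(vd) / n_possible[k] < min_nonzero_frac) return(NULL)
    data.table::data.table(
      d_bin = d, n = length(vd),
      B = stats::quantile(vd, quantile_lo, names = FALSE),
      T = stats::quantile(vd, quantile_hi, names = FALSE))
  }))
  if (is.null(tab) || nrow(tab) < 2L) {
    stop_data("no usable distance bins for inherent fit")
  }
  d_bp <- tab$d_bin * res
  fit_curve <- function(y) {
    co <- stats::coef(stats::lm(log(y) ~ log(d_bp)))
    c(k = exp(unname(co[1])), alpha = -unname(co[2]))
  }
  fb <- fit_curve(tab$B)
  ft <- fit_curve(tab$T)
  tab$B_fit <- fb["k"] * d_bp^(-fb["alpha"])
  tab$T_fit <- ft["k"] * d_bp^(-ft["alpha"])
  if (require_gap && any(tab$T_fit <= tab$B_fit)) {
    stop_data(paste0("degenerate inherent fit: top curve does not exceed ",
                     "background at every fitted distance"))
  }
  inherent_model(k_bg = unname(fb["k"]), alpha_bg = unname(fb["alpha"]),
                 k_top = unname(ft["k"]), alpha_top = unname(ft["alpha"]),
                 resolution = res, eps = min(v[v > 0]) / 2, mode = spec$mode,
                 quantile_lo = quantile_lo, quantile_hi = quantile_hi,
                 table = tab)
}

#' Score contact values on the distance-free 0-1 inherent scale
#'
#' Linearly rescales `log v` between the background and top curves at the
#' pixel's genomic distance: `v = B(d)` scores exactly 0, `v = T(d)` scores
#' exactly 1, `sqrt(B*T)` scores 0.5, and results are clamped to `[0, 1]`.
#' Zero (absent) pixels score 0 by definition; positive values are floored
#' at the model's `eps` before taking logs.
#'
#' @param model an [inherent_model()].
#' @param v contact value(s) in the model's numeric space.
#' @param d genomic distance(s) in bp; must be > 0 (the diagonal is not
#'   scored).
#' @return scores in `[0, 1]`, vectorized over `v`/`d`.
#' @export
inherent_score <- function(model, v, d) {
  if (any(d <= 0)) stop_usage("inherent score requires distance > 0")
  B <- inherent_background(model, d)
  Tt <- inherent_top(model, d)
  if (any(Tt <= B)) {
    stop_data("model is degenerate at distance %g (T <= B)",
              d[which(Tt <= B)[1]])
  }
  s <- (log(pmax(v, model$eps)) - log(B)) / (log(Tt) - log(B))
  s[v <= 0] <- 0
  pmin(1, pmax(0, s))
}

#' Serialize / restore an inherent model
#'
#' The on-disk form is a TSV with `# key value` header lines (parameters)
#' followed by the per-distance table `distance_bin  B  T`, so extraction
#' runs are reproducible without refitting.
#'
#' @param model an [inherent_model()].
#' @param path file path.
#' @return `read_inherent` returns the restored [inherent_model()].
#' @export
write_inherent <- function(model, path) {
  hdr <- sprintf("# %s\t%s",
                 c("k_bg", "alpha_bg", "k_top", "alpha_top", "resolution",
                   "eps", "mode", "quantile_lo", "quantile_hi"),
                 c(format(c(model$k_bg, model$alpha_bg, model$k_top,
                            model$alpha_top, model$resolution, model$eps),
                          digits = 17), model$mode,
                   format(c(model$quantile_lo, model$quantile_hi),
                          digits = 17)))
  body <- if (!is.null(model$table)) {
    paste(model$table$d_bin,
          format(model$table$B, digits = 17),
          format(model$table$T, digits = 17), sep = "\t")
  } else character()
  writeLines(c(hdr, "# distance_bin\tB\tT", body), path)
  invisible(path)
}

#' @rdname write_inherent
#' @export
read_inherent <- function(path) {
  lines <- readLines(path)
  hdr <- lines[grepl("^# \\S+\t[^\t]+$", lines)]
  kv <- do.call(rbind, strsplit(sub("^# ", "", hdr), "\t"))
  get <- function(k) kv[kv[, 1] == k, 2][1]
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  tab <- NULL
  if (length(body) > 0L) {
    sp <- do.call(rbind, strsplit(body, "\t"))
    tab <- data.table::data.table(d_bin = as.integer(sp[, 1]),
                                  B = as.numeric(sp[, 2]),
                                  T = as.numeric(sp[, 3]))
  }
  inherent_model(k_bg = as.numeric(get("k_bg")),
                 alpha_bg = as.numeric(get("alpha_bg")),
                 k_top = as.numeric(get("k_top")),
                 alpha_top = as.numeric(get("alpha_top")),
                 resolution = as.numeric(get("resolution")),
                 eps = as.numeric(get("eps")), mode = get("mode"),
                 quantile_lo = as.numeric(get("quantile_lo")),
                 quantile_hi = as.numeric(get("quantile_hi")),
                 table = tab)
}
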