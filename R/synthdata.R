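#' Generate a HiChIP-like synthetic contact matrix with planted truth
#'
#' Emulates the plaid structure of a HiChIP contact map: a power-law
#' distance decay `mu(d) = decay_k * d^(-decay_alpha)` (d in bins) for the
#' background, planted loops that multiply single pixels by a fold factor,
#' and flare anchors whose whole row/column is multiplied. `noise =
#' "poisson"` draws integer counts from the pixel means; `noise = "none"`
#' keeps the exact means so the decay is recoverable to machine precision.
#' Everything is deterministic under `seed`.
#'
#' @param chrom_sizes named numeric vector of chromosome lengths (bp).
#' @param resolution bin size in bp.
#' @param decay_alpha,decay_k power-law exponent and level of the decay.
#' @param loops planted loops: a `data.table(chrom, bin1, bin2, fold)`, or
#'   an integer count of loops to place randomly (fold `loop_fold`).
#' @param loop_fold fold enrichment for randomly placed loops.
#' @param flares flare anchors: a `data.table(chrom, bin, fold)`, or an
#'   integer count placed randomly (fold `flare_fold`).
#' @param flare_fold fold enrichment for randomly placed flares.
#' @param noise `"poisson"` or `"none"`.
#' @param seed integer seed for all randomness (default 1729).
#' @param max_dist_bins cap on generated diagonal distance; default all.
#' @param loop_dist_bins range of diagonal distances (bins) for randomly
#'   placed loops.
#' @param total_pairs,spike_pairs metadata totals; `total_pairs` defaults
#'   to the generated count sum, `spike_pairs` (optional) switches the
#'   sample's default space to AQuA.
#' @param name sample name.
#' @return a list: `matrix` (a [contact_matrix()]), `truth` (BEDPE of
#'   planted loops, `score` = fold, with `bin1`/`bin2`), and
#'   `flare_truth` (`chrom`, `bin`, `fold`).
#' @export
make_matrix <- function(chrom_sizes, resolution = 5000, decay_alpha = 1,
                        decay_k = 100, loops = NULL, loop_fold = 5,
                        flares = NULL, flare_fold = 3,
                        noise = c("poisson", "none"), seed = 1729L,
                        max_dist_bins = NULL, loop_dist_bins = c(10L, 300L),
                        total_pairs = NULL, spike_pairs = NULL,
                        name = "synthetic") {
  noise <- match.arg(noise)
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  parts <- vector("list", length(chrom_sizes))
  loop_list <- vector("list", length(chrom_sizes))
  flare_list <- vector("list", length(chrom_sizes))
  for (ci in seq_along(chrom_sizes)) {
    cc <- names(chrom_sizes)[ci]
    nb <- as.integer(ceiling(chrom_sizes[[ci]] / resolution))
    dmax <- min(max_dist_bins %||% (nb - 1L), nb - 1L)
    d <- rep.int(seq_len(dmax), nb - seq_len(dmax))
    i <- sequence(nb - seq_len(dmax), from = 0L) # 0-based bin i per distance
    j <- i + d
    mu <- decay_k * d^(-decay_alpha)
    # planted loops on this chromosome
    lo <- if (is.data.frame(loops)) {
      data.table::as.data.table(loops)[chrom == cc]
    } else if (is.numeric(loops) && length(loops) == 1L && loops > 0) {
      n_here <- round(loops * nb / sum(ceiling(chrom_sizes / resolution)))
      hi_d <- min(loop_dist_bins[2], dmax)
      lo_d <- min(loop_dist_bins[1], hi_d)
      if (n_here > 0) {
        ld <- sample(lo_d:hi_d, n_here, replace = TRUE)
        li <- vapply(ld, function(dd) sample(0:(nb - 1L - dd), 1L), 0L)
        unique(data.table::data.table(chrom = cc, bin1 = li, bin2 = li + ld,
                                      fold = loop_fold))
      } else NULL
    } else NULL
    if (!is.null(lo) && nrow(lo) > 0L) {
      key <- paste(i, j)
      hit <- match(paste(lo$bin1, lo$bin2), key)
      ok <- !is.na(hit)
      mu[hit[ok]] <- mu[hit[ok]] * lo$fold[ok]
      loop_list[[ci]] <- lo[ok]
    }
    # planted flares: whole row/column of the anchor bin
    fl <- if (is.data.frame(flares)) {
      data.table::as.data.table(flares)[chrom == cc]
    } else if (is.numeric(flares) && length(flares) == 1L && flares > 0) {
      n_here <- round(flares * nb / sum(ceiling(chrom_sizes / resolution)))
      if (n_here > 0) {
        data.table::data.table(chrom = cc,
                               bin = sample(0:(nb - 1L), n_here),
                               fold = flare_fold)
      } else NULL
    } else NULL
    if (!is.null(fl) && nrow(fl) > 0L) {
      for (b in seq_len(nrow(fl))) {
        touch <- i == fl$bin[b] | j == fl$bin[b]
        mu[touch] <- mu[touch] * fl$fold[b]
      }
      flare_list[[ci]] <- fl
    }
    cnt <- if (noise == "poisson") stats::rpois(length(mu), mu) else mu
    keep <- cnt > 0
    parts[[ci]] <- data.table::data.table(chrom1 = cc, bin1 = i[keep],
                                          chrom2 = cc, bin2 = j[keep],
                                          count = cnt[keep])
  }
  px <- data.table::rbindlist(parts)
  meta <- sample_meta(name, resolution,
                      total_pairs %||% max(1, round(sum(px$count))),
                      spike_pairs, chrom_sizes)
  truth_dt <- data.table::rbindlist(loop_list)
  truth <- if (!is.null(truth_dt) && nrow(truth_dt) > 0L) {
    data.table::data.table(
      chrom1 = truth_dt$chrom, start1 = truth_dt$bin1 * resolution,
      end1 = (truth_dt$bin1 + 1) * resolution,
      chrom2 = truth_dt$chrom, start2 = truth_dt$bin2 * resolution,
      end2 = (truth_dt$bin2 + 1) * resolution,
      score = truth_dt$fold, bin1 = truth_dt$bin1, bin2 = truth_dt$bin2)
  } else {
    bedpe(character(), numeric(), numeric(),
          character(), numeric(), numeric())
  }
  list(matrix = contact_matrix(px, meta), truth = truth,
       flare_truth = data.table::rbindlist(flare_list))
}

#' Generate non-overlapping random genomic elements
#'
#' Draws `n` non-overlapping intervals uniformly over the genome, with
#' widths uniform in `width_range`, deterministically under `seed`.
#'
#' @param chrom_sizes named numeric vector of chromosome lengths (bp).
#' @param n number of elements.
#' @param width_range two-element numeric range of element widths (bp).
#' @param seed integer seed (default 1729).
#' @param labels optional label pool sampled into the `name` column.
#' @return an interval `data.table`, sorted by position.
#' @export
make_elements <- function(chrom_sizes, n, width_range = c(1000, 5000),
                          seed = 1729L, labels = NULL) {
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  empty <- data.table::data.table(chrom = character(), start = numeric(),
                                  end = numeric())
  if (n == 0L) return(empty)
  total <- sum(chrom_sizes)
  acc <- empty
  for (attempt in 1:50) {
    need <- n - nrow(acc)
    if (need <= 0L) break
    chrom <- sample(names(chrom_sizes), 2L * need, replace = TRUE,
                    prob = chrom_sizes / total)
    width <- round(stats::runif(2L * need, width_range[1], width_range[2]))
    start <- floor(stats::runif(2L * need) *
                     (chrom_sizes[chrom] - width))
    cand <- data.table::data.table(chrom = chrom, start = start,
                                   end = start + width)
    acc <- data.table::rbindlist(list(acc, cand))
    data.table::setorder(acc, chrom, start)
    # greedy overlap rejection within the accumulated set
    keep <- rep(TRUE, nrow(acc))
    last_end <- -Inf; last_chrom <- ""
    for (k in seq_len(nrow(acc))) {
      if (acc$chrom[k] == last_chrom && acc$start[k] < last_end) {
        keep[k] <- FALSE
      } else {
        last_end <- acc$end[k]; last_chrom <- acc$chrom[k]
      }
    }
    acc <- acc[keep]
  }
  if (nrow(acc) < n) stop_data("could not place %d non-overlapping elements", n)
  out <- acc[sample(seq_len(nrow(acc)), n)]
  data.table::setorder(out, chrom, start)
  if (!is.null(labels)) out$name <- sample(labels, n, replace = TRUE)
  out
}
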