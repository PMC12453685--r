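#' Build candidate element pairs from BED files
#'
#' Constructs the BEDPE of all pairwise combinations of elements, either
#' within a single BED file (self-pairing) or across two files (e.g. gene
#' TSSs x regulatory elements), optionally constrained by pair distance
#' and/or a third BED of containing intervals (typically TADs). The result
#' is a canvas of candidate interactions for downstream matrix queries.
#'
#' Pairs are kept iff both feet are on the same chromosome (unless
#' `trans = TRUE`), the midpoint distance lies in `[min_dist, max_dist]`,
#' the feet do not overlap (unless `allow_overlap`), and — when `within`
#' is given — both feet fall inside one single common containing interval.
#' Identical feet are always dropped; output is deduplicated after
#' canonicalization and sorted.
#'
#' @param a interval table (from [read_bed()]).
#' @param b optional second interval table; omitted means self-pairing of
#'   `a`.
#' @param min_dist,max_dist distance bounds in bp (inclusive).
#' @param within optional containing intervals (e.g. TADs); a pair
#'   survives only if some single interval contains both feet entirely.
#' @param allow_overlap keep pairs whose feet overlap.
#' @param trans build interchromosomal pairs instead (requires `b`);
#'   distance bounds are then ignored with a warning.
#' @param distance `"midpoint"` (default; centre-to-centre) or `"gap"`
#'   (inner-edge distance, 0 for touching/overlapping feet).
#' @return a canonical, sorted BEDPE `data.table`.
#' @examples
#' a <- bed_intervals("chr1", c(0, 100, 200, 300, 400) * 100,
#'                    c(0, 100, 200, 300, 400) * 100 + 1000)
#' nrow(build_pairs(a))  # 5 choose 2 = 10
#' @export
build_pairs <- function(a, b = NULL, min_dist = 0, max_dist = Inf,
                        within = NULL, allow_overlap = FALSE, trans = FALSE,
                        distance = c("midpoint", "gap")) {
  distance <- match.arg(distance)
  if (min_dist > max_dist) stop_usage("min_dist exceeds max_dist")
  if (trans && is.null(b)) stop_usage("trans building requires a second BED")
  a <- data.table::as.data.table(a)
  self <- is.null(b)
  b <- if (self) a else data.table::as.data.table(b)
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(bedpe(character(), numeric(), numeric(),
                 character(), numeric(), numeric()))
  }
  ai <- a[, list(chrom = chrom, start = start, end = end, ia = .I)]
  bi <- b[, list(chrom = chrom, start = start, end = end, ib = .I)]
  if (trans) {
    if (is.finite(max_dist) || min_dist > 0) {
      warning("distance constraints are ignored for trans pairs")
    }
    pr <- data.table::CJ(ia = ai$ia, ib = bi$ib)
    pr <- cbind(ai[pr$ia, list(chrom1 = chrom, start1 = start, end1 = end)],
                bi[pr$ib, list(chrom2 = chrom, start2 = start, end2 = end)])
    pr <- pr[pr$chrom1 != pr$chrom2]
  } else {
    pr <- merge(ai, bi, by = "chrom", allow.cartesian = TRUE,
                suffixes = c("1", "2"))
    if (self) pr <- pr[pr$ia < pr$ib]
    data.table::setnames(pr, c("chrom", "start1", "end1", "ia",
                               "start2", "end2", "ib"),
                         c("chrom1", "start1", "end1", "ia",
                           "start2", "end2", "ib"), skip_absent = TRUE)
    pr$chrom2 <- pr$chrom1
    dist <- if (distance == "midpoint") {
      abs((pr$start2 + pr$end2) / 2 - (pr$start1 + pr$end1) / 2)
    } else {
      pmax(0, pmax(pr$start1, pr$start2) - pmin(pr$end1, pr$end2))
    }
    pr <- pr[dist >= min_dist & dist <= max_dist]
  }
  # drop identical feet; drop overlapping feet unless allowed
  same <- pr$chrom1 == pr$chrom2 & pr$start1 == pr$start2 &
    pr$end1 == pr$end2
  pr <- pr[!same]
  if (!allow_overlap && nrow(pr) > 0L) {
    ovl <- pr$chrom1 == pr$chrom2 & pr$start1 < pr$end2 &
      pr$start2 < pr$end1
    pr <- pr[!ovl]
  }
  if (!is.null(within) && nrow(pr) > 0L) {
    w <- data.table::as.data.table(within)
    ok <- vapply(seq_len(nrow(pr)), function(i) {
      any(w$chrom == pr$chrom1[i] & w$chrom == pr$chrom2[i] &
            w$start <= pr$start1[i] & w$end >= pr$end1[i] &
            w$start <= pr$start2[i] & w$end >= pr$end2[i])
    }, logical(1))
    pr <- pr[ok]
  }
  out <- bedpe(pr$chrom1, pr$start1, pr$end1, pr$chrom2, pr$start2, pr$end2)
  out <- unique(out)
  sort_bedpe(out)
}
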