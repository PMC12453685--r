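#' Sparse binned contact matrix
#'
#' Stores per-chromosome-pair sparse triplets `(bin_i, bin_j) -> count` at a
#' fixed resolution, upper triangle only for intrachromosomal pairs
#' (`bin1 <= bin2`); interchromosomal entries are stored under the ordered
#' chromosome pair (chrom-sizes order). Duplicate entries are summed,
#' zero-count entries dropped.
#'
#' @param pixels `data.table`/data.frame with columns `chrom1, bin1, chrom2,
#'   bin2, count` (bin index = floor(start / resolution)).
#' @param meta a [sample_meta()].
#' @return an object of class `contact_matrix`.
#' @export
contact_matrix <- function(pixels, meta) {
  px <- data.table::as.data.table(pixels)
  if (nrow(px) == 0L) {
    px <- data.table::data.table(chrom1 = character(), bin1 = integer(),
                                 chrom2 = character(), bin2 = integer(),
                                 count = numeric())
  }
  px <- px[, list(chrom1 = as.character(chrom1), bin1 = as.integer(bin1),
                  chrom2 = as.character(chrom2), bin2 = as.integer(bin2),
                  count = as.numeric(count))]
  if (nrow(px) > 0L) {
    if (any(px$count < 0)) stop_data("negative contact count")
    if (any(px$bin1 < 0 | px$bin2 < 0)) stop_data("negative bin index")
    unknown <- setdiff(unique(c(px$chrom1, px$chrom2)),
                       names(meta$chrom_sizes))
    if (length(unknown) > 0L) {
      stop_data("chromosome '%s' not in chrom_sizes", unknown[1])
    }
    maxbin1 <- matrix_n_bins(meta, px$chrom1) - 1L
    maxbin2 <- matrix_n_bins(meta, px$chrom2) - 1L
    if (any(px$bin1 > maxbin1 | px$bin2 > maxbin2)) {
      stop_data("bin index beyond chromosome end")
    }
    corder <- names(meta$chrom_sizes)
    rr <- chrom_rank(c(px$chrom1, px$chrom2), corder)
    r1 <- rr[seq_len(nrow(px))]
    r2 <- rr[nrow(px) + seq_len(nrow(px))]
    swap <- r2 < r1 | (r1 == r2 & px$bin2 < px$bin1)
    if (any(swap)) {
      tmpc <- px$chrom1[swap]; tmpb <- px$bin1[swap]
      data.table::set(px, which(swap), "chrom1", px$chrom2[swap])
      data.table::set(px, which(swap), "bin1", px$bin2[swap])
      data.table::set(px, which(swap), "chrom2", tmpc)
      data.table::set(px, which(swap), "bin2", tmpb)
    }
    px <- px[, list(count = sum(count)),
             by = c("chrom1", "bin1", "chrom2", "bin2")]
    px <- px[count > 0]
    data.table::setorder(px, chrom1, chrom2, bin1, bin2)
  }
  data.table::setkeyv(px, c("chrom1", "chrom2", "bin1", "bin2"))
  structure(list(meta = meta, pixels = px), class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %s: %d pixels, %g bp bins, %d chroms\n",
              x$meta$name, nrow(x$pixels), x$meta$resolution,
              length(x$meta$chrom_sizes)))
  invisible(x)
}

# number of bins on a chromosome (vectorized over chrom)
matrix_n_bins <- function(meta, chrom) {
  sz <- meta$chrom_sizes[chrom]
  if (any(is.na(sz))) stop_data("unknown chromosome '%s'",
                                chrom[which(is.na(sz))[1]])
  as.integer(ceiling(sz / meta$resolution))
}

#' Read the native sparse contact-triplet format
#'
#' The native dialect is a headerless TSV of
#' `chrom_i  bin_i  chrom_j  bin_j  count` with bin indices
#' `floor(start / resolution)`. Entries given in either orientation are
#' folded onto the canonical triangle and duplicates summed, so shuffled
#' files load to identical matrices.
#'
#' @param path triplet TSV; an empty file yields an empty matrix.
#' @param meta a [sample_meta()] carrying resolution and chrom sizes.
#' @return a [contact_matrix()].
#' @export
read_contacts <- function(path, meta) {
  if (!file.exists(path)) stop_usage("contact file not found: %s", path)
  if (file.size(path) == 0L) {
    return(contact_matrix(NULL, meta))
  }
  px <- data.table::fread(path, sep = "\t", header = FALSE,
                          col.names = c("chrom1", "bin1", "chrom2", "bin2",
                                        "count"),
                          colClasses = list(character = c(1L, 3L)))
  if (any(px$count < 0)) {
    stop_data("contact parse error at line %d of %s: negative count",
              which(px$count < 0)[1], path)
  }
  contact_matrix(px, meta)
}

#' Write the native sparse contact-triplet format
#' @param m a [contact_matrix()].
#' @param path output TSV path.
#' @export
write_contacts <- function(m, path) {
  px <- m$pixels
  lines <- if (nrow(px) == 0L) character() else
    paste(px$chrom1, px$bin1, px$chrom2, px$bin2,
          format(px$count, scientific = FALSE, trim = TRUE, digits = 15),
          sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

# Dense rectangular window in bin coordinates, symmetric completion applied.
# bins1/bins2 are inclusive integer bin ranges on chrom1/chrom2.
window_bins <- function(m, chrom1, bins1, chrom2, bins2,
                        spec = norm_spec("none")) {
  corder <- names(m$meta$chrom_sizes)
  if (!chrom1 %in% corder) stop_data("unknown chromosome '%s'", chrom1)
  if (!chrom2 %in% corder) stop_data("unknown chromosome '%s'", chrom2)
  b1 <- bins1[1]:bins1[2]
  b2 <- bins2[1]:bins2[2]
  grid <- matrix(0, nrow = length(b1), ncol = length(b2),
                 dimnames = NULL)
  px <- m$pixels
  fill <- function(sel, rows, cols) {
    if (nrow(sel) > 0L) {
      idx <- cbind(rows, cols)
      # duplicate targets cannot arise: storage is canonical and unique
      grid[idx] <<- grid[idx] + sel$count
    }
  }
  if (chrom1 == chrom2) {
    sel <- px[px$chrom1 == chrom1 & px$chrom2 == chrom2]
    # orientation (i in b1, j in b2)
    s1 <- sel[bin1 >= bins1[1] & bin1 <= bins1[2] &
                bin2 >= bins2[1] & bin2 <= bins2[2]]
    fill(s1, match(s1$bin1, b1), match(s1$bin2, b2))
    # mirrored orientation (j in b1, i in b2), excluding the diagonal
    s2 <- sel[bin2 >= bins1[1] & bin2 <= bins1[2] &
                bin1 >= bins2[1] & bin1 <= bins2[2] & bin1 != bin2]
    fill(s2, match(s2$bin2, b1), match(s2$bin1, b2))
  } else {
    rr <- chrom_rank(c(chrom1, chrom2), corder)
    swapped <- rr[1] > rr[2]
    ca <- if (swapped) chrom2 else chrom1
    cb <- if (swapped) chrom1 else chrom2
    ba <- if (swapped) b2 else b1
    bb <- if (swapped) b1 else b2
    sel <- px[px$chrom1 == ca & px$chrom2 == cb]
    sel <- sel[bin1 >= min(ba) & bin1 <= max(ba) &
                 bin2 >= min(bb) & bin2 <= max(bb)]
    if (swapped) fill(sel, match(sel$bin2, b1), match(sel$bin1, b2))
    else fill(sel, match(sel$bin1, b1), match(sel$bin2, b2))
  }
  list(values = normalize_value(grid, m$meta, spec), bins1 = b1, bins2 = b2,
       chrom1 = chrom1, chrom2 = chrom2, resolution = m$meta$resolution)
}

#' Fetch a dense normalized window from a contact matrix
#'
#' Returns the rectangular grid of normalized values for two genomic
#' ranges, with symmetric completion applied so callers never deal with
#' triangle storage; absent pixels are 0.
#'
#' @param m a [contact_matrix()].
#' @param range1,range2 ranges as `"chr:start-end"` strings or
#'   chrom/start/end lists; `range2` defaults to `range1`.
#' @param spec a [norm_spec()].
#' @return a list with `values` (rows = range1 bins, cols = range2 bins),
#'   `bins1`, `bins2`, chromosome names and the resolution.
#' @export
fetch_window <- function(m, range1, range2 = range1,
                         spec = norm_spec("none")) {
  r1 <- parse_range(range1)
  r2 <- parse_range(range2)
  res <- m$meta$resolution
  rng_bins <- function(r) {
    nb <- matrix_n_bins(m$meta, r$chrom)
    lo <- max(0L, as.integer(floor(r$start / res)))
    hi <- min(nb - 1L, as.integer(floor((r$end - 1) / res)))
    if (hi < lo) stop_usage("range %s:%g-%g contains no bins",
                            r$chrom, r$start, r$end)
    c(lo, hi)
  }
  window_bins(m, r1$chrom, rng_bins(r1), r2$chrom, rng_bins(r2), spec)
}

#' Two-sample delta window
#'
#' Subtracts the normalized window of `m2` from that of `m1` on the common
#' bin grid, for direct treatment-vs-control comparison. Each sample is
#' mapped into its own caller-chosen numeric space first; mixing spaces is
#' allowed but warned about.
#'
#' @param m1,m2 two [contact_matrix()] objects at the same resolution.
#' @param range1,range2 window ranges (as in [fetch_window()]).
#' @param spec1,spec2 numeric spaces, default the per-sample defaults.
#' @return as [fetch_window()], with a signed `values` grid.
#' @export
delta_matrix <- function(m1, m2, range1, range2 = range1,
                         spec1 = default_mode(m1$meta),
                         spec2 = default_mode(m2$meta)) {
  if (m1$meta$resolution != m2$meta$resolution) {
    stop_usage("delta requires equal resolutions (%g vs %g)",
               m1$meta$resolution, m2$meta$resolution)
  }
  if (spec1$mode != spec2$mode) {
    warning(sprintf("delta mixes numeric spaces: %s vs %s",
                    spec1$mode, spec2$mode))
  }
  w1 <- fetch_window(m1, range1, range2, spec1)
  w2 <- fetch_window(m2, range1, range2, spec2)
  if (!identical(dim(w1$values), dim(w2$values))) {
    stop_data("windows disagree between samples (check chrom sizes)")
  }
  w1$values <- w1$values - w2$values
  w1$signed <- TRUE
  w1
}
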