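#' Per-sample metadata
#'
#' Holds what normalization needs to know about one sample: the matrix
#' resolution, the total number of valid interaction pairs on the target
#' genome, the (optional) spike-in genome pair count, and the chromosome
#' sizes of the build.
#'
#' @param name sample name.
#' @param resolution bin size in bp (> 0).
#' @param total_pairs total valid target-genome pairs (> 0).
#' @param spike_pairs optional spike-in-genome valid pairs (> 0); presence
#'   switches the sample's default numeric space from CPM to AQuA.
#' @param chrom_sizes named numeric vector, chromosome -> length in bp.
#' @return an object of class `sample_meta`.
#' @export
sample_meta <- function(name, resolution, total_pairs, spike_pairs = NULL,
                        chrom_sizes) {
  if (resolution <= 0) stop_usage("resolution must be > 0")
  if (total_pairs <= 0) stop_usage("total_pairs must be > 0")
  if (!is.null(spike_pairs) && spike_pairs <= 0) {
    stop_usage("spike_pairs, when present, must be > 0")
  }
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes)))) {
    stop_usage("chrom_sizes must be a named vector")
  }
  structure(list(name = as.character(name), resolution = as.numeric(resolution),
                 total_pairs = as.numeric(total_pairs),
                 spike_pairs = if (is.null(spike_pairs)) NULL
                               else as.numeric(spike_pairs),
                 chrom_sizes = chrom_sizes),
            class = "sample_meta")
}

#' @export
print.sample_meta <- function(x, ...) {
  cat(sprintf("<sample_meta> %s: %g bp bins, %g pairs%s, %d chroms\n",
              x$name, x$resolution, x$total_pairs,
              if (is.null(x$spike_pairs)) "" else
                sprintf(" (+%g spike-in)", x$spike_pairs),
              length(x$chrom_sizes)))
  invisible(x)
}

#' Read a two-column chrom-sizes file
#' @param path TSV of chromosome name and length in bp.
#' @return named numeric vector in file order (the order defines the
#'   canonical interchromosomal foot order).
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "size"),
                          colClasses = c("character", "numeric"))
  stats::setNames(df$size, df$chrom)
}

#' Numeric-space specification
#'
#' @param mode one of `"none"` (raw counts), `"cpm"` (counts per million)
#'   or `"aqua"` (spike-in normalization).
#' @param aqua_factor optional explicit AQuA factor; when omitted the
#'   default `total_pairs / spike_pairs` of the sample is used.
#' @return an object of class `norm_spec`.
#' @export
norm_spec <- function(mode = c("none", "cpm", "aqua"), aqua_factor = NULL) {
  mode <- match.arg(mode)
  structure(list(mode = mode, aqua_factor = aqua_factor), class = "norm_spec")
}

#' Default numeric space for a sample
#'
#' Samples with a spike-in pair count default to AQuA normalization and
#' samples without one default to CPM.
#'
#' @param meta a [sample_meta()].
#' @return a [norm_spec()].
#' @export
default_mode <- function(meta) {
  norm_spec(if (!is.null(meta$spike_pairs)) "aqua" else "cpm")
}

#' Map raw contact counts into a numeric space
#'
#' `none` returns the value unchanged; `cpm` scales by `1e6 / total_pairs`;
#' `aqua` additionally multiplies CPM by the AQuA factor, which defaults to
#' `total_pairs / spike_pairs`. All modes are linear in the input.
#'
#' @param v raw count(s), >= 0 (vectorized).
#' @param meta a [sample_meta()].
#' @param spec a [norm_spec()]; defaults to [default_mode()] of the sample.
#' @return normalized numeric vector the same length as `v`.
#' @examples
#' m <- sample_meta("s", 5000, 1e6, chrom_sizes = c(chr1 = 1e6))
#' normalize_value(5, m, norm_spec("cpm"))  # 5.0: million-read identity
#' @export
normalize_value <- function(v, meta, spec = default_mode(meta)) {
  switch(spec$mode,
    none = v,
    cpm = v * 1e6 / meta$total_pairs,
    aqua = {
      f <- spec$aqua_factor
      if (is.null(f)) {
        if (is.null(meta$spike_pairs)) {
          stop_usage(paste0("sample '%s': aqua normalization requires ",
                            "spike_pairs or an explicit aqua_factor"),
                     meta$name)
        }
        f <- meta$total_pairs / meta$spike_pairs
      }
      v * 1e6 / meta$total_pairs * f
    })
}
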