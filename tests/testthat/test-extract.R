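# a model with known truth for deterministic extraction tests: the
# background curve matches the generator's decay, the top curve sits
# 8-fold above it with the same exponent
truth_model <- function(resolution = 5000, decay_k = 100, alpha = 1,
                        top_fold = 8) {
  inherent_model(k_bg = decay_k * resolution^alpha, alpha_bg = alpha,
                 k_top = top_fold * decay_k * resolution^alpha,
                 alpha_top = alpha, resolution = resolution)
}

test_that("threshold 0 reports every nonzero off-diagonal pixel in scope", {
  sim <- std_sim(noise = "none", seed = 1)
  m <- sim$matrix
  model <- truth_model()
  loops <- extract_single(m, model, "chr1:0-250000", threshold = 0,
                          min_dist = 0)
  px <- m$pixels[m$pixels$bin1 <= 49 & m$pixels$bin2 <= 49 &
                   m$pixels$bin2 > m$pixels$bin1, ]
  expect_equal(nrow(loops), nrow(px))
  expect_error(extract_single(m, model, "chr1:0-250000", threshold = 1.2),
               "threshold")
  expect_error(extract_single(m, model, "chr1:0-250000", threshold = -0.1),
               "threshold")
})

test_that("planted loops above background pass a high threshold", {
  loops10 <- data.table::data.table(chrom = "chr1", bin1 = 40L, bin2 = 120L,
                                    fold = 10)
  sim <- make_matrix(std_sizes, 5000, 1, 100, loops = loops10,
                     noise = "none", seed = 1)
  model <- truth_model()
  got <- extract_single(sim$matrix, model, "chr1:0-2250000",
                        threshold = 0.8)
  expect_equal(nrow(got), 1L)
  expect_equal(got$bin1, 40L); expect_equal(got$bin2, 120L)
  # score of a 10-fold pixel under an 8-fold top curve clamps at 1
  expect_equal(got$score, 1)
})

test_that("globbing merges components under the Chebyshev radius rule", {
  res <- 5000
  mk <- function(b1, b2) data.table::data.table(
    chrom1 = "chr1", start1 = b1 * res, end1 = (b1 + 1) * res,
    chrom2 = "chr1", start2 = b2 * res, end2 = (b2 + 1) * res,
    score = 0.9, bin1 = b1, bin2 = b2)
  # two supra-threshold bins 5 bins apart
  two <- rbind(mk(10L, 50L), mk(15L, 50L))
  expect_equal(nrow(glob_loops(two, radius = 3, resolution = res)), 2L)
  expect_equal(nrow(glob_loops(two, radius = 5, resolution = res)), 1L)
  merged <- glob_loops(two, radius = 5, resolution = res)
  expect_equal(merged$start1, 10 * res); expect_equal(merged$end1, 16 * res)
  expect_equal(merged$n_bins, 2L)

  # radius 0 on isolated bins is the identity
  iso <- rbind(mk(10L, 50L), mk(20L, 80L), mk(40L, 90L))
  g0 <- glob_loops(iso, radius = 0, resolution = res)
  expect_equal(nrow(g0), 3L)
  expect_equal(g0$n_bins, rep(1L, 3))

  # component score is the max of member scores, not the sum
  pair <- rbind(mk(10L, 50L), mk(11L, 50L))
  pair$score <- c(0.7, 0.95)
  expect_equal(glob_loops(pair, radius = 0, resolution = res)$score, 0.95)
})

test_that("glob components equal brute-force BFS partitions at radius 0-5", {
  set.seed(19)
  n <- 120
  b1 <- sample(0:60, n, replace = TRUE)
  b2 <- b1 + sample(5:40, n, replace = TRUE)
  keep <- !duplicated(paste(b1, b2))
  b1 <- b1[keep]; b2 <- b2[keep]
  loops <- data.table::data.table(
    chrom1 = "chr1", start1 = b1 * 5000, end1 = (b1 + 1) * 5000,
    chrom2 = "chr1", start2 = b2 * 5000, end2 = (b2 + 1) * 5000,
    score = runif(sum(keep)), bin1 = b1, bin2 = b2)
  for (r in 0:5) {
    got <- pairspace:::glob_components(loops$chrom1, loops$bin1,
                                       loops$bin2, r)
    want <- oracle_glob(loops$bin1, loops$bin2, r + 1L)
    expect_identical(partition_signature(got), partition_signature(want))
    # partition property: sizes conserve the input
    gl <- glob_loops(loops, radius = r, resolution = 5000)
    expect_equal(sum(gl$n_bins), nrow(loops))
  }
})

test_that("TAD-scoped extraction equals the deduplicated per-TAD union", {
  sim <- std_sim(loops = 20, noise = "poisson", seed = 1729)
  m <- sim$matrix
  model <- std_fit(sim, "loops20_1729")
  tads <- bed_intervals("chr1", c(0, 4e5, 9e5), c(5e5, 1e6, 1.4e6))
  whole <- extract_single(m, model, tads, threshold = 0.9)
  per_tad <- unique(data.table::rbindlist(lapply(1:3, function(i)
    extract_single(m, model, tads[i], threshold = 0.9))))
  data.table::setorder(per_tad, chrom1, start1, start2)
  expect_equal(whole, per_tad, ignore_attr = TRUE)
})

test_that("flat landscapes yield no flare anchors", {
  rows <- list()
  for (i in 0:59) for (j in i:59) rows[[length(rows) + 1L]] <-
    list("chrA", i, "chrA", j, 50)
  m <- toy_matrix(rows, tiny_meta())
  model <- inherent_model(k_bg = 10 * 100, alpha_bg = 0, k_top = 80 * 100,
                          alpha_top = 0, resolution = 100)
  anchors <- detect_flares(m, model, "chrA:0-6000", flare_z = 1)
  expect_equal(nrow(anchors), 0L)
})

test_that("a planted flare is detected and crossings are reported", {
  res <- 5000
  sizes <- c(chr1 = 1e6)
  flares <- data.table::data.table(chrom = "chr1", bin = c(40L, 120L),
                                   fold = 12)
  sim <- make_matrix(sizes, res, 1, 100, flares = flares, noise = "none",
                     seed = 1)
  model <- truth_model()
  anchors <- detect_flares(sim$matrix, model, "chr1:0-1000000", flare_z = 3)
  expect_setequal(anchors$bin, c(40L, 120L))
  # monotone growth of the anchor set as flare_z decreases
  a2 <- detect_flares(sim$matrix, model, "chr1:0-1000000", flare_z = 1)
  expect_true(all(anchors$bin %in% a2$bin))
  # the two flares cross at exactly one off-band pixel
  cr <- flare_crossings(sim$matrix, model, anchors, threshold = 0.8)
  expect_equal(nrow(cr), 1L)
  expect_equal(cr$bin1, 40L); expect_equal(cr$bin2, 120L)
  expect_equal(cr$mode, "flare")
  # threshold 0 reports every nonzero anchor-by-anchor off-band pixel
  cr0 <- flare_crossings(sim$matrix, model, anchors, threshold = 0)
  expect_equal(nrow(cr0), 1L)
})

test_that("planted loops are recovered from noisy matrices by globbing", {
  sim <- std_sim(loops = 20, fold = 5, noise = "poisson", seed = 1729)
  m <- sim$matrix
  model <- std_fit(sim, "loops20_1729")
  gl <- glob_loops(extract_single(m, model, "chr1:0-2250000", 0.7),
                   radius = 1)
  hit <- vapply(seq_len(nrow(sim$truth)), function(i)
    any(gl$chrom1 == sim$truth$chrom1[i] &
          gl$start1 <= sim$truth$start1[i] &
          gl$end1 >= sim$truth$end1[i] &
          gl$start2 <= sim$truth$start2[i] &
          gl$end2 >= sim$truth$end2[i]), logical(1))
  expect_gte(mean(hit), 0.9)
})
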