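test_that("degenerate 1x1 windows agree across all four formulas", {
  m <- toy_matrix(list(list("chrA", 5, "chrA", 9, 4)))
  rec <- bedpe("chrA", 500, 600, "chrA", 900, 1000)
  for (f in c("center", "max", "sum", "mean")) {
    expect_equal(query_values(rec, m, norm_spec("none"), formula = f)$score,
                 4)
  }
})

test_that("mean includes zero pixels; sum is the plain total", {
  # 1x3 window with values {0, 0, 6}
  m <- toy_matrix(list(list("chrA", 2, "chrA", 12, 6)))
  rec <- bedpe("chrA", 200, 300, "chrA", 1000, 1300)
  expect_equal(query_values(rec, m, norm_spec("none"), formula = "sum")$score, 6)
  expect_equal(query_values(rec, m, norm_spec("none"), formula = "mean")$score, 2)
  expect_equal(query_values(rec, m, norm_spec("none"), formula = "mean",
                            mean_nonzero = TRUE)$score, 6)
})

test_that("fix = FALSE relocates feet to the defining bin", {
  m <- toy_matrix(list(list("chrA", 2, "chrA", 10, 1),
                       list("chrA", 4, "chrA", 12, 9)))
  rec <- bedpe("chrA", 200, 500, "chrA", 1000, 1300)  # 3x3 window
  relocated <- query_values(rec, m, norm_spec("none"), formula = "max",
                            fix = FALSE)
  expect_equal(relocated$start1, 400); expect_equal(relocated$end1, 500)
  expect_equal(relocated$start2, 1200); expect_equal(relocated$end2, 1300)
  expect_equal(relocated$score, 9)
  centered <- query_values(rec, m, norm_spec("none"), formula = "center",
                           fix = FALSE)
  expect_equal(centered$start1, 300)  # midpoint 350 -> bin 3
  expect_equal(centered$start2, 1100)
  expect_error(query_values(rec, m, norm_spec("none"), formula = "sum",
                            fix = FALSE), "defining bin")
})

test_that("every formula matches a dense brute-force scan on random windows", {
  set.seed(17)
  meta <- tiny_meta()
  rows <- lapply(1:400, function(i)
    list("chrA", sample(0:99, 1), "chrA", sample(0:99, 1), sample(1:30, 1)))
  m <- toy_matrix(rows, meta)
  dense <- oracle_dense(m, "chrA")
  for (rep in 1:50) {
    a <- sort(sample(0:99, 2)); b <- sort(sample(0:99, 2))
    rec <- data.table::data.table(
      chrom1 = "chrA", start1 = a[1] * 100, end1 = (a[2] + 1) * 100,
      chrom2 = "chrA", start2 = b[1] * 100, end2 = (b[2] + 1) * 100)
    win <- dense[(a[1] + 1):(a[2] + 1), (b[1] + 1):(b[2] + 1), drop = FALSE]
    c1 <- floor(floor((rec$start1 + rec$end1) / 2) / 100)
    c2 <- floor(floor((rec$start2 + rec$end2) / 2) / 100)
    expected <- c(max = max(win), sum = sum(win), mean = mean(win),
                  center = dense[c1 + 1, c2 + 1])
    for (f in names(expected)) {
      expect_identical(
        query_values(rec, m, norm_spec("none"), formula = f)$score,
        unname(expected[f]))
    }
  }
})

test_that("sum is additive over disjoint window partitions", {
  set.seed(29)
  rows <- lapply(1:200, function(i)
    list("chrA", sample(0:99, 1), "chrA", sample(0:99, 1), sample(1:9, 1)))
  m <- toy_matrix(rows, tiny_meta())
  whole <- bedpe("chrA", 0, 4000, "chrA", 6000, 10000)
  left <- bedpe("chrA", 0, 2000, "chrA", 6000, 10000)
  right <- bedpe("chrA", 2000, 4000, "chrA", 6000, 10000)
  qs <- function(r) query_values(r, m, norm_spec("none"),
                                 formula = "sum")$score
  expect_equal(qs(whole), qs(left) + qs(right))
  qmean <- query_values(whole, m, norm_spec("none"), formula = "mean")$score
  w <- fetch_window(m, "chrA:0-4000", "chrA:6000-10000")
  expect_gte(qmean, min(w$values)); expect_lte(qmean, max(w$values))
})

test_that("max and sum are monotone under window expansion", {
  set.seed(37)
  rows <- lapply(1:200, function(i)
    list("chrA", sample(0:99, 1), "chrA", sample(0:99, 1), sample(1:9, 1)))
  m <- toy_matrix(rows, tiny_meta())
  rec <- bedpe("chrA", 3000, 3500, "chrA", 7000, 7500)
  prev_max <- -Inf; prev_sum <- -Inf
  for (e in 0:4) {
    vmax <- query_values(rec, m, norm_spec("none"), formula = "max",
                         expand = e)$score
    vsum <- query_values(rec, m, norm_spec("none"), formula = "sum",
                         expand = e)$score
    expect_gte(vmax, prev_max); expect_gte(vsum, prev_sum)
    prev_max <- vmax; prev_sum <- vsum
  }
})

test_that("delta queries subtract per sample and are antisymmetric", {
  m1 <- toy_matrix(list(list("chrA", 2, "chrA", 8, 8),
                        list("chrA", 3, "chrA", 9, 2)))
  m2 <- toy_matrix(list(list("chrA", 2, "chrA", 8, 3),
                        list("chrA", 3, "chrA", 9, 7)))
  recs <- bedpe("chrA", c(200, 0), c(400, 1000), "chrA", c(800, 0),
                c(1000, 1000))
  for (f in c("max", "sum", "mean", "center")) {
    d12 <- query_values(recs, m1, norm_spec("none"), formula = f,
                        m2 = m2, spec2 = norm_spec("none"))$score
    d21 <- query_values(recs, m2, norm_spec("none"), formula = f,
                        m2 = m1, spec2 = norm_spec("none"))$score
    expect_equal(d12, -d21)
    same <- query_values(recs, m1, norm_spec("none"), formula = f,
                         m2 = m1, spec2 = norm_spec("none"))$score
    expect_equal(same, c(0, 0))
  }
  # per-sample max differs from the max of the pixelwise difference
  rec <- bedpe("chrA", 200, 400, "chrA", 800, 1000)
  per_sample <- query_values(rec, m1, norm_spec("none"), formula = "max",
                             m2 = m2, spec2 = norm_spec("none"))$score
  pixelwise <- query_values(rec, m1, norm_spec("none"), formula = "max",
                            m2 = m2, spec2 = norm_spec("none"),
                            delta_pixelwise = TRUE)$score
  expect_equal(per_sample, 8 - 7)
  expect_equal(pixelwise, 8 - 3)
})
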