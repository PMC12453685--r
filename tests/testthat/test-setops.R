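test_that("intersection classes report promoter-enhancer architecture", {
  promoters <- bed_intervals("chr1", 100, 200, name = "P")
  enhancers <- bed_intervals("chr1", 1000, 1100, name = "E")
  rec <- bedpe("chr1", 120, 180, "chr1", 1020, 1080)
  got <- classify_intersections(rec, promoters, enhancers)
  expect_equal(got$tag, "P-E")

  # no overlap anywhere
  far <- bedpe("chr1", 5000, 5100, "chr1", 9000, 9100)
  expect_equal(classify_intersections(far, promoters, enhancers)$tag, "0-0")
  expect_equal(nrow(classify_intersections(far, promoters, enhancers,
                                           invert = TRUE)), 1L)
  expect_equal(nrow(classify_intersections(rec, promoters, enhancers,
                                           invert = TRUE)), 0L)

  # two labels on one foot join sorted
  both <- bed_intervals("chr1", c(100, 150), c(200, 250),
                        name = c("P", "E"))
  gq <- classify_intersections(bedpe("chr1", 120, 180, "chr1", 5000, 5100),
                               both)
  expect_equal(gq$tag, "E,P-0")
})

test_that("boolean and BED reporting modes work with the require switch", {
  ann <- bed_intervals("chr1", c(100, 9000), c(200, 9100),
                       name = c("P", "E"))
  recs <- bedpe("chr1", c(120, 120, 5000), c(180, 180, 5100),
                "chr1", c(9020, 5000, 7000), c(9080, 5100, 7100))
  hit_either <- classify_intersections(recs, ann, report = "bool")$hit
  expect_equal(hit_either, c(TRUE, TRUE, FALSE))
  hit_both <- classify_intersections(recs, ann, report = "bool",
                                     require = "both")$hit
  expect_equal(hit_both, c(TRUE, FALSE, FALSE))
  hit_down <- classify_intersections(recs, ann, report = "bool",
                                     require = "downstream")$hit
  expect_equal(hit_down, c(TRUE, FALSE, FALSE))
  bed_out <- classify_intersections(recs, ann, report = "bed")
  expect_equal(nrow(bed_out), 2L)
  expect_setequal(bed_out$label, c("P", "E"))
})

test_that("classification matches a quadratic brute-force scan", {
  set.seed(47)
  recs <- random_bedpe(150, seed = 47)
  k <- 60
  chrom <- sample(c("chr1", "chr2"), k, replace = TRUE)
  s <- floor(runif(k, 0, 1e6))
  ann <- bed_intervals(chrom, s, s + floor(runif(k, 200, 4000)),
                       name = sample(c("P", "E", "CTCF"), k, replace = TRUE))
  got <- classify_intersections(recs, ann)$tag
  expect_equal(got, oracle_classify(recs, ann))
})

test_that("2D union resolves overlaps to the transitive fixpoint", {
  a <- bedpe("chr1", 0, 10, "chr1", 100, 110)
  b <- bedpe("chr1", 5, 15, "chr1", 105, 115)
  u <- union_records(a, b)
  expect_equal(nrow(u), 1L)
  expect_equal(unlist(u[1, c("start1", "end1", "start2", "end2")]),
               c(start1 = 0, end1 = 15, start2 = 100, end2 = 115))
  # the merged 2D area exceeds each member's geometric piece
  expect_gte((u$end1 - u$start1) * (u$end2 - u$start2), 10 * 10)

  # identity when nothing is mergeable, idempotence, input-order invariance
  x <- bedpe("chr1", c(0, 1000), c(10, 1010), "chr1", c(100, 2000),
             c(110, 2010))
  expect_equal(union_records(x), x)
  expect_equal(union_records(x, x), union_records(x))
  expect_equal(union_records(a, b), union_records(b, a))
})

test_that("union matches an iterative brute-force merge on random input", {
  for (seed in c(53, 59)) {
    x <- random_bedpe(120, seed = seed, span = 2e5, width = c(2000, 9000))
    got <- as.data.frame(union_records(x))
    want <- oracle_union(as.data.frame(x))
    expect_equal(got, want, ignore_attr = TRUE)
    # order invariance of the fixpoint
    shuf <- x[sample(nrow(x))]
    expect_equal(as.data.frame(union_records(shuf)), want,
                 ignore_attr = TRUE)
  }
})

test_that("union keeps the max member score when asked", {
  a <- bedpe("chr1", 0, 10, "chr1", 100, 110, score = 1.5)
  b <- bedpe("chr1", 5, 15, "chr1", 105, 115, score = 4.5)
  u <- union_records(a, b, keep_score = TRUE)
  expect_equal(u$score, 4.5)
  expect_false("score" %in% names(union_records(a, b)))
})

test_that("daisy-chains cluster together; interleaved chains stay apart", {
  # A-B, B-C, C-D share feet pairwise along the chain
  chain <- bedpe("chr1", c(0, 1000, 2000), c(100, 1100, 2100),
                 "chr1", c(1000, 2000, 3000), c(1100, 2100, 3100))
  cl <- cluster_records(chain)
  expect_equal(unique(cl$tag), "cluster_1")

  # two foot-disjoint chains interleaved along the genome
  interleaved <- bedpe("chr1", c(0, 500), c(100, 600),
                       "chr1", c(1000, 1500), c(1100, 1600))
  ci <- cluster_records(interleaved)
  expect_equal(ci$tag, c("cluster_1", "cluster_2"))

  # a single row is the minimal cluster
  single <- cluster_records(bedpe("chr1", 0, 10, "chr1", 50, 60))
  expect_equal(single$tag, "cluster_1")
})

test_that("clustering equals brute-force union-find on 500 random rows", {
  x <- random_bedpe(500, seed = 61, span = 3e5, width = c(1000, 6000))
  got <- cluster_records(x)$tag
  want <- oracle_cluster(x)
  expect_identical(partition_signature(got), partition_signature(want))
  # conservation: every input row appears exactly once, in order
  expect_equal(got |> length(), nrow(x))
  expect_equal(cluster_records(x)[, 1:6], x[, 1:6])
})

test_that("cluster summaries report the documented per-cluster fields", {
  # one-row cluster: feet 5 kb wide, midpoints 10 kb apart
  one <- cluster_records(bedpe("chr1", 10000, 15000, "chr1", 20000, 25000))
  ann <- annotate_clusters(one)
  expect_equal(ann$n_loops, 1L)
  expect_equal(ann$loops_span_bp, 10000)
  expect_equal(ann$range_bp, 15000)
  expect_true(is.na(ann$total_cpm))
  expect_true(is.na(ann$n_tss))

  # three TSSs on one foot
  tss <- bed_intervals("chr1", c(10100, 11000, 14000, 90000),
                       c(10200, 11100, 14100, 90100))
  expect_equal(annotate_clusters(one, tss = tss)$n_tss, 3L)

  # with a matrix, total CPM sums the per-loop sum query
  m <- toy_matrix(list(list("chrA", 2, "chrA", 8, 10),
                       list("chrA", 3, "chrA", 9, 30)),
                  tiny_meta(total = 1e6))
  recs <- cluster_records(bedpe("chrA", c(200, 200), c(400, 400),
                                "chrA", c(800, 800), c(1000, 1000)))
  ann2 <- annotate_clusters(recs, m = m)
  q <- query_values(recs, m, norm_spec("cpm"), formula = "sum")$score
  expect_equal(ann2$total_cpm, sum(q))
  expect_error(annotate_clusters(bedpe("chr1", 0, 10, "chr1", 50, 60)),
               "cluster_records")
})
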