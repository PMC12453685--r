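# independent brute-force oracles used by the unit and acceptance tests;
# deliberately naive (double loops, dense matrices) and kept free of any
# package internals beyond public accessors

# full dense symmetric intrachromosomal matrix of raw counts
oracle_dense <- function(m, chrom) {
  nb <- ceiling(m$meta$chrom_sizes[[chrom]] / m$meta$resolution)
  M <- matrix(0, nb, nb)
  px <- m$pixels[m$pixels$chrom1 == chrom & m$pixels$chrom2 == chrom, ]
  for (k in seq_len(nrow(px))) {
    i <- px$bin1[k] + 1L; j <- px$bin2[k] + 1L
    M[i, j] <- M[i, j] + px$count[k]
    if (i != j) M[j, i] <- M[j, i] + px$count[k]
  }
  M
}

# brute-force pair enumeration with the build predicates
oracle_build <- function(a, b = NULL, min_dist = 0, max_dist = Inf,
                         within = NULL, allow_overlap = FALSE) {
  self <- is.null(b)
  if (self) b <- a
  rows <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (self && j <= i) next
      if (a$chrom[i] != b$chrom[j]) next
      f1 <- c(a$start[i], a$end[i]); f2 <- c(b$start[j], b$end[j])
      if (f1[1] == f2[1] && f1[2] == f2[2]) next
      dd <- abs((f2[1] + f2[2]) / 2 - (f1[1] + f1[2]) / 2)
      if (dd < min_dist || dd > max_dist) next
      if (!allow_overlap && f1[1] < f2[2] && f2[1] < f1[2]) next
      if (!is.null(within)) {
        ok <- any(within$chrom == a$chrom[i] &
                    within$start <= min(f1[1], f2[1]) &
                    within$end >= max(f1[2], f2[2]))
        if (!ok) next
      }
      if (f2[1] < f1[1] || (f2[1] == f1[1] && f2[2] < f1[2])) {
        tmp <- f1; f1 <- f2; f2 <- tmp
      }
      rows[[length(rows) + 1L]] <-
        data.frame(chrom1 = a$chrom[i], start1 = f1[1], end1 = f1[2],
                   chrom2 = a$chrom[i], start2 = f2[1], end2 = f2[2])
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(chrom1 = character(), start1 = numeric(),
                      end1 = numeric(), chrom2 = character(),
                      start2 = numeric(), end2 = numeric()))
  }
  out <- unique(do.call(rbind, rows))
  out[order(out$chrom1, out$start1, out$start2, out$end1, out$end2), ,
      drop = FALSE]
}

# per-foot label strings by quadratic overlap scan
oracle_classify <- function(records, ann) {
  labels <- if (!is.null(ann$label)) ann$label else ann$name
  lab_of <- function(chrom, s, e) {
    hits <- labels[ann$chrom == chrom & ann$start < e & s < ann$end]
    if (length(hits) == 0L) "0" else
      paste(sort(unique(hits)), collapse = ",")
  }
  vapply(seq_len(nrow(records)), function(i) {
    paste0(lab_of(records$chrom1[i], records$start1[i], records$end1[i]),
           "-",
           lab_of(records$chrom2[i], records$start2[i], records$end2[i]))
  }, "")
}

# union-find cluster membership over the any-foot-overlap relation
oracle_cluster <- function(records) {
  n <- nrow(records)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  feet <- function(i) list(
    c1 = records$chrom1[i], s1 = records$start1[i], e1 = records$end1[i],
    c2 = records$chrom2[i], s2 = records$start2[i], e2 = records$end2[i])
  ovl <- function(ca, sa, ea, cb, sb, eb) ca == cb && sa < eb && sb < ea
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      a <- feet(i); b <- feet(j)
      touch <- ovl(a$c1, a$s1, a$e1, b$c1, b$s1, b$e1) ||
        ovl(a$c1, a$s1, a$e1, b$c2, b$s2, b$e2) ||
        ovl(a$c2, a$s2, a$e2, b$c1, b$s1, b$e1) ||
        ovl(a$c2, a$s2, a$e2, b$c2, b$s2, b$e2)
      if (touch) parent[find(i)] <- find(j)
    }
  }
  vapply(seq_len(n), find, 0L)
}

# BFS connected components of pixels under Chebyshev distance <= reach
oracle_glob <- function(bin1, bin2, reach) {
  n <- length(bin1)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0L) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(is.na(comp) &
                    abs(bin1 - bin1[v]) <= reach &
                    abs(bin2 - bin2[v]) <= reach)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# normalized partition signature for comparing component labelings
partition_signature <- function(labels) {
  unname(sort(vapply(split(seq_along(labels), labels), function(ix)
    paste(sort(ix), collapse = ","), "")))
}

# iterative O(n^2) 2D union to fixpoint
oracle_union <- function(x) {
  x <- unique(x[, c("chrom1", "start1", "end1", "chrom2", "start2", "end2")])
  repeat {
    merged <- FALSE
    i <- 1L
    while (i < nrow(x)) {
      j <- i + 1L
      while (j <= nrow(x)) {
        if (x$chrom1[i] == x$chrom1[j] && x$chrom2[i] == x$chrom2[j] &&
            x$start1[i] < x$end1[j] && x$start1[j] < x$end1[i] &&
            x$start2[i] < x$end2[j] && x$start2[j] < x$end2[i]) {
          x$start1[i] <- min(x$start1[i], x$start1[j])
          x$end1[i] <- max(x$end1[i], x$end1[j])
          x$start2[i] <- min(x$start2[i], x$start2[j])
          x$end2[i] <- max(x$end2[i], x$end2[j])
          x <- x[-j, ]
          merged <- TRUE
        } else j <- j + 1L
      }
      i <- i + 1L
    }
    if (!merged) break
  }
  x <- unique(x)
  x[order(x$chrom1, x$start1, x$start2, x$end1, x$end2), , drop = FALSE]
}

# random BEDPE fixture on a couple of chromosomes
random_bedpe <- function(n, seed, span = 1e6, width = c(500, 3000)) {
  set.seed(seed)
  chrom <- sample(c("chr1", "chr2"), n, replace = TRUE)
  s1 <- floor(runif(n, 0, span))
  w1 <- floor(runif(n, width[1], width[2]))
  s2 <- floor(runif(n, 0, span))
  w2 <- floor(runif(n, width[1], width[2]))
  bedpe(chrom, s1, s1 + w1, chrom, s2, s2 + w2)
}

# small shared fixtures -----------------------------------------------------

tiny_meta <- function(total = 1e6, spike = NULL, res = 100,
                      sizes = c(chrA = 10000, chrB = 8000)) {
  sample_meta("tiny", res, total, spike, sizes)
}

# matrix from explicit triplets (list of c(chrom,bin1,chrom,bin2,count))
toy_matrix <- function(rows, meta = tiny_meta()) {
  px <- data.table::rbindlist(lapply(rows, function(r)
    data.table::data.table(chrom1 = r[[1]], bin1 = as.integer(r[[2]]),
                           chrom2 = r[[3]], bin2 = as.integer(r[[4]]),
                           count = as.numeric(r[[5]]))))
  contact_matrix(px, meta)
}

std_sizes <- c(chr1 = 2.25e6)

std_sim <- local({
  cache <- new.env()
  function(loops = 0, fold = 5, noise = "poisson", seed = 1729) {
    key <- paste(loops, fold, noise, seed)
    if (is.null(cache[[key]])) {
      cache[[key]] <- make_matrix(std_sizes, 5000, 1, 100, loops = loops,
                                  loop_fold = fold, noise = noise,
                                  seed = seed)
    }
    cache[[key]]
  }
})

std_fit <- local({
  cache <- new.env()
  function(sim, key) {
    if (is.null(cache[[key]])) cache[[key]] <- fit_inherent(sim$matrix)
    cache[[key]]
  }
})
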