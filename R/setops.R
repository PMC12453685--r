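# label vector for a labeled BED: name column when present, else a single
# fallback token for the whole file
bed_labels <- function(bed, fallback) {
  if ("name" %in% names(bed) && !all(is.na(bed$name))) {
    ifelse(is.na(bed$name), fallback, bed$name)
  } else rep(fallback, nrow(bed))
}

#' Classify BEDPE rows by 1D BED intersections
#'
#' Classifies each interaction by which labeled elements its upstream
#' (foot1) and downstream (foot2) feet overlap (>= 1 bp, half-open). A row
#' whose upstream foot hits a promoter `P` and downstream foot an enhancer
#' `E` is tagged `"P-E"`; a foot with no hit contributes `"0"`, and
#' multiple labels on one foot are comma-joined in sorted order.
#'
#' @param records BEDPE table (canonical foot order defines upstream /
#'   downstream).
#' @param bed_a labeled intervals; labels come from the `name` column when
#'   present, else `label_a` tags the whole file.
#' @param bed_b optional second labeled set (e.g. promoters and enhancers
#'   as two files).
#' @param report `"class"` appends the class tag (7th column), `"bool"`
#'   appends a logical `hit` column, `"bed"` returns the intersecting BED
#'   rows themselves, deduplicated.
#' @param invert absence detection: return only records with no hit on
#'   either foot.
#' @param label_a,label_b fallback labels for unnamed files.
#' @param require which feet must hit for `report = "bool"`:
#'   `"either"` (default), `"both"`, `"upstream"`, `"downstream"`.
#' @return records with a `tag` or `hit` column, or a BED `data.table`.
#' @export
classify_intersections <- function(records, bed_a, bed_b = NULL,
                                   report = c("class", "bool", "bed"),
                                   invert = FALSE,
                                   label_a = "A", label_b = "B",
                                   require = c("either", "both",
                                               "upstream", "downstream")) {
  report <- match.arg(report)
  require <- match.arg(require)
  x <- data.table::copy(data.table::as.data.table(records))
  ann <- data.table::as.data.table(bed_a)
  ann$label <- bed_labels(ann, label_a)
  if (!is.null(bed_b)) {
    b <- data.table::as.data.table(bed_b)
    b$label <- bed_labels(b, label_b)
    ann <- data.table::rbindlist(list(ann[, c("chrom", "start", "end", "label")],
                                      b[, c("chrom", "start", "end", "label")]))
  } else ann <- ann[, c("chrom", "start", "end", "label")]
  foot_hits <- function(chrom, start, end) {
    if (nrow(x) == 0L || nrow(ann) == 0L) {
      return(list(labs = rep("0", nrow(x)), hit = rep(FALSE, nrow(x)),
                  pairs = data.table::data.table(row = integer(),
                                                 ai = integer())))
    }
    feet <- GenomicRanges::GRanges(chrom,
                                   IRanges::IRanges(start + 1L, end))
    ov <- GenomicRanges::findOverlaps(feet, as_granges(ann))
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    labs <- rep("0", nrow(x))
    if (length(qh) > 0L) {
      joined <- vapply(split(ann$label[sh], qh), function(l)
        paste(sort(unique(l)), collapse = ","), "")
      labs[as.integer(names(joined))] <- joined
    }
    list(labs = labs, hit = labs != "0",
         pairs = data.table::data.table(row = qh, ai = sh))
  }
  f1 <- foot_hits(x$chrom1, x$start1, x$end1)
  f2 <- foot_hits(x$chrom2, x$start2, x$end2)
  if (invert) return(x[!(f1$hit | f2$hit)])
  if (report == "class") {
    x$tag <- paste0(f1$labs, "-", f2$labs)
    return(x)
  }
  if (report == "bool") {
    x$hit <- switch(require,
                    either = f1$hit | f2$hit,
                    both = f1$hit & f2$hit,
                    upstream = f1$hit,
                    downstream = f2$hit)
    return(x)
  }
  idx <- sort(unique(c(f1$pairs$ai, f2$pairs$ai)))
  ann[idx]
}

#' 2D union of BEDPE sets
#'
#' Merges interaction rows across one or more BEDPE sets: two rows are
#' mergeable iff their foot1 intervals overlap AND their foot2 intervals
#' overlap (after canonicalization); merged rows take the per-axis span
#' union, and merging repeats to the transitive fixpoint. Because spans
#' grow, the output areas can exceed the geometric union of the inputs.
#' Scores and tags are dropped (the union is a coordinate scaffold for
#' re-querying) unless `keep_score = TRUE`, which attaches the maximum
#' member score.
#'
#' @param ... BEDPE tables (or a single list of them).
#' @param keep_score re-attach the max score of merged members.
#' @return a deduplicated, sorted BEDPE `data.table`; the result is
#'   idempotent and independent of input order.
#' @export
union_records <- function(..., keep_score = FALSE) {
  ins <- list(...)
  if (length(ins) == 1L && is.list(ins[[1]]) && !is.data.frame(ins[[1]])) {
    ins <- ins[[1]]
  }
  cols <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  x <- data.table::rbindlist(lapply(ins, function(d) {
    d <- data.table::as.data.table(d)
    keep <- c(cols, if (keep_score && "score" %in% names(d)) "score")
    d <- d[, keep, with = FALSE]
    if (keep_score && !"score" %in% names(d)) d$score <- NA_real_
    d
  }), fill = TRUE)
  if (nrow(x) == 0L) return(x)
  x <- canonicalize_bedpe(x)
  repeat {
    n_before <- nrow(x)
    g1 <- GenomicRanges::GRanges(x$chrom1,
                                 IRanges::IRanges(x$start1 + 1L, x$end1))
    ov1 <- GenomicRanges::findOverlaps(g1, drop.self = TRUE,
                                       drop.redundant = TRUE)
    p1 <- data.table::data.table(a = S4Vectors::queryHits(ov1),
                                 b = S4Vectors::subjectHits(ov1))
    # require the second feet to overlap pairwise as well
    keep <- x$chrom2[p1$a] == x$chrom2[p1$b] &
      x$start2[p1$a] < x$end2[p1$b] & x$start2[p1$b] < x$end2[p1$a]
    p1 <- p1[keep]
    g <- igraph::graph_from_data_frame(
      p1, directed = FALSE, vertices = data.frame(name = seq_len(nrow(x))))
    comp <- igraph::components(g)$membership[as.character(seq_len(nrow(x)))]
    x$.comp <- comp
    x <- if (keep_score) {
      x[, list(chrom1 = chrom1[1], start1 = min(start1), end1 = max(end1),
               chrom2 = chrom2[1], start2 = min(start2), end2 = max(end2),
               score = if (all(is.na(score))) NA_real_
                       else max(score, na.rm = TRUE)), by = ".comp"]
    } else {
      x[, list(chrom1 = chrom1[1], start1 = min(start1), end1 = max(end1),
               chrom2 = chrom2[1], start2 = min(start2), end2 = max(end2)),
        by = ".comp"]
    }
    x$.comp <- NULL
    x <- canonicalize_bedpe(x)
    if (nrow(x) == n_before) break
  }
  sort_bedpe(unique(x))
}

#' Cluster BEDPE rows into connected components
#'
#' Builds the graph whose nodes are the 1D-merged feet (feet overlapping by
#' >= 1 bp across all rows are one node) and whose edges are the BEDPE
#' rows, then labels connected components `cluster_1, cluster_2, ...` in
#' order of their leftmost node. A single row is the minimal cluster; two
#' clusters can interleave along the 1D genome yet stay disjoint, because
#' membership is purely graph-structural.
#'
#' @param records BEDPE table.
#' @param adjacency also merge book-ended (touching) feet into one node.
#' @return the records with a `tag` column (`"cluster_k"`), every input
#'   row appearing exactly once, in input order.
#' @export
cluster_records <- function(records, adjacency = FALSE) {
  x <- data.table::copy(data.table::as.data.table(records))
  if (nrow(x) == 0L) { x$tag <- character(0); return(x) }
  feet <- GenomicRanges::GRanges(
    c(x$chrom1, x$chrom2),
    IRanges::IRanges(c(x$start1, x$start2) + 1L, c(x$end1, x$end2)))
  nodes <- GenomicRanges::reduce(feet,
                                 min.gapwidth = if (adjacency) 1L else 0L)
  hit <- GenomicRanges::findOverlaps(feet, nodes, select = "first")
  n <- nrow(x)
  edges <- data.frame(from = hit[seq_len(n)], to = hit[n + seq_len(n)])
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = seq_along(nodes)))
  comp <- igraph::components(g)$membership[as.character(seq_along(nodes))]
  # order components by their leftmost node
  node_dt <- data.table::data.table(
    comp = comp,
    rank = chrom_rank(as.character(GenomicRanges::seqnames(nodes))),
    start = GenomicRanges::start(nodes))
  first <- node_dt[, list(rank = min(rank), start = min(start[rank == min(rank)])),
                   by = "comp"]
  data.table::setorder(first, rank, start)
  relabel <- stats::setNames(seq_len(nrow(first)), first$comp)
  x$tag <- paste0("cluster_", relabel[as.character(comp[edges$from])])
  x
}

#' Summarize clusters of interactions
#'
#' Takes the tagged output of [cluster_records()] and produces one summary
#' row per cluster: bounding coordinates, number of participating loops,
#' total CPM contact frequency (when a matrix is supplied), total range,
#' summed loop-anchor span, and counts of user-supplied TSS and cCRE
#' annotations overlapping any foot (each annotation interval counted once
#' per cluster).
#'
#' @param records BEDPE table with a `tag` column from [cluster_records()].
#' @param m optional [contact_matrix()]; enables the `total_cpm` column
#'   (sum formula, CPM space, over every loop of the cluster).
#' @param tss,ccre optional interval tables of TSSs / candidate
#'   cis-regulatory elements.
#' @return a `data.table` with one row per cluster: `cluster_id`, `chrom`,
#'   `start`, `end`, `n_loops`, `total_cpm`, `range_bp`, `loops_span_bp`,
#'   `n_tss`, `n_ccre`.
#' @export
annotate_clusters <- function(records, m = NULL, tss = NULL, ccre = NULL) {
  x <- data.table::as.data.table(records)
  if (!"tag" %in% names(x) || any(is.na(x$tag))) {
    stop_usage("records lack cluster tags; run cluster_records() first")
  }
  if (!is.null(m)) {
    x$.cpm <- query_values(x, m, spec = norm_spec("cpm"),
                           formula = "sum")$score
  }
  count_overlaps <- function(cl_rows, ann) {
    if (is.null(ann)) return(NA_integer_)
    ann <- data.table::as.data.table(ann)
    if (nrow(ann) == 0L) return(0L)
    feet <- GenomicRanges::GRanges(
      c(cl_rows$chrom1, cl_rows$chrom2),
      IRanges::IRanges(c(cl_rows$start1, cl_rows$start2) + 1L,
                       c(cl_rows$end1, cl_rows$end2)))
    length(unique(S4Vectors::subjectHits(
      GenomicRanges::findOverlaps(feet, as_granges(ann)))))
  }
  out <- x[, {
    chroms <- c(chrom1, chrom2)
    starts <- c(start1, start2)
    ends <- c(end1, end2)
    lead <- chroms[order(chrom_rank(chroms), starts)][1]
    on_lead <- chroms == lead
    list(chrom = lead,
         start = min(starts[on_lead]), end = max(ends[on_lead]),
         n_loops = .N,
         total_cpm = if (is.null(m)) NA_real_ else sum(.cpm),
         loops_span_bp = sum(end1 - start1) + sum(end2 - start2),
         n_tss = count_overlaps(.SD, tss),
         n_ccre = count_overlaps(.SD, ccre))
  }, by = "tag"]
  out$range_bp <- out$end - out$start
  data.table::setnames(out, "tag", "cluster_id")
  ord <- order(as.integer(sub("^cluster_", "", out$cluster_id)))
  data.table::setcolorder(out, c("cluster_id", "chrom", "start", "end",
                                 "n_loops", "total_cpm", "range_bp",
                                 "loops_span_bp", "n_tss", "n_ccre"))
  out[ord]
}
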