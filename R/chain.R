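# Chaining: group simple pairs into similar regions. All functions below
# operate on a tibble of simple pairs from one (query record, reference
# record, strand) combination; the pipeline dispatches the groups.
#
# Steps, in pipeline order: cluster by PosDiff -> resolve duplicated query
# positions -> remove outliers -> split on long dissimilar gaps -> trim
# overlaps -> fill the remaining gaps with normal pairs.

#' Cluster simple pairs by position difference
#'
#' Sorts pairs by `pos_diff` and breaks a cluster wherever two adjacent
#' sorted values differ by more than `max_diff`, which bounds the indel size
#' tolerated between co-linear seeds.
#'
#' @param pairs A tibble of simple pairs (one strand/record combination).
#' @param params A [seed_params()] object.
#' @return The pairs sorted by `pos_diff` with a `cluster` id column.
#' @export
cluster_by_posdiff <- function(pairs, params = seed_params()) {
  if (nrow(pairs) == 0L) abort("no simple pairs to cluster")
  pairs <- arrange(pairs, .data$pos_diff, .data$j1, .data$i1)
  brk <- c(FALSE, diff(pairs$pos_diff) > params$max_diff)
  mutate(pairs, cluster = cumsum(brk) + 1L)
}

#' Remove outlier simple pairs from a cluster
#'
#' Pairs are re-sorted by query position; an interior pair is an outlier
#' when its PosDiff differs by more than `outlier_tol` from both neighbours.
#' A terminal pair (single neighbour) is removed when the difference exceeds
#' `terminal_tol` (default `max_diff`). The gap left by a removed outlier is
#' closed later by the ordinary normal-pair machinery.
#'
#' @param cluster A tibble of simple pairs from one cluster.
#' @param params A [seed_params()] object.
#' @return The surviving pairs, in query order.
#' @export
remove_outliers <- function(cluster, params = seed_params()) {
  cluster <- arrange(cluster, .data$j1, .data$i1)
  n <- nrow(cluster)
  if (n <= 1L) return(cluster)
  term_tol <- params$terminal_tol %||% params$max_diff
  pd <- cluster$pos_diff
  d_prev <- c(NA_integer_, abs(diff(pd)))
  d_next <- c(abs(diff(pd)), NA_integer_)
  out <- !is.na(d_prev) & !is.na(d_next) &
    d_prev > params$outlier_tol & d_next > params$outlier_tol
  out[1] <- d_next[1] > term_tol
  out[n] <- d_prev[n] > term_tol
  cluster[!out, , drop = FALSE]
}

#' Resolve simple pairs that share a query position
#'
#' When a query fragment occurs several times in the reference, its LMEM is
#' emitted once per occurrence and the copies share identical query
#' coordinates. Among such duplicates, the pair whose PosDiff is closest to
#' that of the nearest unique simple pair (in query order) is kept; without
#' any unique pair in the cluster, the pair closest to the cluster's median
#' PosDiff is kept. Exact ties keep the first pair in sorted order.
#'
#' @param cluster A tibble of simple pairs from one cluster.
#' @return The cluster with one pair per query position, in query order.
#' @export
resolve_duplicates <- function(cluster) {
  cluster <- arrange(cluster, .data$j1, .data$j2, .data$i1)
  key <- paste(cluster$j1, cluster$j2)
  if (!anyDuplicated(key)) return(cluster)
  uniq <- cluster[cluster$unique, , drop = FALSE]
  keep <- rep(TRUE, nrow(cluster))
  for (k in unique(key[duplicated(key)])) {
    idx <- which(key == k)
    jpos <- cluster$j1[idx[1]]
    if (nrow(uniq) > 0L) {
      dist <- abs(uniq$j1 - jpos)
      # nearest unique pair; ties go to the preceding (smaller j1) one
      ref_pd <- uniq$pos_diff[order(dist, uniq$j1)][1]
    } else {
      ref_pd <- median(cluster$pos_diff)
    }
    best <- idx[order(abs(cluster$pos_diff[idx] - ref_pd))][1]
    keep[setdiff(idx, best)] <- FALSE
  }
  cluster[keep, , drop = FALSE]
}

# distinct k-mers of a sequence
seq_kmers <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  unique(substring(seq, 1:(L - k + 1L), k:L))
}

#' Split a cluster at long dissimilar gaps
#'
#' For adjacent pairs a, b the gap is `j1(b) - j2(a)`. When it exceeds
#' `gap_break` the fragments between the pairs on each sequence are compared
#' by counting shared distinct k-mers; if fewer than `gap / kmer_divisor`
#' are shared the fragments are considered dissimilar and `b` initiates a
#' new similar region.
#'
#' @param cluster A tibble of simple pairs from one cluster, query-sorted.
#' @param p_seq,q_seq Reference and query sequences (strings; the query in
#'   the strand frame of the cluster).
#' @param params A [seed_params()] object.
#' @return The cluster with a `segment` id column marking the splits.
#' @export
split_on_dissimilar_gaps <- function(cluster, p_seq, q_seq,
                                     params = seed_params()) {
  cluster <- arrange(cluster, .data$j1, .data$i1)
  p_seq <- as_seq(p_seq)
  q_seq <- as_seq(q_seq)
  n <- nrow(cluster)
  brk <- rep(FALSE, n)
  if (n > 1L) {
    gap <- cluster$j1[-1L] - cluster$j2[-n]
    for (a in which(gap > params$gap_break)) {
      pf <- substr(p_seq, cluster$i2[a] + 1L, cluster$i1[a + 1L] - 1L)
      qf <- substr(q_seq, cluster$j2[a] + 1L, cluster$j1[a + 1L] - 1L)
      shared <- length(intersect(seq_kmers(pf, params$sim_kmer),
                                 seq_kmers(qf, params$sim_kmer)))
      if (shared < gap[a] / params$kmer_divisor) brk[a + 1L] <- TRUE
    }
  }
  mutate(cluster, segment = cumsum(brk) + 1L)
}

#' Trim overlaps between adjacent simple pairs
#'
#' Adjacent pairs a, b (query-sorted) overlap when `i1(b) <= i2(a)` or
#' `j1(b) <= j2(a)`, which happens around tandem repeats. The overlap is
#' chopped off the end of the preceding pair, on both coordinates, so the
#' trimmed fragments stay residue-identical; pairs trimmed below one residue
#' are dropped.
#'
#' @param cluster A tibble of simple pairs from one region, query-sorted.
#' @return The trimmed pairs; no adjacent pairs overlap afterwards.
#' @export
trim_overlaps <- function(cluster) {
  cluster <- arrange(cluster, .data$j1, .data$i1)
  repeat {
    n <- nrow(cluster)
    if (n <= 1L) break
    ov <- pmax(cluster$i2[-n] - cluster$i1[-1L] + 1L,
               cluster$j2[-n] - cluster$j1[-1L] + 1L, 0L)
    trim <- c(as.integer(ov), 0L)
    cluster$i2 <- cluster$i2 - trim
    cluster$j2 <- cluster$j2 - trim
    alive <- cluster$i2 >= cluster$i1
    if (all(alive)) break
    cluster <- cluster[alive, , drop = FALSE]
  }
  if ("len" %in% names(cluster)) cluster$len <- cluster$i2 - cluster$i1 + 1L
  cluster
}

#' Fill gaps between simple pairs with normal pairs
#'
#' Inserts a normal pair between every two adjacent simple pairs that are not
#' contiguous on both sequences. A side with no residues in the gap carries
#' the sentinel coordinates (-1, -1); such a pair is a pure insertion or
#' deletion. The region begins and ends at simple-pair boundaries (terminal
#' sequence is not extended).
#'
#' @param cluster A tibble of simple pairs from one region, trimmed and
#'   query-sorted.
#' @return A region tibble: the pairs in query order with a `kind` column
#'   (`"simple"` or `"normal"`) and coordinates `i1`, `i2`, `j1`, `j2`.
#' @export
fill_gaps <- function(cluster) {
  cluster <- arrange(cluster, .data$j1, .data$i1)
  n <- nrow(cluster)
  meta <- intersect(c("q_name", "r_name", "strand"), names(cluster))
  simple <- cluster[, c(meta, c("i1", "i2", "j1", "j2"))]
  simple$kind <- "simple"
  simple$.ord <- 2L * seq_len(n) - 1L
  if (n > 1L) {
    dp <- cluster$i1[-1L] - cluster$i2[-n]
    dq <- cluster$j1[-1L] - cluster$j2[-n]
    has <- dp > 1L | dq > 1L
    if (any(has)) {
      a <- which(has)
      normal <- tibble(
        kind = "normal",
        i1 = ifelse(dp[a] > 1L, cluster$i2[a] + 1L, -1L),
        i2 = ifelse(dp[a] > 1L, cluster$i1[a + 1L] - 1L, -1L),
        j1 = ifelse(dq[a] > 1L, cluster$j2[a] + 1L, -1L),
        j2 = ifelse(dq[a] > 1L, cluster$j1[a + 1L] - 1L, -1L),
        .ord = 2L * a)
      for (mcol in meta) normal[[mcol]] <- cluster[[mcol]][1L]
      out <- bind_rows(simple, normal)
      out <- out[order(out$.ord), , drop = FALSE]
      out$.ord <- NULL
      return(out[, c(meta, "kind", "i1", "i2", "j1", "j2")])
    }
  }
  simple$.ord <- NULL
  simple[, c(meta, "kind", "i1", "i2", "j1", "j2")]
}

#' Chain simple pairs into similar regions
#'
#' Composite of the chaining steps: PosDiff clustering, duplicate
#' resolution, outlier removal, dissimilar-gap splitting, overlap trimming
#' and gap filling.
#'
#' @param pairs Simple pairs from one (query, reference, strand) group.
#' @param p_seq,q_seq Reference and query sequences (query in strand frame).
#' @param params A [seed_params()] object.
#' @return A list of region tibbles (see [fill_gaps()]).
#' @export
chain_seeds <- function(pairs, p_seq, q_seq, params = seed_params()) {
  if (nrow(pairs) == 0L) return(list())
  clustered <- cluster_by_posdiff(pairs, params)
  regions <- list()
  for (cl in split(clustered, clustered$cluster)) {
    cl <- remove_outliers(resolve_duplicates(cl), params)
    if (nrow(cl) == 0L) next
    seg <- split_on_dissimilar_gaps(cl, p_seq, q_seq, params)
    for (sg in split(seg, seg$segment)) {
      sg <- trim_overlaps(sg)
      if (nrow(sg) == 0L) next
      regions[[length(regions) + 1L]] <- fill_gaps(sg)
    }
  }
  regions
}
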