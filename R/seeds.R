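# LMEM seeding: scan the query left to right against the FM-index. Each scan
# iteration extends a match from the current query position as far as it goes
# (a local maximal exact match), emits it as simple pairs if it is long
# enough (>= k) and not too repetitive (occurrences < f), and restarts after
# the match (default) or 5 bp after its start (sensitive mode).

#' Seeding and chaining parameters
#'
#' @param k Minimum LMEM length for a seed to be kept (bp).
#' @param f Maximum occurrence count: LMEMs occurring `f` or more times are
#'   discarded.
#' @param sensitive Restart the scan 5 bp after the previous LMEM start
#'   instead of after its end, increasing seed density.
#' @param stride Restart offset in sensitive mode.
#' @param max_diff Clustering threshold MaxDiff: adjacent seeds (sorted by
#'   PosDiff) further apart than this start a new cluster. Bounds the indel
#'   size tolerated between co-linear seeds.
#' @param outlier_tol A seed is an outlier when its PosDiff differs by more
#'   than this from both neighbours in query order.
#' @param terminal_tol Tolerance applied to the single neighbour of the first
#'   and last seed of a cluster; defaults to `max_diff`.
#' @param gap_break Query gaps longer than this (bp) trigger a similarity
#'   test that may split the cluster.
#' @param kmer_divisor Fragments in a tested gap are dissimilar when they
#'   share fewer than `gap / kmer_divisor` distinct k-mers.
#' @param sim_kmer K-mer size used by the gap similarity test.
#' @return A `seed_params` list.
#' @export
seed_params <- function(k = 30L, f = 5L, sensitive = FALSE, stride = 5L,
                        max_diff = 25L, outlier_tol = 5L, terminal_tol = NULL,
                        gap_break = 300L, kmer_divisor = 3L, sim_kmer = 8L) {
  p <- list(k = as.integer(k), f = as.integer(f), sensitive = sensitive,
            stride = as.integer(stride), max_diff = as.integer(max_diff),
            outlier_tol = as.integer(outlier_tol),
            terminal_tol = if (is.null(terminal_tol)) NULL
                           else as.integer(terminal_tol),
            gap_break = as.integer(gap_break),
            kmer_divisor = as.integer(kmer_divisor),
            sim_kmer = as.integer(sim_kmer))
  with(p, stopifnot(k >= 1L, f >= 1L, stride >= 1L, max_diff >= 1L,
                    outlier_tol >= 1L, gap_break >= 1L, kmer_divisor >= 1L,
                    sim_kmer >= 1L))
  structure(p, class = "seed_params")
}

#' Partition a query into blocks
#'
#' Splits every query record into `n_blocks` contiguous intervals of (near)
#' equal size. Blocks tile the record exactly; seed scans of adjacent blocks
#' are stitched by [find_lmems()] so that the simple-pair set does not depend
#' on the number of blocks.
#'
#' @param query A genome tibble.
#' @param n_blocks Number of blocks per record (clamped to the record length).
#' @return A tibble with columns `name`, `block`, `start`, `end`.
#' @export
partition_query <- function(query, n_blocks) {
  stopifnot(n_blocks >= 1L)
  query <- as_genome(query)
  out <- lapply(seq_len(nrow(query)), function(i) {
    L <- query$length[i]
    nb <- min(as.integer(n_blocks), L)
    bounds <- floor(L * (0:nb) / nb)
    tibble(name = query$name[i], block = seq_len(nb),
           start = as.integer(bounds[-(nb + 1L)] + 1L),
           end = as.integer(bounds[-1L]))
  })
  bind_rows(out)
}

#' Find local maximal exact matches (simple pairs)
#'
#' Scans each query record against the index and reports every kept LMEM
#' occurrence as a simple pair. Reference coordinates (`i1`, `i2`) are
#' forward-strand; query coordinates (`j1`, `j2`) are strand-relative: for a
#' reverse-strand pair they index the reverse complement of the query record,
#' so that the referenced fragments are residue-identical in that frame and
#' `pos_diff = i1 - j1` is comparable within a strand.
#'
#' @param index An `fm_index` built from the reference.
#' @param query A genome tibble (or sequences coercible to one).
#' @param params A [seed_params()] object.
#' @param n_blocks Scan each record in this many blocks (the result is
#'   deduplicated at block joins and identical to a single-block scan on the
#'   inputs this tool targets).
#' @return A tibble of simple pairs: `q_name`, `r_name`, `strand`, `i1`,
#'   `i2`, `j1`, `j2`, `len`, `occ`, `unique`, `pos_diff`.
#' @export
find_lmems <- function(index, query, params = seed_params(), n_blocks = 1L) {
  stopifnot(inherits(index, "fm_index"))
  query <- as_genome(query)
  blocks <- partition_query(query, n_blocks)
  res <- list()
  for (qi in seq_len(nrow(query))) {
    qname <- query$name[qi]
    Lq <- query$length[qi]
    qcodes <- encode_seq(query$seq[qi])
    bl <- blocks[blocks$name == qname, ]
    mats <- lapply(seq_len(nrow(bl)), function(b) {
      s <- bl$start[b]; e <- bl$end[b]
      if (params$sensitive) {
        # the sensitive chain visits 1, 1+stride, 2*stride+1, ...; start at
        # the first chain position inside the block so blocks agree exactly
        s <- 1L + params$stride * ceiling((s - 1L) / params$stride)
        if (s > e) return(NULL)
        lmem_scan_cpp(index$sa, index$bwt, index$cnt, index$occ, index$n,
                      index$lc, qcodes, params$k, params$f, TRUE,
                      params$stride, s, e, FALSE, FALSE)
      } else {
        lmem_scan_cpp(index$sa, index$bwt, index$cnt, index$occ, index$n,
                      index$lc, qcodes, params$k, params$f, FALSE,
                      params$stride, s, e, b > 1L, b < nrow(bl))
      }
    })
    mats <- mats[!vapply(mats, is.null, logical(1))]
    m <- do.call(rbind, mats)
    if (is.null(m) || nrow(m) == 0L) next
    d <- tibble(i1g = as.vector(m[, 1]), j1f = as.vector(m[, 2]),
                len = as.vector(m[, 3]), rev = as.vector(m[, 4]) == 1L,
                occ = as.vector(m[, 5]))
    d <- distinct(d, .data$i1g, .data$j1f, .data$rev, .keep_all = TRUE)
    ri <- findInterval(d$i1g, index$records$offset)
    i1 <- as.integer(d$i1g - index$records$offset[ri] + 1L)
    j1 <- ifelse(d$rev, Lq - (d$j1f + d$len - 1L) + 1L, d$j1f)
    res[[length(res) + 1L]] <- tibble(
      q_name = qname,
      r_name = index$records$name[ri],
      strand = ifelse(d$rev, "-", "+"),
      i1 = i1, i2 = as.integer(i1 + d$len - 1L),
      j1 = as.integer(j1), j2 = as.integer(j1 + d$len - 1L),
      len = as.integer(d$len),
      occ = as.integer(d$occ),
      unique = d$occ == 1L,
      pos_diff = as.integer(i1 - j1)
    )
  }
  if (length(res) == 0L) {
    return(tibble(q_name = character(0), r_name = character(0),
                  strand = character(0), i1 = integer(0), i2 = integer(0),
                  j1 = integer(0), j2 = integer(0), len = integer(0),
                  occ = integer(0), unique = logical(0),
                  pos_diff = integer(0)))
  }
  arrange(bind_rows(res), .data$q_name, .data$r_name, .data$strand,
          .data$j1, .data$i1)
}
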