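# Closing the gaps: normal pairs are classified into three types.
# Type I  - equal-sized fragments with few mismatches: an un-gapped
#           positional scan is already the best alignment.
# Type II - one side empty: a pure insertion or deletion, no DP needed.
# Type III- everything else: global affine-gap dynamic programming.
# The alignment of a similar region is the concatenation of the per-pair
# alignments in query order (simple pairs are all-match by construction).

OP_CHARS <- c("=", "X", "I", "D")

#' Alignment scoring parameters
#'
#' @param match Match score (positive).
#' @param mismatch Mismatch penalty (positive; subtracted).
#' @param gap_open Gap opening penalty; a gap of length L costs
#'   `gap_open + L * gap_extend`. The defaults keep
#'   `gap_open > mismatch + match` (a substitution next to an indel is never
#'   re-represented as two separate gaps) and `gap_extend` well below
#'   `mismatch` (two nearby opposite-sign indels are not collapsed into a
#'   net indel plus a mismatch run); BWA's scoring satisfies the same
#'   inequalities.
#' @param gap_extend Gap extension penalty.
#' @param type1_max_mismatch_frac Equal-sized normal pairs with a mismatch
#'   fraction below this are aligned un-gapped (Type I).
#' @param max_cells Matrix-size ceiling above which the DP falls back to a
#'   banded matrix (logged via `message()`).
#' @return An `align_params` list.
#' @export
align_params <- function(match = 2L, mismatch = 4L, gap_open = 8L,
                         gap_extend = 1L, type1_max_mismatch_frac = 0.3,
                         max_cells = 6.4e7) {
  stopifnot(match > 0, mismatch >= 0, gap_open >= gap_extend, gap_extend >= 0,
            type1_max_mismatch_frac > 0, type1_max_mismatch_frac < 1,
            max_cells >= 1e4)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 type1_max_mismatch_frac = type1_max_mismatch_frac,
                 max_cells = max_cells),
            class = "align_params")
}

np_frag <- function(np, seq, side) {
  a <- if (side == "p") np$i1 else np$j1
  b <- if (side == "p") np$i2 else np$j2
  if (a < 0L) "" else substr(seq, a, b)
}

new_alignment <- function(p_start, p_end, q_start, q_end, ops, lens, score,
                          strand = "+", p_name = NULL, q_name = NULL) {
  structure(list(p_start = p_start, p_end = p_end, q_start = q_start,
                 q_end = q_end, strand = strand, score = score,
                 p_name = p_name, q_name = q_name,
                 ops = tibble(op = ops, len = as.integer(lens))),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("pairwise alignment  P[%d..%d] ~ Q[%d..%d] (%s)  score %d\n",
              x$p_start, x$p_end, x$q_start, x$q_end, x$strand, x$score))
  cat("ops:", paste0(x$ops$len, x$ops$op, collapse = " "), "\n")
  invisible(x)
}

# Largest mismatch count for which the un-gapped alignment of an equal-sized
# pair is provably optimal: any gapped alternative pays at least two gap
# openings (net length change 0 needs one insertion and one deletion) and can
# recover at most (match + mismatch) per mismatch column, so with
# nmis * (match + mismatch) <= 2 * (gap_open + gap_extend) no gapped
# alignment can win and the linear scan is exact, not a heuristic.
type1_mismatch_bound <- function(params) {
  as.integer((2L * (params$gap_open + params$gap_extend)) %/%
               (params$match + params$mismatch))
}

#' Classify a normal pair
#'
#' Type I requires equal sizes, a mismatch fraction below
#' `type1_max_mismatch_frac`, and a mismatch count small enough that the
#' un-gapped alignment is provably optimal under the scoring scheme (see the
#' note on `gap_open` in [align_params()]); equal-sized pairs with more
#' mismatches go to the gapped aligner, which simply reproduces the un-gapped
#' alignment when that is best.
#'
#' @param np A normal pair (one-row tibble or list with `i1`, `i2`, `j1`,
#'   `j2`; -1/-1 marks an empty side).
#' @param p_seq,q_seq Reference and query sequences (strings or single-record
#'   genomes; query in the strand frame of the region).
#' @param params An [align_params()] object.
#' @return `"I"`, `"II"` or `"III"`.
#' @export
classify_normal_pair <- function(np, p_seq, q_seq, params = align_params()) {
  lp <- if (np$i1 < 0L) 0L else np$i2 - np$i1 + 1L
  lq <- if (np$j1 < 0L) 0L else np$j2 - np$j1 + 1L
  if (lp == 0L && lq == 0L) abort("normal pair with both sides empty")
  if (lp == 0L || lq == 0L) return("II")
  if (lp == lq) {
    a <- np_frag(np, as_seq(p_seq), "p")
    b <- np_frag(np, as_seq(q_seq), "q")
    nmis <- length(mismatch_positions_cpp(a, b))
    if (nmis / lp < params$type1_max_mismatch_frac &&
        nmis <= type1_mismatch_bound(params)) {
      return("I")
    }
  }
  "III"
}

type1_ops <- function(len, mis) {
  flag <- rep(FALSE, len)
  flag[mis] <- TRUE
  r <- rle(flag)
  list(ops = ifelse(r$values, "X", "="), lens = r$lengths)
}

#' Un-gapped alignment of a Type I normal pair
#'
#' @inheritParams classify_normal_pair
#' @return A `pairwise_alignment` with match/mismatch runs only.
#' @export
align_type1 <- function(np, p_seq, q_seq, params = align_params()) {
  a <- np_frag(np, as_seq(p_seq), "p")
  b <- np_frag(np, as_seq(q_seq), "q")
  if (nchar(a) != nchar(b) || nchar(a) == 0L) {
    abort("Type I alignment requires equal-sized non-empty fragments")
  }
  mis <- mismatch_positions_cpp(a, b)
  o <- type1_ops(nchar(a), mis)
  score <- params$match * (nchar(a) - length(mis)) -
    params$mismatch * length(mis)
  new_alignment(np$i1, np$i2, np$j1, np$j2, o$ops, o$lens, score)
}

#' Gap alignment of a Type II normal pair
#'
#' One side is empty: the whole pair is a single insertion (query side
#' present) or deletion (reference side present).
#'
#' @param np A normal pair classified Type II.
#' @param params An [align_params()] object.
#' @return A `pairwise_alignment` with one gap op.
#' @export
align_type2 <- function(np, params = align_params()) {
  p_empty <- np$i1 < 0L
  q_empty <- np$j1 < 0L
  if (p_empty == q_empty) abort("Type II requires exactly one empty side")
  len <- if (p_empty) np$j2 - np$j1 + 1L else np$i2 - np$i1 + 1L
  op <- if (p_empty) "I" else "D"
  score <- -(params$gap_open + len * params$gap_extend)
  new_alignment(np$i1, np$i2, np$j1, np$j2, op, len, score)
}

#' Affine-gap alignment of a Type III normal pair
#'
#' Global (end-to-end over both fragments) affine-gap dynamic programming;
#' with the full matrix (the default for fragments this pipeline produces)
#' the score is maximal under the scoring scheme.
#'
#' @inheritParams classify_normal_pair
#' @return A `pairwise_alignment`.
#' @export
align_type3 <- function(np, p_seq, q_seq, params = align_params()) {
  a <- np_frag(np, as_seq(p_seq), "p")
  b <- np_frag(np, as_seq(q_seq), "q")
  if (nchar(a) == 0L || nchar(b) == 0L) {
    abort("Type III alignment requires two non-empty fragments")
  }
  r <- affine_align_cpp(a, b, params$match, params$mismatch, params$gap_open,
                        params$gap_extend, params$max_cells)
  if (isTRUE(r$banded)) {
    message(sprintf("fragment pair %d x %d above DP ceiling; banded alignment used",
                    nchar(a), nchar(b)))
  }
  new_alignment(np$i1, np$i2, np$j1, np$j2, OP_CHARS[r$ops + 1L], r$lens,
                r$score)
}

merge_op_runs <- function(ops, lens) {
  if (length(ops) <= 1L) return(list(ops = ops, lens = as.integer(lens)))
  grp <- cumsum(c(TRUE, ops[-1L] != ops[-length(ops)]))
  list(ops = ops[!duplicated(grp)],
       lens = as.integer(rowsum(as.integer(lens), grp)[, 1]))
}

#' Concatenate per-pair alignments into the region alignment
#'
#' Simple pairs contribute all-match runs; normal pairs contribute the
#' supplied alignments. Adjacent pairs must be contiguous on each consumed
#' sequence.
#'
#' @param region A region tibble from [fill_gaps()].
#' @param aligned A list, parallel to the region rows, with a
#'   `pairwise_alignment` for every normal row (`NULL` for simple rows).
#' @param params An [align_params()] object (used to score the match runs).
#' @return A `pairwise_alignment` spanning the region.
#' @export
assemble_region <- function(region, aligned, params = align_params()) {
  n <- nrow(region)
  stopifnot(length(aligned) == n)
  ops <- list(); lens <- list(); score <- 0
  p_cur <- NA_integer_; q_cur <- NA_integer_
  for (r in seq_len(n)) {
    if (region$kind[r] == "simple") {
      len <- region$i2[r] - region$i1[r] + 1L
      ops[[r]] <- "="; lens[[r]] <- len
      score <- score + params$match * len
      pa_p1 <- region$i1[r]; pa_p2 <- region$i2[r]
      pa_q1 <- region$j1[r]; pa_q2 <- region$j2[r]
    } else {
      pa <- aligned[[r]]
      if (is.null(pa)) abort("normal pair without an alignment")
      ops[[r]] <- pa$ops$op; lens[[r]] <- pa$ops$len
      score <- score + pa$score
      pa_p1 <- region$i1[r]; pa_p2 <- region$i2[r]
      pa_q1 <- region$j1[r]; pa_q2 <- region$j2[r]
    }
    if (pa_p1 > 0L) {
      if (!is.na(p_cur) && pa_p1 != p_cur + 1L) {
        abort("adjacent pair alignments are not contiguous on the reference")
      }
      p_cur <- pa_p2
    }
    if (pa_q1 > 0L) {
      if (!is.na(q_cur) && pa_q1 != q_cur + 1L) {
        abort("adjacent pair alignments are not contiguous on the query")
      }
      q_cur <- pa_q2
    }
  }
  m <- merge_op_runs(unlist(ops), unlist(lens))
  first <- region[1L, ]; last <- region[n, ]
  new_alignment(first$i1, p_cur, first$j1, q_cur, m$ops, m$lens, score,
                strand = if ("strand" %in% names(region)) first$strand else "+",
                p_name = if ("r_name" %in% names(region)) first$r_name else NULL,
                q_name = if ("q_name" %in% names(region)) first$q_name else NULL)
}

#' Align one similar region
#'
#' Classifies and aligns every normal pair of the region, then assembles the
#' complete local alignment.
#'
#' @param region A region tibble from [fill_gaps()].
#' @param p_seq,q_seq Reference and query sequences (query in strand frame).
#' @param params An [align_params()] object.
#' @return A `pairwise_alignment`.
#' @export
align_region <- function(region, p_seq, q_seq, params = align_params()) {
  p_seq <- as_seq(p_seq)
  q_seq <- as_seq(q_seq)
  kind <- region$kind
  i1 <- region$i1; i2 <- region$i2; j1 <- region$j1; j2 <- region$j2
  n <- length(kind)
  # contiguity of consumed coordinates
  pi <- which(i1 > 0L); qi <- which(j1 > 0L)
  if (length(pi) > 1L && !all(i1[pi][-1L] == i2[pi][-length(pi)] + 1L)) {
    abort("region pairs are not contiguous on the reference")
  }
  if (length(qi) > 1L && !all(j1[qi][-1L] == j2[qi][-length(qi)] + 1L)) {
    abort("region pairs are not contiguous on the query")
  }
  ops <- vector("list", n); lens <- vector("list", n)
  score <- 0
  for (r in seq_len(n)) {
    if (kind[r] == "simple") {
      len <- i2[r] - i1[r] + 1L
      ops[[r]] <- "="; lens[[r]] <- len
      score <- score + params$match * len
      next
    }
    lp <- if (i1[r] < 0L) 0L else i2[r] - i1[r] + 1L
    lq <- if (j1[r] < 0L) 0L else j2[r] - j1[r] + 1L
    if (lp == 0L || lq == 0L) {            # Type II: pure indel
      len <- max(lp, lq)
      ops[[r]] <- if (lp == 0L) "I" else "D"; lens[[r]] <- len
      score <- score - (params$gap_open + len * params$gap_extend)
      next
    }
    a <- substr(p_seq, i1[r], i2[r]); b <- substr(q_seq, j1[r], j2[r])
    if (lp == lq) {
      mis <- mismatch_positions_cpp(a, b)
      if (length(mis) / lp < params$type1_max_mismatch_frac &&
          length(mis) <= type1_mismatch_bound(params)) {    # Type I
        o <- type1_ops(lp, mis)
        ops[[r]] <- o$ops; lens[[r]] <- o$lens
        score <- score + params$match * (lp - length(mis)) -
          params$mismatch * length(mis)
        next
      }
    }
    al <- affine_align_cpp(a, b, params$match, params$mismatch,  # Type III
                           params$gap_open, params$gap_extend, params$max_cells)
    if (isTRUE(al$banded)) {
      message(sprintf("fragment pair %d x %d above DP ceiling; banded alignment used",
                      lp, lq))
    }
    ops[[r]] <- OP_CHARS[al$ops + 1L]; lens[[r]] <- al$lens
    score <- score + al$score
  }
  m <- merge_op_runs(unlist(ops), unlist(lens))
  new_alignment(i1[1L], i2[pi[length(pi)]], j1[1L], j2[qi[length(qi)]],
                m$ops, m$lens, score,
                strand = if ("strand" %in% names(region)) region$strand[1L] else "+",
                p_name = if ("r_name" %in% names(region)) region$r_name[1L] else NULL,
                q_name = if ("q_name" %in% names(region)) region$q_name[1L] else NULL)
}

#' Reconstruct the aligned fragments from an alignment
#'
#' Applies the edit operations to the underlying sequences; useful to verify
#' that an alignment reproduces its input fragments.
#'
#' @param alignment A `pairwise_alignment`.
#' @param p_seq,q_seq The sequences the alignment refers to.
#' @return A list with `p` and `q`, the two reconstructed fragments.
#' @export
alignment_fragments <- function(alignment, p_seq, q_seq) {
  p_seq <- as_seq(p_seq); q_seq <- as_seq(q_seq)
  list(p = substr(p_seq, alignment$p_start, alignment$p_end),
       q = substr(q_seq, alignment$q_start, alignment$q_end))
}
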