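# Scoring called variants against a truth set. SNVs must match exactly
# (chromosome, coordinate, alleles). Indels match when they are the same
# kind, their anchors are within 10 bp (inclusive), and they describe the
# same edit up to shifting within the local repeat context: an indel placed
# at either end of a tandem repeat is the same event, which is checked by
# applying both edits to the reference window and comparing the haplotypes.

#' Are two indels the same event up to repeat shifting?
#'
#' @param v1,v2 Single-row variant tibbles (same chromosome).
#' @param ref_seq The reference sequence of that chromosome.
#' @return TRUE when applying either variant to the reference yields the
#'   same local haplotype.
#' @export
variants_equivalent <- function(v1, v2, ref_seq) {
  if (!is.character(ref_seq) || length(ref_seq) != 1L) {
    ref_seq <- record_seq(ref_seq)
  }
  # work on a local window so the check is cheap on chromosome-scale input
  lo <- max(1L, min(v1$pos, v2$pos) - 25L)
  hi <- min(nchar(ref_seq),
            max(v1$pos + nchar(v1$ref), v2$pos + nchar(v2$ref)) + 25L)
  win <- toupper(substr(ref_seq, lo, hi))
  w1 <- v1; w1$pos <- v1$pos - lo + 1L
  w2 <- v2; w2$pos <- v2$pos - lo + 1L
  identical(apply_variants(win, w1), apply_variants(win, w2))
}

match_indels <- function(called, truth, ref_seq, window = 10L,
                         require_equivalence = FALSE,
                         one_to_one = FALSE) {
  nt <- nrow(truth)
  matched_truth <- rep(FALSE, nt)
  tp <- 0L
  if (nrow(called)) called <- arrange(called, .data$pos)
  for (c_i in seq_len(nrow(called))) {
    cv <- called[c_i, ]
    cand <- which((!one_to_one | !matched_truth) &
                    truth$kind == cv$kind &
                    abs(truth$pos - cv$pos) <= window)
    if (!length(cand)) next
    # nearest first, ties to the left (smaller truth position)
    cand <- cand[order(abs(truth$pos[cand] - cv$pos), truth$pos[cand])]
    for (t_i in cand) {
      if (!require_equivalence || variants_equivalent(cv, truth[t_i, ], ref_seq)) {
        matched_truth[t_i] <- TRUE
        tp <- tp + 1L
        break
      }
    }
  }
  if (!one_to_one) {
    # each side is scored independently: a truth event is identified when
    # any prediction of its kind lies within the window (and is equivalent,
    # if required), regardless of how the predictions were credited
    for (t_i in which(!matched_truth)) {
      tv <- truth[t_i, ]
      cand <- which(called$kind == tv$kind & abs(called$pos - tv$pos) <= window)
      for (c_i in cand) {
        if (!require_equivalence ||
            variants_equivalent(called[c_i, ], tv, ref_seq)) {
          matched_truth[t_i] <- TRUE
          break
        }
      }
    }
  }
  list(tp = tp, fp = nrow(called) - tp, fn = sum(!matched_truth))
}

#' Evaluate called variants against a truth set
#'
#' SNVs require identical chromosome, coordinate and alleles. Indels require
#' the same kind and an anchor within 10 bp (inclusive) of the corresponding
#' true event; the coordinate tolerance makes the score robust to
#' representation shifts within tandem repeats and homopolymers (an indel
#' placed at either end of a repeat is the same event).
#'
#' Counting follows the benchmark definition by default (`"per_event"`): a
#' prediction is a TP when a true event of its kind lies within the window,
#' and a true event is identified (not FN) when any prediction of its kind
#' lies within the window — each side is scored independently. With
#' `counting = "one_to_one"` every truth event is creditable at most once
#' (greedy nearest-first, ties to the left). With
#' `indel_match = "equivalent"` a match additionally requires that the two
#' edits give the same local haplotype (see [variants_equivalent()]), a
#' stricter, representation-aware score. Precision is TP/(TP+FP) and recall
#' TP/(TP+FN); an undefined ratio is reported as NA.
#'
#' @param called,truth Variant tibbles.
#' @param reference The reference genome tibble the coordinates refer to.
#' @param indel_match `"position"` (coordinate within 10, the benchmark
#'   definition) or `"equivalent"` (additionally require haplotype
#'   equivalence).
#' @param counting `"per_event"` (benchmark definition) or `"one_to_one"`.
#' @return A tibble with one row per class (`snv`, `indel`): `tp`, `fp`,
#'   `fn`, `precision`, `recall`.
#' @export
evaluate_calls <- function(called, truth, reference,
                           indel_match = c("position", "equivalent"),
                           counting = c("per_event", "one_to_one")) {
  indel_match <- match.arg(indel_match)
  counting <- match.arg(counting)
  reference <- as_genome(reference)
  called <- as_tibble(called); truth <- as_tibble(truth)
  # truth must be non-overlapping for one-to-one matching to be well defined
  tt <- arrange(truth, .data$chrom, .data$pos)
  by_chrom <- split(tt, tt$chrom)
  for (ch in by_chrom) {
    if (nrow(ch) > 1L &&
        any(ch$pos[-1L] <= ch$pos[-nrow(ch)] + nchar(ch$ref[-nrow(ch)]) - 1L)) {
      abort("truth set contains overlapping events")
    }
  }
  key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt)
  c_snv <- called[called$kind == "SNV", , drop = FALSE]
  t_snv <- truth[truth$kind == "SNV", , drop = FALSE]
  if (counting == "one_to_one") {
    # exact matching with key multiplicities capped on both sides
    ck <- table(key(c_snv)); tk <- table(key(t_snv))
    common <- intersect(names(ck), names(tk))
    tp_snv <- as.integer(sum(pmin(ck[common], tk[common])))
    snv <- tibble(class = "snv", tp = tp_snv,
                  fp = nrow(c_snv) - tp_snv,
                  fn = nrow(t_snv) - tp_snv)
  } else {
    tp_snv <- sum(key(c_snv) %in% key(t_snv))
    snv <- tibble(class = "snv", tp = as.integer(tp_snv),
                  fp = nrow(c_snv) - as.integer(tp_snv),
                  fn = sum(!key(t_snv) %in% key(c_snv)))
  }

  c_ind <- called[called$kind != "SNV", , drop = FALSE]
  t_ind <- truth[truth$kind != "SNV", , drop = FALSE]
  tp_i <- 0L; fp_i <- 0L; fn_i <- 0L
  for (ch in union(unique(c_ind$chrom), unique(t_ind$chrom))) {
    res <- match_indels(c_ind[c_ind$chrom == ch, , drop = FALSE],
                        t_ind[t_ind$chrom == ch, , drop = FALSE],
                        record_seq(reference, ch),
                        require_equivalence = indel_match == "equivalent",
                        one_to_one = counting == "one_to_one")
    tp_i <- tp_i + res$tp; fp_i <- fp_i + res$fp; fn_i <- fn_i + res$fn
  }
  ind <- tibble(class = "indel", tp = tp_i, fp = fp_i, fn = fn_i)

  out <- bind_rows(snv, ind)
  mutate(out,
         precision = ifelse(.data$tp + .data$fp > 0,
                            .data$tp / (.data$tp + .data$fp), NA_real_),
         recall = ifelse(.data$tp + .data$fn > 0,
                         .data$tp / (.data$tp + .data$fn), NA_real_))
}
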