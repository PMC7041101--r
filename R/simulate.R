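# Benchmark machinery: plant variants into a genome at fixed per-Mbp rates
# and keep the exact edit script as a truth set, so that alignment-derived
# calls can be scored for precision and recall.

#' Mutation rate profile
#'
#' Default rates are 20,000 SNVs, 350 small indels (1-10 bp) and 100 large
#' indels (11-20 bp) per Mbp; presets 3x and 5x multiply only the SNV rate
#' (60,000 and 100,000 per Mbp).
#'
#' @param snv_per_mb SNVs per 1 Mbp.
#' @param small_indel_per_mb Indels of size 1-10 bp per 1 Mbp.
#' @param large_indel_per_mb Indels of size 11-20 bp per 1 Mbp.
#' @param preset One of "1x", "3x", "5x": multiplies the SNV rate.
#' @param seed Optional RNG seed used by [mutate_genome()].
#' @return A `mutation_profile` list.
#' @export
mutation_profile <- function(snv_per_mb = 20000, small_indel_per_mb = 350,
                             large_indel_per_mb = 100,
                             preset = c("1x", "3x", "5x"), seed = NULL) {
  preset <- match.arg(preset)
  mult <- c("1x" = 1, "3x" = 3, "5x" = 5)[[preset]]
  stopifnot(snv_per_mb >= 0, small_indel_per_mb >= 0, large_indel_per_mb >= 0)
  structure(list(snv_per_mb = snv_per_mb * mult,
                 small_indel_per_mb = small_indel_per_mb,
                 large_indel_per_mb = large_indel_per_mb,
                 small_range = c(1L, 10L), large_range = c(11L, 20L),
                 seed = seed),
            class = "mutation_profile")
}

# footprint on the template: positions the event occupies (anchor included)
event_footprint <- function(kind, size) {
  ifelse(kind == "DEL", size + 1L, ifelse(kind == "INS", 2L, 1L))
}

#' Plant variants into a genome
#'
#' Draws event counts from the per-Mbp rates scaled by template length,
#' places them uniformly over non-N sites with at least 1 bp separation
#' between event footprints, and returns the mutated genome together with
#' the exact edit script (truth set).
#'
#' @param template A genome tibble (every record is mutated independently).
#' @param profile A [mutation_profile()].
#' @return A list with `genome` (mutated genome tibble) and `variants`
#'   (truth tibble, VCF-style left-anchored).
#' @export
mutate_genome <- function(template, profile = mutation_profile()) {
  template <- as_genome(template)
  with_seed(profile$seed, {
    res <- lapply(seq_len(nrow(template)), function(i) {
      mutate_record(template$name[i], template$seq[i], profile)
    })
    genome <- as_genome(tibble(
      name = template$name,
      seq = vapply(res, function(x) x$seq, character(1))
    ))
    truth <- bind_rows(lapply(res, function(x) x$truth))
    list(genome = genome, variants = truth)
  })
}

mutate_record <- function(name, seq, profile) {
  L <- nchar(seq)
  n_snv <- as.integer(round(L / 1e6 * profile$snv_per_mb))
  n_small <- as.integer(round(L / 1e6 * profile$small_indel_per_mb))
  n_large <- as.integer(round(L / 1e6 * profile$large_indel_per_mb))
  n_ev <- n_snv + n_small + n_large
  if (n_ev == 0L) {
    return(list(seq = seq, truth = empty_variants()))
  }
  kind <- c(rep("SNV", n_snv),
            sample(c("INS", "DEL"), n_small + n_large, replace = TRUE))
  size <- c(rep(1L, n_snv),
            sample(profile$small_range[1]:profile$small_range[2], n_small,
                   replace = TRUE),
            sample(profile$large_range[1]:profile$large_range[2], n_large,
                   replace = TRUE))
  fp <- event_footprint(kind, size)
  max_fp <- max(fp)
  if (L < sum(fp + 1L) + max_fp) {
    abort("template too short to host the requested number of events")
  }
  rawseq <- charToRaw(seq)
  is_n <- rawseq == as.raw(78L)  # 'N'
  # anchors live in [2, L - max_fp]: pos 1 is excluded so indel anchors always
  # have a preceding base and SNVs never sit at an unanchored edge deletion
  ok_site <- function(pos, fpl) {
    end <- pos + fpl - 1L
    bad <- pos < 2L | end > L
    if (any(is_n)) {
      bad <- bad | vapply(seq_along(pos), function(t) {
        any(is_n[pos[t]:min(end[t], L)])
      }, logical(1))
    }
    !bad
  }
  pos <- sample.int(L - max_fp - 1L, n_ev, replace = TRUE) + 1L
  for (iter in 1:200) {
    o <- order(pos)
    pos_o <- pos[o]; fp_o <- fp[o]
    clash <- !ok_site(pos_o, fp_o)
    if (length(pos_o) > 1L) {
      gap_ok <- pos_o[-1L] > pos_o[-n_ev] + fp_o[-n_ev]  # >= 1 bp separation
      clash[-1L] <- clash[-1L] | !gap_ok
      clash[-n_ev] <- clash[-n_ev] | !gap_ok
    }
    if (!any(clash)) { pos <- pos_o; kind <- kind[o]; size <- size[o]; fp <- fp_o; break }
    pos[o[clash]] <- sample.int(L - max_fp - 1L, sum(clash), replace = TRUE) + 1L
    if (iter == 200L) abort("could not place events without overlap; template too short or too repetitive")
  }
  bases <- c("A", "C", "G", "T")
  anchor <- substring(seq, pos, pos)
  ref <- anchor; alt <- character(n_ev)
  snv <- kind == "SNV"; del <- kind == "DEL"; ins <- kind == "INS"
  if (any(snv)) {
    cur <- match(anchor[snv], bases)
    off <- sample.int(3L, sum(snv), replace = TRUE)
    alt[snv] <- bases[((cur - 1L + off) %% 4L) + 1L]
  }
  if (any(del)) {
    ref[del] <- substring(seq, pos[del], pos[del] + size[del])
    alt[del] <- anchor[del]
  }
  if (any(ins)) {
    draws <- bases[sample.int(4L, sum(size[ins]), replace = TRUE)]
    grp <- rep(seq_len(sum(ins)), size[ins])
    alt[ins] <- paste0(anchor[ins],
                       vapply(split(draws, grp), paste0, character(1),
                              collapse = ""))
  }
  truth <- tibble(chrom = name, pos = as.integer(pos), kind = kind,
                  ref = ref, alt = alt)
  # build the mutated sequence from the event script (all vectorized):
  # copy [cur, end] of the template, append the event's contribution, repeat
  copy_end <- ifelse(snv, pos - 1L, pos)
  nxt <- pos + ifelse(del, size + 1L, 1L)
  copy_start <- c(1L, nxt[-n_ev])
  contrib <- ifelse(snv, alt, ifelse(ins, substring(alt, 2L), ""))
  pieces <- substring(seq, copy_start, copy_end)
  mutated <- paste0(paste0(pieces, contrib, collapse = ""),
                    substr(seq, nxt[n_ev], L))
  list(seq = mutated, truth = truth)
}

#' Average sequence identity implied by a truth set
#'
#' One SNV contributes one mismatch; an indel of net size n contributes n
#' mismatches. Returns `100 * (1 - total mismatches / genome size)`.
#'
#' @param truth A variant tibble.
#' @param genome_size Number of residues in the genome.
#' @return The identity percentage.
#' @export
compute_asi <- function(truth, genome_size) {
  stopifnot(genome_size > 0)
  truth <- as_tibble(truth)
  mism <- ifelse(truth$kind == "SNV", 1L,
                 abs(nchar(truth$ref) - nchar(truth$alt)))
  100 * (1 - sum(mism) / genome_size)
}
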