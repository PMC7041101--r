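# Shared fixtures built in code.

# a simple-pair row in the package's tibble layout
sp_row <- function(i1, j1, len = 50L, unique = TRUE, label = NA_character_,
                   strand = "+") {
  tibble::tibble(q_name = "q", r_name = "r", strand = strand,
                 i1 = as.integer(i1), i2 = as.integer(i1 + len - 1L),
                 j1 = as.integer(j1), j2 = as.integer(j1 + len - 1L),
                 len = as.integer(len), occ = if (unique) 1L else 2L,
                 unique = unique, pos_diff = as.integer(i1 - j1),
                 label = label)
}

# the nine-pair clustering/outlier configuration: pairs are named by their
# rank in PosDiff order; pairs 6 and 7 share a query interval (repeat copy)
nine_pair_cluster <- function() {
  conf <- list(
    # label, j1, pos_diff, unique
    list("S1", 200L, 0L, TRUE),
    list("S2", 400L, 10L, TRUE),
    list("S3", 100L, 10L, TRUE),
    list("S4", 500L, 11L, TRUE),
    list("S5", 600L, 12L, TRUE),
    list("S6", 300L, 13L, FALSE),
    list("S7", 300L, 15L, FALSE),
    list("S8", 700L, 40L, TRUE),
    list("S9", 800L, 100L, TRUE)
  )
  dplyr::bind_rows(lapply(conf, function(x) {
    sp_row(i1 = x[[2]] + x[[3]], j1 = x[[2]], len = 50L, unique = x[[4]],
           label = x[[1]])
  }))
}

# a normal pair row
np_row <- function(i1, i2, j1, j2) {
  tibble::tibble(i1 = as.integer(i1), i2 = as.integer(i2),
                 j1 = as.integer(j1), j2 = as.integer(j2))
}

# random-genome pair with planted variants, small scale
small_benchmark <- function(len = 50000L, gseed = 5L, mseed = 6L,
                            profile = wgalignr::mutation_profile(seed = NULL)) {
  p <- wgalignr::random_genome(len, seed = gseed)
  profile$seed <- mseed
  mut <- wgalignr::mutate_genome(p, profile)
  list(ref = p, qry = mut$genome, truth = mut$variants)
}

empty_variants_tbl <- function() {
  tibble::tibble(chrom = character(0), pos = integer(0), kind = character(0),
                 ref = character(0), alt = character(0))
}
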