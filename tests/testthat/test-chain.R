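# PosDiff clustering, outlier removal, duplicate resolution, gap splitting,
# overlap trimming and normal-pair gap filling.

test_that("clustering breaks exactly where sorted PosDiff jumps exceed MaxDiff", {
  pairs <- nine_pair_cluster()
  cl <- cluster_by_posdiff(pairs, seed_params(max_diff = 25))
  # sorted by PosDiff (S2/S3 tie on PosDiff 10 and sort by query position)
  expect_identical(cl$label, c("S1", "S3", "S2", paste0("S", 4:9)))
  expect_identical(cl$pos_diff, sort(pairs$pos_diff))
  expect_identical(cl$cluster[1:8], rep(1L, 8))     # |pd8 - pd9| = 60 breaks
  expect_identical(cl$cluster[9], 2L)
})

test_that("equal PosDiff values form a single cluster", {
  pairs <- dplyr::bind_rows(lapply(seq(1, 901, by = 100), function(j) {
    sp_row(i1 = j + 7L, j1 = j)
  }))
  cl <- cluster_by_posdiff(pairs, seed_params())
  expect_true(all(cl$cluster == 1L))
})

test_that("clusters equal the >MaxDiff gap partition of sorted PosDiff values", {
  set.seed(91)
  for (rep in 1:100) {
    pd <- sample(-100:100, sample(2:40, 1), replace = TRUE)
    pairs <- dplyr::bind_rows(lapply(seq_along(pd), function(t) {
      sp_row(i1 = 1000L + 60L * t + pd[t], j1 = 1000L + 60L * t)
    }))
    md <- sample(1:40, 1)
    cl <- cluster_by_posdiff(pairs, seed_params(max_diff = md))
    spd <- sort(pd)
    oracle <- cumsum(c(FALSE, diff(spd) > md)) + 1L
    expect_identical(cl$cluster, oracle)
    expect_identical(cl$pos_diff, spd)
  }
})

test_that("duplicate query positions keep the pair nearest a unique PosDiff", {
  pairs <- nine_pair_cluster()[1:8, ]  # the first PosDiff cluster
  out <- resolve_duplicates(pairs)
  expect_false("S7" %in% out$label)    # S6 kept over S7
  expect_true("S6" %in% out$label)
  expect_identical(nrow(out), 7L)
  # no duplicates present: unchanged (up to query sorting)
  nodup <- pairs[pairs$label != "S7", ]
  expect_identical(sort(resolve_duplicates(nodup)$label), sort(nodup$label))
})

test_that("duplicate resolution ties are deterministic", {
  base <- sp_row(i1 = 100L, j1 = 100L, label = "U")           # unique anchor
  d1 <- sp_row(i1 = 205L, j1 = 200L, unique = FALSE, label = "D1") # pd +5
  d2 <- sp_row(i1 = 195L, j1 = 200L, unique = FALSE, label = "D2") # pd -5
  cluster <- dplyr::bind_rows(base, d1, d2)
  out1 <- resolve_duplicates(cluster)
  out2 <- resolve_duplicates(dplyr::bind_rows(d2, base, d1))
  # |pd - 0| = 5 for both; first in sorted (j1, j2, i1) order wins: D2 (i1 195)
  expect_identical(out1$label, out2$label)
  expect_true("D2" %in% out1$label && !("D1" %in% out1$label))
})

test_that("median PosDiff decides duplicates when no unique pair exists", {
  pairs <- dplyr::bind_rows(
    sp_row(i1 = 110L, j1 = 100L, unique = FALSE, label = "A1"),  # pd 10
    sp_row(i1 = 140L, j1 = 100L, unique = FALSE, label = "A2"),  # pd 40
    sp_row(i1 = 212L, j1 = 200L, unique = FALSE, label = "B1"),  # pd 12
    sp_row(i1 = 230L, j1 = 200L, unique = FALSE, label = "B2"))  # pd 30
  out <- resolve_duplicates(pairs)
  # median pd = 21: A2 (|40-21|=19) loses to A1 (11); B1 (9) beats B2 (9)? no:
  # |12-21| = 9, |30-21| = 9: tie, first in sort order (B1, i1 212) kept
  expect_setequal(out$label, c("A1", "B1"))
})

test_that("interior and terminal outliers are removed per the two rules", {
  pairs <- resolve_duplicates(nine_pair_cluster()[1:8, ])
  out <- remove_outliers(pairs, seed_params())
  expect_identical(out$label, c("S3", "S6", "S2", "S4", "S5"))  # query order
  # identical PosDiff: nothing removed
  flat <- dplyr::bind_rows(lapply(1:5, function(t) {
    sp_row(i1 = 100L * t + 3L, j1 = 100L * t)
  }))
  expect_identical(nrow(remove_outliers(flat, seed_params())), 5L)
})

test_that("the stricter terminal tolerance can be requested", {
  pairs <- resolve_duplicates(nine_pair_cluster()[1:8, ])
  out <- remove_outliers(pairs, seed_params(terminal_tol = 5))
  # with tolerance 5, S3 (|10 - 0| = 10 > 5) is removed as well
  expect_identical(out$label, c("S6", "S2", "S4", "S5"))
})

test_that("outlier removal preserves the query order of survivors", {
  set.seed(92)
  for (rep in 1:25) {
    n <- sample(3:20, 1)
    pairs <- dplyr::bind_rows(lapply(1:n, function(t) {
      sp_row(i1 = 100L * t + sample(-30:30, 1), j1 = 100L * t,
             label = paste0("P", t))
    }))
    out <- remove_outliers(pairs, seed_params())
    kept <- pairs$label[pairs$label %in% out$label]
    expect_identical(out$label, kept)
  }
})

test_that("gaps split only when long and dissimilar", {
  params <- seed_params()
  # contiguous flanks with a configurable gap in the middle
  mk <- function(gap_p, gap_q) {
    a <- sp_row(i1 = 1L, j1 = 1L, len = 100L)
    b <- sp_row(i1 = 100L + gap_p + 1L, j1 = 100L + gap_q + 1L, len = 100L)
    dplyr::bind_rows(a, b)
  }
  flank <- random_genome(100, seed = 93)$seq
  # short gap: never splits regardless of content
  g200 <- random_genome(200, seed = 94)$seq
  h200 <- random_genome(200, seed = 95)$seq
  p <- paste0(flank, g200, flank); q <- paste0(flank, h200, flank)
  s <- split_on_dissimilar_gaps(mk(200, 200), p, q, params)
  expect_true(all(s$segment == 1L))
  # 600 bp of independent random sequence on each side: splits
  g600 <- random_genome(600, seed = 96)$seq
  h600 <- random_genome(600, seed = 97)$seq
  p <- paste0(flank, g600, flank); q <- paste0(flank, h600, flank)
  s <- split_on_dissimilar_gaps(mk(600, 600), p, q, params)
  expect_identical(s$segment, c(1L, 2L))
  # 600 bp with 1% substitutions: similar, no split
  g_chars <- strsplit(g600, "")[[1]]
  set.seed(98)
  idx <- sample(600, 6)
  g_chars[idx] <- vapply(g_chars[idx], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }, character(1))
  q <- paste0(flank, paste0(g_chars, collapse = ""), flank)
  p <- paste0(flank, g600, flank)
  s <- split_on_dissimilar_gaps(mk(600, 600), p, q, params)
  expect_true(all(s$segment == 1L))
})

test_that("overlap trimming reproduces the tandem-repeat worked example", {
  a <- np_row(301, 330, 321, 350)
  b <- np_row(323, 335, 351, 363)
  cluster <- dplyr::bind_rows(a, b)
  out <- trim_overlaps(cluster)
  expect_identical(out$i1, c(301L, 323L))
  expect_identical(out$i2, c(322L, 335L))
  expect_identical(out$j1, c(321L, 351L))
  expect_identical(out$j2, c(342L, 363L))
  # non-overlapping pairs are unchanged
  free <- dplyr::bind_rows(np_row(1, 50, 1, 50), np_row(60, 90, 60, 90))
  expect_identical(trim_overlaps(free), free)
})

test_that("after trimming no adjacent pairs overlap and fragments stay identical", {
  set.seed(99)
  for (rep in 1:20) {
    # build a genome with a tandem repeat so real overlapping seeds exist
    unit <- random_genome(sample(4:10, 1), seed = 300 + rep)$seq
    left <- random_genome(60, seed = 400 + rep)$seq
    right <- random_genome(60, seed = 500 + rep)$seq
    p <- paste0(left, strrep(unit, 5), right)
    q <- paste0(left, strrep(unit, 7), right)
    idx <- build_index(c(r = p))
    s <- find_lmems(idx, c(q = q), seed_params(k = 12, f = 12))
    s <- s[s$strand == "+", ]
    cl <- cluster_by_posdiff(s, seed_params())
    cl <- resolve_duplicates(cl[cl$cluster == 1L, ])
    out <- trim_overlaps(cl)
    n <- nrow(out)
    if (n > 1L) {
      expect_true(all(out$i1[-1L] > out$i2[-n]))
      expect_true(all(out$j1[-1L] > out$j2[-n]))
    }
    for (r in seq_len(n)) {
      expect_identical(substr(p, out$i1[r], out$i2[r]),
                       substr(q, out$j1[r], out$j2[r]))
    }
  }
})

test_that("gap filling inserts normal pairs with the boundary formulas", {
  # P gap of 10 and Q gap of 4 between the pairs
  cluster <- dplyr::bind_rows(np_row(51, 100, 151, 200),
                              np_row(111, 160, 205, 254))
  reg <- fill_gaps(cluster)
  expect_identical(reg$kind, c("simple", "normal", "simple"))
  expect_identical(unlist(reg[2, c("i1", "i2", "j1", "j2")], use.names = FALSE),
                   c(101L, 110L, 201L, 204L))
  # the trimmed worked example: P contiguous, Q gap [343, 350]
  trimmed <- trim_overlaps(dplyr::bind_rows(np_row(301, 330, 321, 350),
                                            np_row(323, 335, 351, 363)))
  reg <- fill_gaps(trimmed)
  expect_identical(reg$kind, c("simple", "normal", "simple"))
  expect_identical(unlist(reg[2, c("i1", "i2", "j1", "j2")], use.names = FALSE),
                   c(-1L, -1L, 343L, 350L))
  # contiguous pairs: no normal pair
  touching <- dplyr::bind_rows(np_row(1, 50, 1, 50), np_row(51, 90, 51, 90))
  expect_identical(fill_gaps(touching)$kind, c("simple", "simple"))
})

test_that("filled regions are contiguous on both sequences", {
  set.seed(104)
  for (rep in 1:20) {
    n <- sample(2:10, 1)
    i <- 1L; j <- 1L
    rows <- list()
    for (t in 1:n) {
      len <- sample(20:60, 1)
      rows[[t]] <- np_row(i, i + len - 1L, j, j + len - 1L)
      i <- i + len + sample(c(0L, 0L, sample(2:40, 1)), 1)
      j <- j + len + sample(c(0L, 0L, sample(2:40, 1)), 1)
    }
    reg <- fill_gaps(dplyr::bind_rows(rows))
    pi <- reg[reg$i1 > 0L, ]
    qi <- reg[reg$j1 > 0L, ]
    if (nrow(pi) > 1L) expect_true(all(pi$i1[-1L] == pi$i2[-nrow(pi)] + 1L))
    if (nrow(qi) > 1L) expect_true(all(qi$j1[-1L] == qi$j2[-nrow(qi)] + 1L))
  }
})
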