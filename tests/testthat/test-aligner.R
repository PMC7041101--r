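# Normal-pair classification, the three alignment paths, and region assembly.

test_that("normal pairs are classified I / II / III per the rules", {
  p <- "ACGTACGTACGT"
  q <- "ACCTACGTACGT"
  params <- align_params()
  # 1 mismatch in 4 (fraction 0.25 < 0.3)
  expect_identical(classify_normal_pair(np_row(1, 4, 1, 4), p, q, params), "I")
  # one empty side
  expect_identical(classify_normal_pair(np_row(-1, -1, 3, 10), p, q, params), "II")
  expect_identical(classify_normal_pair(np_row(3, 10, -1, -1), p, q, params), "II")
  # equal-length but heavily mismatching (reversed fragment)
  p2 <- "AAAACCCCGGGG"
  q2 <- "GGGGCCCCAAAA"
  expect_identical(classify_normal_pair(np_row(1, 12, 1, 12), p2, q2, params),
                   "III")
  expect_error(classify_normal_pair(np_row(-1, -1, -1, -1), p, q, params),
               "both sides empty")
})

test_that("equal-sized pairs above the provable un-gapped bound go to the DP", {
  params <- align_params()
  bound <- wgalignr:::type1_mismatch_bound(params)
  expect_identical(bound, 3L)   # 2*(8+1) %/% (2+4)
  # 4 mismatches in 60 bp: fraction 0.067 < 0.3 but above the bound
  set.seed(41)
  p <- random_genome(60, seed = 411)$seq
  pc <- strsplit(p, "")[[1]]
  qc <- pc
  for (t in c(10, 20, 30, 40)) qc[t] <- setdiff(c("A","C","G","T"), pc[t])[1]
  q <- paste0(qc, collapse = "")
  expect_identical(classify_normal_pair(np_row(1, 60, 1, 60), p, q, params),
                   "III")
})

test_that("type I alignment is a positional match/mismatch encoding", {
  pa <- align_type1(np_row(1, 4, 1, 4), "ACGT", "ACCT")
  expect_identical(pa$ops$op, c("=", "X", "="))
  expect_identical(pa$ops$len, c(2L, 1L, 1L))
  id <- align_type1(np_row(1, 6, 1, 6), "ACGTAC", "ACGTAC")
  expect_identical(id$ops$op, "=")
  expect_identical(id$ops$len, 6L)
})

test_that("type I scores agree with the gapped DP on random type I instances", {
  set.seed(43)
  params <- align_params()
  for (rep in 1:100) {
    len <- sample(10:60, 1)
    p <- random_genome(len, seed = 4000 + rep)$seq
    pc <- strsplit(p, "")[[1]]
    qc <- pc
    nmis <- sample(0:min(3, len %/% 4), 1)
    if (nmis > 0) {
      at <- sample(len, nmis)
      qc[at] <- vapply(pc[at], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1)
      }, character(1))
    }
    q <- paste0(qc, collapse = "")
    np <- np_row(1, len, 1, len)
    t1 <- align_type1(np, p, q, params)
    t3 <- align_type3(np, p, q, params)
    expect_identical(t1$score, t3$score)
  }
})

test_that("type II alignment is a single gap op that round-trips", {
  q <- "ACGTACGTAA"
  ins <- align_type2(np_row(-1, -1, 3, 10))
  expect_identical(ins$ops$op, "I")
  expect_identical(ins$ops$len, 8L)
  expect_identical(substr(q, ins$q_start, ins$q_end), "GTACGTAA")
  del <- align_type2(np_row(5, 7, -1, -1))
  expect_identical(del$ops$op, "D")
  expect_identical(del$ops$len, 3L)
})

test_that("gapped alignment scores match an exhaustive affine DP oracle", {
  params <- align_params()
  # the classic toy pair plus random fragments up to 50 bp
  cases <- list(c("GATTACA", "GATCA"))
  set.seed(44)
  for (rep in 1:40) {
    cases[[length(cases) + 1L]] <- c(
      random_genome(sample(1:50, 1), seed = 6000 + rep)$seq,
      random_genome(sample(1:50, 1), seed = 7000 + rep)$seq)
  }
  for (cs in cases) {
    np <- np_row(1, nchar(cs[1]), 1, nchar(cs[2]))
    pa <- align_type3(np, cs[1], cs[2], params)
    expect_identical(pa$score,
                     as.integer(naive_affine_score(
                       cs[1], cs[2], params$match, params$mismatch,
                       params$gap_open, params$gap_extend)),
                     info = paste(cs, collapse = " / "))
    # ops reconstruct both fragments exactly
    rec <- ops_reconstruct(pa, cs[1], cs[2])
    expect_identical(rec$p, cs[1])
    expect_identical(rec$q, cs[2])
  }
})

test_that("identical fragments align all-match; one substitution reproduces type I", {
  params <- align_params()
  p <- random_genome(30, seed = 45)$seq
  pa <- align_type3(np_row(1, 30, 1, 30), p, p, params)
  expect_identical(pa$ops$op, "=")
  expect_identical(pa$score, 60L)
  qc <- strsplit(p, "")[[1]]
  qc[17] <- setdiff(c("A", "C", "G", "T"), qc[17])[1]
  q <- paste0(qc, collapse = "")
  t3 <- align_type3(np_row(1, 30, 1, 30), p, q, params)
  t1 <- align_type1(np_row(1, 30, 1, 30), p, q, params)
  expect_identical(t3$ops, t1$ops)
})

test_that("substitutions into an identical fragment never increase the score", {
  set.seed(46)
  params <- align_params()
  for (rep in 1:20) {
    a <- random_genome(sample(10:40, 1), seed = 8000 + rep)$seq
    len <- nchar(a)
    s_id <- align_type3(np_row(1, len, 1, len), a, a, params)$score
    expect_identical(s_id, 2L * len)     # the attainable maximum
    bc <- strsplit(a, "")[[1]]
    for (k in 1:3) {
      at <- sample(len, 1)
      bc[at] <- sample(setdiff(c("A", "C", "G", "T"), bc[at]), 1)
      sk <- align_type3(np_row(1, len, 1, len), a,
                        paste0(bc, collapse = ""), params)$score
      # the identity score is the global maximum; any divergence costs score
      expect_lt(sk, s_id)
    }
  }
})

test_that("oversized fragment pairs fall back to a banded matrix with a message", {
  params <- align_params(max_cells = 1e4)
  a <- random_genome(300, seed = 47)$seq
  b <- paste0(substr(a, 1, 150), substr(a, 161, 300))  # one 10 bp deletion
  expect_message(
    pa <- align_type3(np_row(1, 300, 1, 290), a, b, params),
    "banded")
  rec <- ops_reconstruct(pa, a, b)
  expect_identical(rec$p, a)
  expect_identical(rec$q, b)
  # the band is wide enough here to still find the optimum
  expect_identical(pa$score,
                   align_type3(np_row(1, 300, 1, 290), a, b,
                               align_params())$score)
})

test_that("assemble_region concatenates pair alignments and checks contiguity", {
  params <- align_params()
  p <- "AAACCCGGGTTT"
  q <- "AAACCCTTGGGTTT"  # 2 bp insertion after position 6
  region <- tibble::tibble(kind = c("simple", "normal", "simple"),
                           i1 = c(1L, -1L, 7L), i2 = c(6L, -1L, 12L),
                           j1 = c(1L, 7L, 9L), j2 = c(6L, 8L, 14L))
  aligned <- list(NULL, align_type2(region[2, ], params), NULL)
  pa <- assemble_region(region, aligned, params)
  expect_identical(pa$ops$op, c("=", "I", "="))
  expect_identical(pa$ops$len, c(6L, 2L, 6L))
  rec <- ops_reconstruct(pa, p, q)
  expect_identical(rec$p, p)
  expect_identical(rec$q, q)
  expect_identical(nchar(rec$q), nchar(rec$p) + 2L)
  # one simple pair only: all-match
  one <- tibble::tibble(kind = "simple", i1 = 1L, i2 = 12L, j1 = 1L, j2 = 12L)
  pa1 <- assemble_region(one, list(NULL), params)
  expect_identical(pa1$ops$op, "=")
  # discontiguity is a contract violation
  bad <- tibble::tibble(kind = c("simple", "simple"),
                        i1 = c(1L, 9L), i2 = c(6L, 12L),
                        j1 = c(1L, 7L), j2 = c(6L, 10L))
  expect_error(assemble_region(bad, list(NULL, NULL), params), "contiguous")
})

test_that("align_region equals the per-pair operations composed by assemble_region", {
  params <- align_params()
  bench <- small_benchmark(len = 3000L, gseed = 48, mseed = 49,
                           profile = mutation_profile(snv_per_mb = 4000,
                                                      small_indel_per_mb = 600,
                                                      large_indel_per_mb = 300))
  idx <- build_index(bench$ref)
  seeds <- find_lmems(idx, bench$qry, seed_params(k = 15))
  regs <- chain_seeds(seeds[seeds$strand == "+", ], bench$ref$seq,
                      bench$qry$seq, seed_params())
  for (reg in regs) {
    fast <- align_region(reg, bench$ref$seq, bench$qry$seq, params)
    aligned <- lapply(seq_len(nrow(reg)), function(r) {
      if (reg$kind[r] != "normal") return(NULL)
      np <- reg[r, ]
      switch(classify_normal_pair(np, bench$ref$seq, bench$qry$seq, params),
             I = align_type1(np, bench$ref$seq, bench$qry$seq, params),
             II = align_type2(np, params),
             III = align_type3(np, bench$ref$seq, bench$qry$seq, params))
    })
    slow <- assemble_region(reg, aligned, params)
    expect_identical(fast$ops, slow$ops)
    expect_identical(fast$score, slow$score)
  }
})

test_that("assembled alignments reproduce the query over planted-variant genomes", {
  for (rep in 1:20) {
    bench <- small_benchmark(len = 4000L, gseed = 100 + rep, mseed = 200 + rep)
    idx <- build_index(bench$ref)
    seeds <- find_lmems(idx, bench$qry, seed_params(k = 20))
    regs <- chain_seeds(seeds[seeds$strand == "+", ], bench$ref$seq,
                        bench$qry$seq, seed_params())
    expect_gt(length(regs), 0L)
    for (reg in regs) {
      pa <- align_region(reg, bench$ref$seq, bench$qry$seq)
      rec <- ops_reconstruct(pa, bench$ref$seq, bench$qry$seq)
      expect_identical(rec$p, substr(bench$ref$seq, pa$p_start, pa$p_end))
      expect_identical(rec$q, substr(bench$qry$seq, pa$q_start, pa$q_end))
      # conservation: consumed spans equal region spans
      expect_identical(sum(pa$ops$len[pa$ops$op %in% c("=", "X", "D")]),
                       pa$p_end - pa$p_start + 1L)
      expect_identical(sum(pa$ops$len[pa$ops$op %in% c("=", "X", "I")]),
                       pa$q_end - pa$q_start + 1L)
    }
  }
})
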