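# Independent oracles, deliberately written without reusing package
# internals: naive string scans, a brute-force suffix sort, and a plain
# three-matrix affine-gap DP for scores.

# occurrences of pattern in text by naive scan
naive_count <- function(text, pattern) {
  n <- nchar(text); m <- nchar(pattern)
  if (m == 0L || m > n) return(0L)
  sum(vapply(1:(n - m + 1L), function(i) {
    substr(text, i, i + m - 1L) == pattern
  }, logical(1)))
}

# the text the index is built over, reconstructed independently
indexed_text <- function(genome) {
  genome <- wgalignr::as_genome(genome)
  p <- paste0(genome$seq, collapse = "#")
  rc <- vapply(rev(strsplit(p, "")[[1]]), function(ch) {
    c(A = "T", C = "G", G = "C", T = "A", N = "N", `#` = "#")[[ch]]
  }, character(1))
  paste0(p, "#", paste0(rc, collapse = ""))
}

# occurrences of a pattern on both strands of a single sequence
naive_two_strand_hits <- function(seq, pattern) {
  n <- nchar(seq); m <- nchar(pattern)
  rc <- wgalignr::revcomp(pattern)
  hits <- list()
  for (i in seq_len(max(0L, n - m + 1L))) {
    frag <- substr(seq, i, i + m - 1L)
    if (frag == pattern) hits[[length(hits) + 1L]] <- c(i, "+")
    if (frag == rc) hits[[length(hits) + 1L]] <- c(i, "-")
  }
  if (!length(hits)) {
    return(data.frame(pos = integer(0), strand = character(0)))
  }
  df <- as.data.frame(do.call(rbind, hits), stringsAsFactors = FALSE)
  names(df) <- c("pos", "strand")
  df$pos <- as.integer(df$pos)
  df[order(df$pos, df$strand), , drop = FALSE]
}

# brute-force suffix array over the constructed text (with terminator);
# symbol order: terminator < separator/N < A < C < G < T
brute_suffix_array <- function(text_with_term) {
  mapped <- chartr("$#ACGT", "!\"CDEF", text_with_term)
  n <- nchar(mapped)
  suf <- substring(mapped, 1:n, n)
  order(suf, method = "radix") - 1L
}

# plain affine-gap global DP, score only; gap of length L costs open + L*ext
naive_affine_score <- function(a, b, match = 2, mismatch = 4, open = 8,
                               ext = 2) {
  n <- nchar(a); m <- nchar(b)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)  # gap consuming a
  F_ <- matrix(NEG, n + 1, m + 1) # gap consuming b
  M[1, 1] <- 0
  for (i in 2:(n + 1)) E[i, 1] <- -(open + (i - 1) * ext)
  for (j in 2:(m + 1)) F_[1, j] <- -(open + (j - 1) * ext)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      best_diag <- max(M[i - 1, j - 1], E[i - 1, j - 1], F_[i - 1, j - 1])
      M[i, j] <- best_diag + if (av[i - 1] == bv[j - 1]) match else -mismatch
      E[i, j] <- max(E[i - 1, j] - ext,
                     max(M[i - 1, j], F_[i - 1, j]) - open - ext)
      F_[i, j] <- max(F_[i, j - 1] - ext,
                      max(M[i, j - 1], E[i, j - 1]) - open - ext)
    }
  }
  max(M[n + 1, m + 1], E[n + 1, m + 1], F_[n + 1, m + 1])
}

# reconstruct both fragments from an alignment's ops (independent of the
# package's own reconstruction helper)
ops_reconstruct <- function(pa, p_seq, q_seq) {
  p <- ""; q <- ""
  pi <- pa$p_start; qi <- pa$q_start
  for (r in seq_len(nrow(pa$ops))) {
    op <- pa$ops$op[r]; len <- pa$ops$len[r]
    if (op %in% c("=", "X", "D")) {
      p <- paste0(p, substr(p_seq, pi, pi + len - 1L)); pi <- pi + len
    }
    if (op %in% c("=", "X", "I")) {
      q <- paste0(q, substr(q_seq, qi, qi + len - 1L)); qi <- qi + len
    }
  }
  list(p = p, q = q)
}

# minimal independent MAF reader: returns a list of blocks, each a list with
# score and a data frame of s-lines
parse_maf <- function(path) {
  lines <- readLines(path)
  blocks <- list()
  cur <- NULL
  for (ln in lines) {
    if (startsWith(ln, "a ")) {
      if (!is.null(cur)) blocks[[length(blocks) + 1L]] <- cur
      cur <- list(score = as.numeric(sub("^a score=", "", ln)),
                  s = list())
    } else if (startsWith(ln, "s ")) {
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      stopifnot(length(f) == 7L)
      cur$s[[length(cur$s) + 1L]] <- data.frame(
        src = f[2], start = as.integer(f[3]), size = as.integer(f[4]),
        strand = f[5], src_size = as.integer(f[6]), text = f[7],
        stringsAsFactors = FALSE)
    }
  }
  if (!is.null(cur)) blocks[[length(blocks) + 1L]] <- cur
  blocks
}
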