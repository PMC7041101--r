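# FM-index over the reference concatenated with its reverse complement.
#
# Text layout (0-based): rec1 # rec2 # ... recR  #  revcomp(all of that)  $
# where '#' is a separator symbol that never matches a pattern residue, so no
# exact match can span a record junction, the strand junction, or a run of Ns
# (N is encoded as the separator class). Backward search over this text finds
# forward-strand occurrences in the P half and reverse-strand occurrences in
# the P' half.

#' Build an FM-index over a reference genome
#'
#' Constructs the suffix array, Burrows-Wheeler transform and rank structures
#' over the reference concatenated with its reverse complement, the exact
#' substring engine behind seed finding. Runs of N are encoded as separator
#' symbols, so seeds are never created within or across them.
#'
#' @param reference A genome (FASTA tibble from [read_fasta()], named
#'   character vector, or `DNAStringSet`).
#' @return An object of class `fm_index`.
#' @export
build_index <- function(reference) {
  reference <- as_genome(reference)
  codes_list <- lapply(reference$seq, encode_seq)
  sep <- 1L
  concat <- integer(0)
  for (i in seq_along(codes_list)) {
    if (i > 1L) concat <- c(concat, sep)
    concat <- c(concat, codes_list[[i]])
  }
  lc <- length(concat)
  text <- c(concat, sep, rev(comp_codes(concat)))
  core <- fm_build_cpp(text)
  offsets <- cumsum(c(0L, head(reference$length + 1L, -1L)))
  structure(
    list(sa = core$sa, bwt = core$bwt, cnt = core$cnt, occ = core$occ,
         n = core$n, lc = lc,
         records = tibble(name = reference$name,
                          length = reference$length,
                          offset = as.integer(offsets))),
    class = "fm_index"
  )
}

#' @export
print.fm_index <- function(x, ...) {
  cat("FM-index over", nrow(x$records), "record(s),",
      sum(x$records$length), "bp (+ reverse complement)\n")
  invisible(x)
}

#' Width (occurrence count) of a suffix-array range
#'
#' @param range An integer vector `c(lo, hi)`; the empty range is `c(0, -1)`.
#' @return `hi - lo + 1`.
#' @export
sa_range_width <- function(range) {
  max(0L, range[2] - range[1] + 1L)
}

.empty_range <- function() c(0L, -1L)

#' Backward search for a pattern
#'
#' Finds the suffix-array range of all occurrences of `pattern` in the
#' indexed text (reference plus reverse complement) in time proportional to
#' the pattern length. Patterns containing N never match; the empty pattern
#' returns the full range.
#'
#' @param index An `fm_index`.
#' @param pattern A residue string over A/C/G/T.
#' @return An integer vector `c(lo, hi)`; width 0 (`c(0, -1)`) if absent.
#' @export
backward_search <- function(index, pattern) {
  stopifnot(inherits(index, "fm_index"))
  pattern <- toupper(pattern)
  if (nchar(pattern) == 0L) return(c(0L, index$n - 1L))
  codes <- encode_seq(pattern)
  r <- fm_search_cpp(index$bwt, index$cnt, index$occ, index$n, codes)
  if (r[1] > r[2]) .empty_range() else r
}

#' Extend a suffix-array range by one symbol on the left
#'
#' Given the range of a pattern S, returns the range of symbol.S; iterating
#' over a reversed pattern reproduces [backward_search()]. The empty range is
#' absorbing, and extending with N always gives the empty range.
#'
#' @param index An `fm_index`.
#' @param range An integer vector `c(lo, hi)`.
#' @param symbol A single residue.
#' @return The extended range.
#' @export
extend_one <- function(index, range, symbol) {
  stopifnot(inherits(index, "fm_index"))
  if (sa_range_width(range) == 0L) return(.empty_range())
  code <- .sym_code_table[utf8ToInt(toupper(symbol)) + 1L]
  if (is.na(code)) abort("symbol outside {A,C,G,T,N}")
  r <- fm_extend_cpp(index$bwt, index$cnt, index$occ,
                     range[1], range[2], code)
  if (r[1] > r[2]) .empty_range() else r
}

#' Map a suffix-array range to reference positions and strands
#'
#' Translates every suffix-array entry of a (non-empty) pattern range back to
#' a 1-based position on a reference record. Hits in the reverse-complement
#' half are reported as reverse-strand hits: strand `-` at position `pos`
#' means the reverse complement of the pattern equals the forward reference
#' at `[pos, pos + len - 1]`.
#'
#' @param index An `fm_index`.
#' @param range The suffix-array range of the pattern.
#' @param len The pattern length.
#' @return A tibble with columns `name`, `pos`, `strand`.
#' @export
locate <- function(index, range, len) {
  stopifnot(inherits(index, "fm_index"))
  if (sa_range_width(range) == 0L) {
    return(tibble(name = character(0), pos = integer(0), strand = character(0)))
  }
  stopifnot(len >= 1L)
  p <- index$sa[(range[1]:range[2]) + 1L]
  lc <- index$lc
  fwd <- p <= lc - len               # hit in the P half: pattern on '+'
  g <- integer(length(p))
  g[fwd] <- p[fwd]
  g[!fwd] <- lc - (p[!fwd] - (lc + 1L)) - len
  strand <- ifelse(fwd, "+", "-")
  ri <- findInterval(g, index$records$offset)
  out <- tibble(name = index$records$name[ri],
                pos = as.integer(g - index$records$offset[ri] + 1L),
                strand = strand)
  arrange(out, .data$name, .data$pos, .data$strand)
}

#' Save an FM-index to disk
#'
#' Writes a self-describing binary container (magic string, version, arrays)
#' that round-trips bit-exactly through [load_index()].
#'
#' @param index An `fm_index`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_index <- function(index, path) {
  stopifnot(inherits(index, "fm_index"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("WGAFMI01", con, nchars = 8L, eos = NULL)
  writeBin(c(1L, index$n, index$lc, nrow(index$records)), con, size = 4L,
           endian = "little")
  for (i in seq_len(nrow(index$records))) {
    nm <- index$records$name[i]
    writeBin(nchar(nm, type = "bytes"), con, size = 4L, endian = "little")
    writeChar(nm, con, nchars = nchar(nm, type = "bytes"), eos = NULL)
  }
  writeBin(index$records$length, con, size = 4L, endian = "little")
  writeBin(index$records$offset, con, size = 4L, endian = "little")
  writeBin(length(index$sa), con, size = 4L, endian = "little")
  writeBin(index$sa, con, size = 4L, endian = "little")
  writeBin(length(index$bwt), con, size = 4L, endian = "little")
  writeBin(index$bwt, con)
  writeBin(length(index$cnt), con, size = 4L, endian = "little")
  writeBin(index$cnt, con, size = 4L, endian = "little")
  writeBin(length(index$occ), con, size = 4L, endian = "little")
  writeBin(index$occ, con, size = 4L, endian = "little")
  invisible(path)
}

#' Load an FM-index written by [save_index()]
#'
#' @param path Path to an index file.
#' @return An `fm_index`.
#' @export
load_index <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 8L, useBytes = TRUE)
  if (!identical(magic, "WGAFMI01")) abort("not a wgalignr index file")
  hdr <- readBin(con, integer(), n = 4L, size = 4L, endian = "little")
  if (hdr[1] != 1L) abort("unsupported index version")
  nrec <- hdr[4]
  names <- character(nrec)
  for (i in seq_len(nrec)) {
    nl <- readBin(con, integer(), n = 1L, size = 4L, endian = "little")
    names[i] <- readChar(con, nl, useBytes = TRUE)
  }
  lens <- readBin(con, integer(), n = nrec, size = 4L, endian = "little")
  offs <- readBin(con, integer(), n = nrec, size = 4L, endian = "little")
  nsa <- readBin(con, integer(), n = 1L, size = 4L, endian = "little")
  sa <- readBin(con, integer(), n = nsa, size = 4L, endian = "little")
  nb <- readBin(con, integer(), n = 1L, size = 4L, endian = "little")
  bwt <- readBin(con, raw(), n = nb)
  ncnt <- readBin(con, integer(), n = 1L, size = 4L, endian = "little")
  cnt <- readBin(con, integer(), n = ncnt, size = 4L, endian = "little")
  nocc <- readBin(con, integer(), n = 1L, size = 4L, endian = "little")
  occ <- readBin(con, integer(), n = nocc, size = 4L, endian = "little")
  structure(
    list(sa = sa, bwt = bwt, cnt = cnt, occ = occ, n = hdr[2], lc = hdr[3],
         records = tibble(name = names, length = lens, offset = offs)),
    class = "fm_index"
  )
}
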