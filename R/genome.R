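# Genome sequences are held as a plain tibble: one row per record with
# columns name, seq (character, uppercase over A/C/G/T/N) and length.
# Coordinates everywhere in the package are 1-based and inclusive.

.ALPHABET <- c("A", "C", "G", "T", "N")

# symbol codes shared with the C++ core:
# 0 terminator, 1 separator/N, 2 A, 3 C, 4 G, 5 T
.sym_code_table <- local({
  tab <- rep(NA_integer_, 256)
  tab[utf8ToInt("A") + 1L] <- 2L
  tab[utf8ToInt("C") + 1L] <- 3L
  tab[utf8ToInt("G") + 1L] <- 4L
  tab[utf8ToInt("T") + 1L] <- 5L
  tab[utf8ToInt("N") + 1L] <- 1L
  tab
})

#' Coerce sequences to a genome tibble
#'
#' Accepts a (named) character vector of sequences, a
#' [Biostrings::DNAStringSet], or a tibble/data frame with `name` and `seq`
#' columns. Sequences are uppercased (soft-masked lowercase residues are not
#' treated specially) and must contain only A, C, G, T or N.
#'
#' @param x Sequences in one of the accepted forms.
#' @return A tibble with columns `name`, `seq`, `length`.
#' @export
as_genome <- function(x) {
  if (inherits(x, "DNAStringSet")) {
    x <- stats::setNames(as.character(x), names(x))
  }
  if (is.character(x)) {
    nm <- names(x) %||% paste0("seq", seq_along(x))
    nm[nm == ""] <- paste0("seq", which(nm == ""))
    # FASTA headers: keep the first whitespace-delimited token
    nm <- sub("\\s.*$", "", nm)
    x <- tibble(name = nm, seq = unname(x))
  }
  if (!is.data.frame(x) || !all(c("name", "seq") %in% names(x))) {
    abort("cannot interpret input as a genome (need sequences or name/seq columns)")
  }
  g <- as_tibble(x[, c("name", "seq")])
  g$seq <- toupper(g$seq)
  g$length <- nchar(g$seq)
  if (nrow(g) == 0L || any(g$length == 0L)) {
    abort("empty genome record(s); every record needs at least one residue")
  }
  if (anyDuplicated(g$name)) abort("duplicated record names in genome")
  bad <- vapply(g$seq, function(s) {
    any(is.na(.sym_code_table[as.integer(charToRaw(s)) + 1L]))
  }, logical(1))
  if (any(bad)) {
    abort(paste0("record '", g$name[which(bad)[1]],
                 "' contains symbols outside {A,C,G,T,N}"))
  }
  g
}

#' Read a FASTA file into a genome tibble
#'
#' Multi-record files, wrapped lines, lowercase residues and N are all
#' accepted; anything outside A/C/G/T/N is rejected.
#'
#' @param path Path to a FASTA file.
#' @return A genome tibble (see [as_genome()]).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  bad <- function(cond) {
    abort(paste0("malformed FASTA '", path, "': ", conditionMessage(cond)))
  }
  # the Biostrings reader only warns on invalid residue codes; escalate
  ss <- tryCatch(Biostrings::readDNAStringSet(path),
                 error = bad, warning = bad)
  as_genome(ss)
}

#' Write a genome tibble to FASTA
#'
#' @param genome A genome tibble.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  genome <- as_genome(genome)
  ss <- Biostrings::DNAStringSet(stats::setNames(genome$seq, genome$name))
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Generate a uniform random genome
#'
#' Draws residues independently and uniformly from A/C/G/T; used to build
#' synthetic benchmark references.
#'
#' @param length Number of residues.
#' @param name Record name.
#' @param seed Optional RNG seed (restores the caller's RNG state).
#' @return A single-record genome tibble.
#' @export
random_genome <- function(length, name = "chr1", seed = NULL) {
  stopifnot(length >= 1)
  seq <- with_seed(seed, {
    rawToChar(charToRaw("ACGT")[sample.int(4L, length, replace = TRUE)])
  })
  tibble(name = name, seq = seq, length = as.integer(length))
}

#' Reverse complement of a sequence
#'
#' @param seq A character string over A/C/G/T/N.
#' @return The reverse-complemented string.
#' @export
revcomp <- function(seq) {
  vapply(seq, function(s) {
    rawToChar(rev(charToRaw(chartr("ACGTacgtNn", "TGCAtgcaNn", s))))
  }, character(1), USE.NAMES = FALSE)
}

# fetch the sequence of one record (or pass a bare string through)
record_seq <- function(genome, name = NULL) {
  if (is.character(genome) && length(genome) == 1L && is.null(name)) {
    return(toupper(genome))
  }
  g <- as_genome(genome)
  if (is.null(name)) {
    if (nrow(g) > 1L) abort("genome has several records; give a record name")
    return(g$seq[1])
  }
  i <- match(name, g$name)
  if (is.na(i)) abort(paste0("no record named '", name, "' in genome"))
  g$seq[i]
}

# accept either a bare sequence string or a genome tibble for P/Q arguments
as_seq <- function(x, name = NULL) {
  if (is.character(x) && length(x) == 1L) return(toupper(x))
  record_seq(x, name)
}

encode_seq <- function(seq) {
  codes <- .sym_code_table[as.integer(charToRaw(seq)) + 1L]
  if (anyNA(codes)) abort("sequence contains symbols outside {A,C,G,T,N}")
  codes
}

comp_codes <- function(codes) {
  out <- codes
  out[codes == 2L] <- 5L
  out[codes == 5L] <- 2L
  out[codes == 3L] <- 4L
  out[codes == 4L] <- 3L
  out
}

# run code with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
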