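# Variant extraction and VCF IO. Variants are tibbles with columns
# chrom, pos, kind ("SNV", "INS", "DEL"), ref, alt. Indels are VCF-style
# left-anchored: pos is the base before the inserted/deleted run and both
# alleles share that anchor base.

empty_variants <- function() {
  tibble(chrom = character(0), pos = integer(0), kind = character(0),
         ref = character(0), alt = character(0))
}

#' Call variants from a region alignment
#'
#' Linearly scans the edit operations of an assembled alignment: every
#' mismatch column yields one SNV, every maximal gap run one insertion or
#' deletion anchored at the preceding reference base. Applying the calls to
#' the reference over the aligned span reproduces the query span.
#'
#' Reverse-strand alignments describe inverted sequence, which has no
#' small-variant representation against the forward reference; they yield an
#' empty call set.
#'
#' @param alignment A `pairwise_alignment` (from [align_region()] or
#'   [assemble_region()]).
#' @param p_seq,q_seq Reference and query sequences the alignment refers to.
#' @return A variant tibble sorted by position.
#' @export
call_variants <- function(alignment, p_seq, q_seq) {
  stopifnot(inherits(alignment, "pairwise_alignment"))
  if (alignment$strand != "+") return(empty_variants())
  p_seq <- as_seq(p_seq); q_seq <- as_seq(q_seq)
  chrom <- alignment$p_name %||% "ref"
  op <- alignment$ops$op
  len <- alignment$ops$len
  pcons <- op %in% c("=", "X", "D")
  qcons <- op %in% c("=", "X", "I")
  pend <- alignment$p_start - 1L + cumsum(ifelse(pcons, len, 0L))
  qend <- alignment$q_start - 1L + cumsum(ifelse(qcons, len, 0L))
  pbeg <- pend - ifelse(pcons, len, 0L) + 1L
  qbeg <- qend - ifelse(qcons, len, 0L) + 1L

  out <- list()
  xi <- which(op == "X")
  if (length(xi)) {
    ppos <- unlist(lapply(xi, function(i) pbeg[i]:pend[i]))
    qpos <- unlist(lapply(xi, function(i) qbeg[i]:qend[i]))
    out$snv <- tibble(chrom = chrom, pos = as.integer(ppos), kind = "SNV",
                      ref = substring(p_seq, ppos, ppos),
                      alt = substring(q_seq, qpos, qpos))
  }
  di <- which(op == "D")
  if (length(di)) {
    anchor <- pbeg[di] - 1L
    if (any(anchor < 1L)) abort("deletion at alignment start has no anchor base")
    out$del <- tibble(chrom = chrom, pos = as.integer(anchor), kind = "DEL",
                      ref = substring(p_seq, anchor, pend[di]),
                      alt = substring(p_seq, anchor, anchor))
  }
  ii <- which(op == "I")
  if (length(ii)) {
    anchor <- pend[ii]  # last consumed reference base before the run
    if (any(anchor < 1L)) abort("insertion at alignment start has no anchor base")
    base <- substring(p_seq, anchor, anchor)
    out$ins <- tibble(chrom = chrom, pos = as.integer(anchor), kind = "INS",
                      ref = base,
                      alt = paste0(base, substring(q_seq, qbeg[ii], qend[ii])))
  }
  if (length(out) == 0L) return(empty_variants())
  arrange(bind_rows(out), .data$pos, .data$kind)
}

#' Apply variants to a reference sequence
#'
#' Replays a (non-overlapping, position-sorted) edit script against a
#' sequence; the inverse of [call_variants()] over an aligned span.
#'
#' @param seq Reference sequence (string).
#' @param variants A variant tibble for one chromosome.
#' @param from,to Span of `seq` to rebuild (defaults to the whole sequence).
#' @return The edited sequence string.
#' @export
apply_variants <- function(seq, variants, from = 1L, to = nchar(seq)) {
  seq <- as_seq(seq)
  v <- arrange(as_tibble(variants), .data$pos)
  v <- v[v$pos >= from & v$pos <= to, , drop = FALSE]
  if (nrow(v) == 0L) return(substr(seq, from, to))
  if (!all(v$kind %in% c("SNV", "INS", "DEL"))) {
    abort(paste0("unknown variant kind: ",
                 setdiff(v$kind, c("SNV", "INS", "DEL"))[1]))
  }
  n <- nrow(v)
  snv <- v$kind == "SNV"; del <- v$kind == "DEL"; ins <- v$kind == "INS"
  # template positions consumed after each event
  nxt <- v$pos + ifelse(del, nchar(v$ref) - nchar(v$alt) + 1L, 1L)
  copy_start <- c(from, nxt[-n])
  if (any(copy_start > v$pos)) abort("overlapping variants in edit script")
  copy_end <- ifelse(snv, v$pos - 1L, v$pos)
  contrib <- ifelse(snv, v$alt, ifelse(ins, substring(v$alt, 2L), ""))
  pieces <- substring(seq, copy_start, copy_end)
  paste0(paste0(pieces, contrib, collapse = ""),
         substr(seq, nxt[n], to))
}

#' Write variants as VCF
#'
#' Minimal VCF v4.2: CHROM, POS, ID, REF, ALT, QUAL, FILTER, INFO, with
#' contig header lines taken from the reference genome.
#'
#' @param variants A variant tibble.
#' @param reference The reference genome tibble (contig names and lengths).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, reference, path) {
  reference <- as_genome(reference)
  v <- arrange(as_tibble(variants), .data$chrom, .data$pos)
  if (nrow(v) && !all(v$chrom %in% reference$name)) {
    abort("variant references a contig absent from the reference genome")
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##source=wgalignr",
           sprintf("##contig=<ID=%s,length=%d>", reference$name,
                   reference$length),
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", sep = "\t"))
  body <- if (nrow(v)) {
    paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", ".",
          paste0("TYPE=", v$kind), sep = "\t")
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF file into a variant tibble
#'
#' Reads any conformant single-allele VCF (via the vcfR parser) and derives
#' the variant kind from the allele lengths.
#'
#' @param path Path to an (uncompressed or bgzipped) VCF file.
#' @return A variant tibble.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) abort(paste0("VCF file not found: ", path))
  vc <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- as.data.frame(vc@fix, stringsAsFactors = FALSE)
  if (nrow(fx) == 0L) return(empty_variants())
  if (any(grepl(",", fx$ALT, fixed = TRUE))) {
    abort("multi-allelic VCF records are not supported")
  }
  ref <- toupper(fx$REF); alt <- toupper(fx$ALT)
  kind <- dplyr::case_when(
    nchar(ref) == 1L & nchar(alt) == 1L ~ "SNV",
    nchar(alt) > nchar(ref) ~ "INS",
    nchar(ref) > nchar(alt) ~ "DEL",
    TRUE ~ NA_character_
  )
  if (anyNA(kind)) abort("VCF contains records that are neither SNV nor simple indel")
  tibble(chrom = fx$CHROM, pos = as.integer(fx$POS), kind = kind,
         ref = ref, alt = alt)
}
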