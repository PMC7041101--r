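# Output writers: MAF blocks, dot-plot segment export, and a human-readable
# pairwise rendering. Internal coordinates are 1-based inclusive; MAF starts
# are 0-based and, for the reverse strand, relative to the reverse-complement
# of the query record (the MAF convention).

gapped_texts <- function(pa, p_seq, q_seq) {
  op <- pa$ops$op; len <- pa$ops$len
  pcons <- op %in% c("=", "X", "D")
  qcons <- op %in% c("=", "X", "I")
  pend <- pa$p_start - 1L + cumsum(ifelse(pcons, len, 0L))
  qend <- pa$q_start - 1L + cumsum(ifelse(qcons, len, 0L))
  pbeg <- pend - ifelse(pcons, len, 0L) + 1L
  qbeg <- qend - ifelse(qcons, len, 0L) + 1L
  ptxt <- ifelse(pcons, substring(p_seq, pbeg, pend),
                 strrep("-", len))
  qtxt <- ifelse(qcons, substring(q_seq, qbeg, qend),
                 strrep("-", len))
  list(p = paste0(ptxt, collapse = ""), q = paste0(qtxt, collapse = ""))
}

#' Write alignments in MAF format
#'
#' One `a` block per similar region with the alignment score, and two `s`
#' lines (reference first). Starts are 0-based; reverse-strand query rows use
#' strand-relative starts as MAF specifies.
#'
#' @param x A `wga_result` from [align_genomes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_maf <- function(x, path) {
  stopifnot(inherits(x, "wga_result"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1 scoring=wgalignr", con)
  for (k in seq_along(x$alignments)) {
    pa <- x$alignments[[k]]
    reg <- x$regions[k, ]
    p_seq <- record_seq(x$reference, reg$r_name)
    q_len <- x$query$length[match(reg$q_name, x$query$name)]
    q_seq <- if (reg$strand == "+") record_seq(x$query, reg$q_name)
             else revcomp(record_seq(x$query, reg$q_name))
    tx <- gapped_texts(pa, p_seq, q_seq)
    p_len <- x$reference$length[match(reg$r_name, x$reference$name)]
    writeLines(sprintf("a score=%d", pa$score), con)
    writeLines(sprintf("s %s %d %d + %d %s", reg$r_name, reg$p_start - 1L,
                       reg$p_end - reg$p_start + 1L, p_len, tx$p), con)
    writeLines(sprintf("s %s %d %d %s %d %s", reg$q_name, reg$q_start - 1L,
                       reg$q_end - reg$q_start + 1L, reg$strand, q_len,
                       tx$q), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Export alignment segments for a dot plot
#'
#' One row per similar region with forward-frame endpoints on both genomes
#' (query on x, reference on y); reverse-strand segments descend.
#'
#' @param x A `wga_result`.
#' @param path Optional path for a tab-separated export.
#' @return The segment tibble, invisibly when `path` is given.
#' @export
export_dotplot <- function(x, path = NULL) {
  stopifnot(inherits(x, "wga_result"))
  r <- x$regions
  q_len <- x$query$length[match(r$q_name, x$query$name)]
  fwd <- r$strand == "+"
  qs <- ifelse(fwd, r$q_start, q_len - r$q_end + 1L)
  qe <- ifelse(fwd, r$q_end, q_len - r$q_start + 1L)
  seg <- tibble(q_name = r$q_name, r_name = r$r_name, strand = r$strand,
                q_start = as.integer(qs), q_end = as.integer(qe),
                r_start = ifelse(fwd, r$p_start, r$p_end),
                r_end = ifelse(fwd, r$p_end, r$p_start))
  if (!is.null(path)) {
    utils::write.table(seg, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(seg))
  }
  seg
}

#' Dot plot of an alignment result
#'
#' @param object A `wga_result`.
#' @param ... Unused.
#' @return A ggplot: query position on x, reference position on y; forward
#'   segments ascend, reverse segments descend.
#' @export
autoplot.wga_result <- function(object, ...) {
  seg <- export_dotplot(object)
  ggplot2::ggplot(seg, ggplot2::aes(x = .data$q_start, y = .data$r_start,
                                    xend = .data$q_end, yend = .data$r_end,
                                    colour = .data$strand)) +
    ggplot2::geom_segment(linewidth = 0.8) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$r_name),
                        cols = ggplot2::vars(.data$q_name)) +
    ggplot2::scale_colour_manual(values = c("+" = "#1b6ca8", "-" = "#c0392b")) +
    ggplot2::labs(x = "query position", y = "reference position",
                  colour = "strand") +
    ggplot2::theme_minimal()
}

#' @export
plot.wga_result <- function(x, ...) print(autoplot(x, ...))

#' Write a human-readable pairwise rendering
#'
#' BLAST-like text: a header per region followed by wrapped triple lines
#' (reference, match bars, query).
#'
#' @param x A `wga_result`.
#' @param path Output path.
#' @param width Residues per line.
#' @return `path`, invisibly.
#' @export
write_pairwise <- function(x, path, width = 60L) {
  stopifnot(inherits(x, "wga_result"))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(x$alignments)) {
    pa <- x$alignments[[k]]
    reg <- x$regions[k, ]
    p_seq <- record_seq(x$reference, reg$r_name)
    q_seq <- if (reg$strand == "+") record_seq(x$query, reg$q_name)
             else revcomp(record_seq(x$query, reg$q_name))
    tx <- gapped_texts(pa, p_seq, q_seq)
    pc <- strsplit(tx$p, "")[[1]]; qc <- strsplit(tx$q, "")[[1]]
    bars <- ifelse(pc == qc, "|", " ")
    writeLines(sprintf(
      "# region %d: %s[%d..%d] vs %s[%d..%d] (%s) identity %.4f score %d",
      reg$region, reg$r_name, reg$p_start, reg$p_end, reg$q_name,
      reg$q_start, reg$q_end, reg$strand, reg$identity, pa$score), con)
    for (s in seq(1L, length(pc), by = width)) {
      e <- min(s + width - 1L, length(pc))
      writeLines(c(paste0("P ", paste0(pc[s:e], collapse = "")),
                   paste0("  ", paste0(bars[s:e], collapse = "")),
                   paste0("Q ", paste0(qc[s:e], collapse = "")),
                   ""), con)
    }
  }
  invisible(path)
}
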