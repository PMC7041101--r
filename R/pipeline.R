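# End-to-end orchestration: seed -> chain -> align per (query record,
# reference record, strand) group, then variant extraction and summary.

#' Run configuration for [align_genomes()]
#'
#' @param seed A [seed_params()] object.
#' @param align An [align_params()] object.
#' @param threads Number of scan blocks per query record. Affects the work
#'   partition only; the output is identical for any value.
#' @param min_identity Regions with identity below this fraction are dropped
#'   from the report (default 0: report everything).
#' @param index A prebuilt `fm_index` for the reference, if available.
#' @param verbose Emit per-stage tallies via `message()`.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = seed_params(), align = align_params(),
                       threads = 1L, min_identity = 0, index = NULL,
                       verbose = FALSE) {
  stopifnot(inherits(seed, "seed_params"), inherits(align, "align_params"),
            threads >= 1L, min_identity >= 0, min_identity <= 1)
  structure(list(seed = seed, align = align, threads = as.integer(threads),
                 min_identity = min_identity, index = index,
                 verbose = verbose),
            class = "run_config")
}

alignment_identity <- function(pa) {
  cols <- sum(pa$ops$len)
  matches <- sum(pa$ops$len[pa$ops$op == "="])
  if (cols == 0L) 0 else matches / cols
}

#' Align two genomes and call variants
#'
#' The full pipeline: LMEM seeding against the FM-index, PosDiff chaining
#' into similar regions, gap closing by un-gapped scan / pure indel /
#' affine-gap DP, and variant extraction from the assembled alignments.
#' Every query record is aligned against all reference records; the output
#' is deterministic and independent of the block/thread count.
#'
#' @param reference,query Genomes (FASTA tibbles, named character vectors,
#'   or paths accepted by [as_genome()] / [read_fasta()]).
#' @param config A [run_config()] object.
#' @return A `wga_result` with elements `regions` (tibble), `alignments`
#'   (list of `pairwise_alignment`, parallel to the region rows),
#'   `variants` (tibble), `reference`, `query`, `config`.
#' @export
align_genomes <- function(reference, query, config = run_config()) {
  reference <- as_genome(reference)
  query <- as_genome(query)
  idx <- config$index %||% build_index(reference)
  say <- function(...) if (config$verbose) message(sprintf(...))

  seeds <- find_lmems(idx, query, config$seed, n_blocks = config$threads)
  say("seeding: %d simple pairs (%d unique)", nrow(seeds), sum(seeds$unique))

  qrc_cache <- new.env(parent = emptyenv())
  q_strand_seq <- function(qname, strand) {
    s <- record_seq(query, qname)
    if (strand == "+") return(s)
    key <- qname
    if (is.null(qrc_cache[[key]])) qrc_cache[[key]] <- revcomp(s)
    qrc_cache[[key]]
  }

  regions <- list(); alignments <- list(); variants <- list()
  if (nrow(seeds)) {
    grp_key <- paste(seeds$q_name, seeds$r_name, seeds$strand, sep = "\r")
    for (g in split(seeds, grp_key)) {
      qname <- g$q_name[1]; rname <- g$r_name[1]; strand <- g$strand[1]
      p_seq <- record_seq(reference, rname)
      q_seq <- q_strand_seq(qname, strand)
      regs <- chain_seeds(g, p_seq, q_seq, config$seed)
      for (reg in regs) {
        pa <- align_region(reg, p_seq, q_seq, config$align)
        id <- alignment_identity(pa)
        if (id < config$min_identity) next
        k <- length(regions) + 1L
        regions[[k]] <- tibble(
          q_name = qname, r_name = rname, strand = strand,
          p_start = pa$p_start, p_end = pa$p_end,
          q_start = pa$q_start, q_end = pa$q_end,
          n_pairs = nrow(reg),
          n_normal = sum(reg$kind == "normal"),
          columns = sum(pa$ops$len),
          identity = id, score = pa$score)
        alignments[[k]] <- pa
        if (strand == "+") {
          variants[[length(variants) + 1L]] <- call_variants(pa, p_seq, q_seq)
        }
      }
    }
  }
  regions <- if (length(regions)) bind_rows(regions) else
    tibble(q_name = character(0), r_name = character(0),
           strand = character(0), p_start = integer(0), p_end = integer(0),
           q_start = integer(0), q_end = integer(0), n_pairs = integer(0),
           n_normal = integer(0), columns = integer(0),
           identity = numeric(0), score = numeric(0))
  ord <- order(regions$r_name, regions$p_start, regions$q_name,
               regions$q_start)
  regions <- regions[ord, , drop = FALSE]
  regions$region <- seq_len(nrow(regions))
  regions <- regions[, c("region", setdiff(names(regions), "region"))]
  alignments <- alignments[ord]
  variants <- if (length(variants)) {
    arrange(bind_rows(variants), .data$chrom, .data$pos, .data$kind)
  } else empty_variants()
  say("chained %d region(s); %d variant(s) called", nrow(regions),
      nrow(variants))
  structure(list(regions = regions, alignments = alignments,
                 variants = variants, reference = reference, query = query,
                 config = config),
            class = "wga_result")
}

#' @export
print.wga_result <- function(x, ...) {
  cat("whole-genome alignment:",
      nrow(x$regions), "region(s),",
      sum(x$regions$columns), "alignment columns,",
      nrow(x$variants), "variant(s)\n")
  if (nrow(x$regions)) {
    cat(sprintf("  mean identity %.4f\n",
                sum(x$regions$identity * x$regions$columns) /
                  sum(x$regions$columns)))
  }
  invisible(x)
}

#' Tidy the variants of an alignment result
#'
#' @param x A `wga_result`.
#' @param ... Unused.
#' @return The variant tibble.
#' @export
tidy.wga_result <- function(x, ...) x$variants

#' One-row summary of an alignment result
#'
#' @param x A `wga_result`.
#' @param ... Unused.
#' @return A one-row tibble with region counts, aligned bases, weighted mean
#'   identity, and per-class variant counts.
#' @export
glance.wga_result <- function(x, ...) {
  tibble(
    n_regions = nrow(x$regions),
    aligned_ref_bases = sum(x$regions$p_end - x$regions$p_start + 1L),
    aligned_columns = sum(x$regions$columns),
    mean_identity = if (nrow(x$regions)) {
      sum(x$regions$identity * x$regions$columns) / sum(x$regions$columns)
    } else NA_real_,
    n_snv = sum(x$variants$kind == "SNV"),
    n_ins = sum(x$variants$kind == "INS"),
    n_del = sum(x$variants$kind == "DEL")
  )
}
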