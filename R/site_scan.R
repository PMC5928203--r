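## Genome-wide scanning for candidate binding sites with strong/weak
## score thresholds.

#' Score fixed-length sequences under a motif model
#'
#' The score of a sequence is the sum of positional weights,
#' `sum_j w(seq[j], j)`.  Because the weight matrix is palindromic, a
#' sequence and its reverse complement score identically.  Sequences
#' containing non-ACGT symbols score `NA`.
#'
#' @param model a [motif_model()].
#' @param seqs character vector of sequences, each of length `model$L`.
#' @return numeric vector of scores.
#' @export
score_site <- function(model, seqs) {
  stopifnot(inherits(model, "motif_model"))
  vapply(toupper(seqs), function(s) {
    if (nchar(s) != model$L)
      stopf("sequence length %d != motif length %d", nchar(s), model$L)
    idx <- base_codes(s)
    if (anyNA(idx)) return(NA_real_)
    sum(model$weights[cbind(idx, seq_len(model$L))])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Scan one upstream region for binding sites
#'
#' Slides the palindromic PWM across the region and reports every window
#' scoring at least the weak threshold.  Because the matrix equals its own
#' reverse-complement mirror, forward and reverse reads of the same
#' interval score identically; each interval is therefore reported once
#' with strand `"."`.  Windows overlapping any non-ACGT base are skipped.
#'
#' @param model a [motif_model()] with calibrated thresholds.
#' @param region an `upstream_region` from [extract_upstream()].
#' @param genome_id genome identifier recorded in the hits.
#' @return data frame of hits sorted by score (descending) with columns
#'   `motif`, `genome_id`, `target_gene`, `contig`, `abs_start`, `abs_end`,
#'   `strand`, `sequence`, `score`, `class` (`strong`/`weak`),
#'   `pos_vs_start_codon` (signed offset of the site start relative to the
#'   start codon, gene orientation) and `region_offset`.
#' @export
scan_region <- function(model, region, genome_id = NA_character_) {
  stopifnot(inherits(model, "motif_model"), inherits(region, "upstream_region"))
  if (is.na(model$weak_threshold)) stopf("motif '%s' has no calibrated thresholds", model$name)
  codes <- base_codes(region$seq)
  S <- scan_scores(model$weights, codes)
  keep <- which(!is.na(S) & S >= model$weak_threshold)
  L <- model$L
  if (!length(keep)) return(empty_hits())
  off <- keep - 1L
  abs_start <- if (region$strand == "+") region$abs_start + off
               else region$abs_end - off - L
  hits <- data.frame(
    motif = model$name,
    genome_id = genome_id,
    target_gene = region$gene_id,
    contig = region$contig_id,
    abs_start = abs_start,
    abs_end = abs_start + L,
    strand = ".",
    sequence = vapply(keep, function(i) substr(region$seq, i, i + L - 1L), character(1)),
    score = S[keep],
    class = ifelse(S[keep] >= model$strong_threshold, "strong", "weak"),
    pos_vs_start_codon = off - region$offset_start_codon,
    region_offset = off,
    stringsAsFactors = FALSE)
  hits[order(-hits$score), , drop = FALSE]
}

empty_hits <- function() {
  data.frame(motif = character(0), genome_id = character(0),
             target_gene = character(0), contig = character(0),
             abs_start = integer(0), abs_end = integer(0),
             strand = character(0), sequence = character(0),
             score = numeric(0), class = character(0),
             pos_vs_start_codon = integer(0), region_offset = integer(0),
             stringsAsFactors = FALSE)
}

#' Scan all operon-leader upstream regions of a genome
#'
#' A site in the shared intergenic region of a divergently transcribed gene
#' pair falls inside both leaders' windows and is attributed to both
#' targets (two hit rows, one genomic interval, `shared = TRUE`), the
#' arrangement through which one palindromic operator co-regulates two
#' divergent operons.
#'
#' @param model a [motif_model()].
#' @param g a [genome()].
#' @param operons output of [group_operons()]; computed if `NULL`.
#' @param window upstream window, see [extract_upstream()].
#' @param max_gap_bp operon gap threshold when `operons` is `NULL`.
#' @return data frame of hits as in [scan_region()], plus `shared`.
#' @export
scan_genome <- function(model, g, operons = NULL, window = c(-350, 50),
                        max_gap_bp = 150) {
  stopifnot(inherits(g, "genome"))
  regions <- leader_upstream_regions(g, operons, window, max_gap_bp)
  hits <- do.call(rbind, lapply(regions, scan_region, model = model,
                                genome_id = g$genome_id))
  if (is.null(hits) || !nrow(hits)) {
    out <- empty_hits(); out$shared <- logical(0); return(out)
  }
  rownames(hits) <- NULL
  key <- paste(hits$contig, hits$abs_start, sep = ":")
  hits$shared <- ave(seq_along(key), key, FUN = length) > 1L
  hits[order(-hits$score), , drop = FALSE]
}

#' Export site hits as GFF3
#'
#' Writes hits as `TF_binding_site` features with `motif`, `score`, `class`
#' and `target_gene` attributes, 1-based inclusive coordinates per the GFF3
#' standard.
#'
#' @param hits data frame from [scan_region()]/[scan_genome()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_hits_gff3 <- function(hits, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = hits$contig,
    ranges = IRanges::IRanges(start = hits$abs_start + 1L, end = hits$abs_end),
    strand = "*")
  gr$type <- "TF_binding_site"
  gr$source <- "regulonscan"
  gr$motif <- hits$motif
  gr$score <- hits$score
  gr$site_class <- hits$class
  gr$target_gene <- hits$target_gene
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Export site hits as TSV
#'
#' Column order is fixed: motif, genome_id, target_gene, contig, abs_start,
#' abs_end, strand, sequence, score, class, pos_vs_start_codon.
#'
#' @inheritParams write_hits_gff3
#' @export
write_hits_tsv <- function(hits, path) {
  cols <- c("motif", "genome_id", "target_gene", "contig", "abs_start",
            "abs_end", "strand", "sequence", "score", "class",
            "pos_vs_start_codon")
  utils::write.table(hits[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
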