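## Genome input/output, operon grouping and upstream-region extraction.
##
## Coordinate convention (used everywhere in this package): 0-based half-open
## intervals on the forward genome strand.  "Position relative to the start
## codon" places the first base of the start codon at offset 0.

#' Construct a genome object
#'
#' A `genome` bundles contig sequences with strand-aware gene annotations.
#' Gene coordinates are 0-based half-open on the forward strand.
#'
#' @param genome_id single string identifying the genome.
#' @param contigs named character vector of nucleotide sequences.
#' @param genes data frame with columns `gene_id`, `contig_id`, `start`,
#'   `end`, `strand` (`"+"`/`"-"`), `protein` (amino-acid string) and
#'   optionally `role` (functional-role label; `NA` when unannotated).
#' @return object of class `genome`.
#' @export
genome <- function(genome_id, contigs, genes) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L)
  if (is.null(names(contigs)) || anyNA(names(contigs)))
    stopf("contigs must be a named character vector")
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  req <- c("gene_id", "contig_id", "start", "end", "strand", "protein")
  miss <- setdiff(req, names(genes))
  if (length(miss)) stopf("genes table lacks column(s): %s", paste(miss, collapse = ", "))
  if (!"role" %in% names(genes)) genes$role <- NA_character_
  if (anyDuplicated(genes$gene_id))
    stopf("duplicate gene ids: %s",
          paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  if (any(!genes$contig_id %in% names(contigs)))
    stopf("gene(s) reference unknown contig(s): %s",
          paste(unique(setdiff(genes$contig_id, names(contigs))), collapse = ", "))
  if (any(genes$start >= genes$end)) stopf("gene start must be < end")
  if (any(!genes$strand %in% c("+", "-"))) stopf("strand must be '+' or '-'")
  clen <- nchar(contigs)[genes$contig_id]
  if (any(genes$start < 0L | genes$end > clen))
    stopf("gene coordinates outside contig bounds")
  structure(list(genome_id = genome_id,
                 contigs = vapply(contigs, toupper, character(1)),
                 genes = genes[order(genes$contig_id, genes$start), , drop = FALSE]),
            class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %s: %d contig(s), %d gene(s), %s bp\n",
              x$genome_id, length(x$contigs), nrow(x$genes),
              format(sum(nchar(x$contigs)), big.mark = ",")))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Readers

#' Load an annotated genome
#'
#' Reads either a GenBank flat file or a FASTA + GFF3 pair into a [genome()].
#' One gene is created per CDS feature; protein sequences are taken from the
#' annotation (`/translation` or a `translation` attribute) or translated
#' from the nucleotide sequence with the bacterial genetic code (table 11).
#'
#' @param path path to the GenBank file, or the FASTA file for
#'   `format = "fasta+gff3"`.
#' @param format `"genbank"` or `"fasta+gff3"`.
#' @param gff_path path to the GFF3 file (required for `"fasta+gff3"`).
#' @param genome_id genome identifier; defaults to the file base name.
#' @return a [genome()] object.
#' @export
load_genome <- function(path, format = c("genbank", "fasta+gff3"),
                        gff_path = NULL, genome_id = NULL) {
  format <- match.arg(format)
  genome_id <- genome_id %||% sub("\\.[^.]*$", "", basename(path))
  if (format == "genbank") load_genbank(path, genome_id)
  else {
    if (is.null(gff_path)) stopf("gff_path is required for format 'fasta+gff3'")
    load_fasta_gff3(path, gff_path, genome_id)
  }
}

translate_cds <- function(dna) {
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(dna),
    genetic.code = Biostrings::getGeneticCode("11"),
    if.fuzzy.codon = "X"))
  sub("\\*$", "", aa)
}

load_fasta_gff3 <- function(fasta_path, gff_path, genome_id) {
  contigs_set <- tryCatch(Biostrings::readDNAStringSet(fasta_path),
                          error = function(e) stopf("cannot parse FASTA '%s': %s",
                                                    fasta_path, conditionMessage(e)))
  contigs <- as.character(contigs_set)
  names(contigs) <- sub("\\s.*$", "", names(contigs))
  gff <- tryCatch(rtracklayer::import(gff_path, format = "gff3"),
                  error = function(e) stopf("cannot parse GFF3 '%s': %s",
                                            gff_path, conditionMessage(e)))
  cds <- gff[gff$type == "CDS"]
  bad <- setdiff(unique(as.character(GenomicRanges::seqnames(cds))), names(contigs))
  if (length(bad))
    stopf("GFF3 references contig(s) absent from FASTA: %s", paste(bad, collapse = ", "))
  md <- S4Vectors::mcols(cds)
  ids <- if ("locus_tag" %in% names(md)) as.character(md$locus_tag)
         else if ("ID" %in% names(md)) as.character(md$ID) else NA_character_
  keep <- !is.na(ids)
  if (any(!keep)) warnf("skipping %d CDS feature(s) without locus tag/ID", sum(!keep))
  cds <- cds[keep]; md <- S4Vectors::mcols(cds); ids <- ids[keep]
  start0 <- GenomicRanges::start(cds) - 1L   # GFF3 is 1-based inclusive
  end0 <- GenomicRanges::end(cds)
  strand <- as.character(GenomicRanges::strand(cds))
  strand[!strand %in% c("+", "-")] <- "+"
  contig_id <- as.character(GenomicRanges::seqnames(cds))
  prot <- if ("translation" %in% names(md)) as.character(md$translation) else rep(NA_character_, length(cds))
  role <- if ("role" %in% names(md)) as.character(md$role) else rep(NA_character_, length(cds))
  for (i in seq_along(ids)) {
    if (is.na(prot[i])) {
      dna <- substr(contigs[[contig_id[i]]], start0[i] + 1L, end0[i])
      if (strand[i] == "-") dna <- revcomp(dna)
      prot[i] <- translate_cds(dna)
    }
  }
  genome(genome_id, contigs,
         data.frame(gene_id = ids, contig_id = contig_id, start = start0,
                    end = end0, strand = strand, protein = prot, role = role,
                    stringsAsFactors = FALSE))
}

## Minimal GenBank flat-file parser: LOCUS/FEATURES/ORIGIN, CDS features with
## simple or complement() locations.  join() and fuzzy locations are skipped
## with a warning.  No pre-installed R package reads GenBank feature tables,
## hence the hand-written reader.
load_genbank <- function(path, genome_id) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(grepl("^LOCUS", lines)))
    stopf("'%s' does not look like a GenBank flat file (no LOCUS line)", path)
  rec_start <- grep("^LOCUS", lines)
  rec_end <- c(rec_start[-1] - 1L, length(lines))
  contigs <- character(0)
  genes <- list()
  for (r in seq_along(rec_start)) {
    rl <- lines[rec_start[r]:rec_end[r]]
    contig_id <- strsplit(trimws(sub("^LOCUS", "", rl[1])), "\\s+")[[1]][1]
    oi <- grep("^ORIGIN", rl)
    if (!length(oi)) stopf("GenBank record '%s' has no ORIGIN section", contig_id)
    seq_lines <- rl[(oi[1] + 1L):length(rl)]
    seq_lines <- seq_lines[!grepl("^//", seq_lines)]
    seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
    contigs[contig_id] <- seq
    fi <- grep("^FEATURES", rl)
    if (!length(fi)) next
    feat <- rl[(fi[1] + 1L):(oi[1] - 1L)]
    # split the feature table into features: new feature = key at column 6
    starts <- grep("^ {5}\\S", feat)
    if (!length(starts)) next
    ends <- c(starts[-1] - 1L, length(feat))
    for (k in seq_along(starts)) {
      block <- feat[starts[k]:ends[k]]
      key <- strsplit(trimws(block[1]), "\\s+")[[1]][1]
      if (key != "CDS") next
      loc <- trimws(sub("^ {5}\\S+\\s*", "", block[1]))
      # continuation lines before the first qualifier belong to the location
      qstart <- grep("^\\s+/", block)
      loc_extra <- if (length(qstart) && qstart[1] > 2) block[2:(qstart[1] - 1L)]
                   else if (!length(qstart) && length(block) > 1) block[-1] else character(0)
      loc <- paste0(loc, paste(trimws(loc_extra), collapse = ""))
      strand <- if (grepl("^complement\\(", loc)) "-" else "+"
      core <- gsub("^complement\\(|\\)$", "", loc)
      if (grepl("join|order|[<>]", core) || !grepl("^\\d+\\.\\.\\d+$", core)) {
        warnf("skipping CDS with unsupported location '%s' in record %s", loc, contig_id)
        next
      }
      se <- as.integer(strsplit(core, "\\.\\.")[[1]])
      quals <- if (length(qstart)) parse_gb_qualifiers(block[qstart[1]:length(block)]) else list()
      gid <- quals[["locus_tag"]] %||% quals[["gene"]] %||% sprintf("%s_cds%d", contig_id, k)
      prot <- quals[["translation"]]
      if (is.null(prot)) {
        dna <- substr(seq, se[1], se[2])
        if (strand == "-") dna <- revcomp(dna)
        prot <- translate_cds(dna)
      }
      genes[[length(genes) + 1L]] <- data.frame(
        gene_id = gid, contig_id = contig_id, start = se[1] - 1L, end = se[2],
        strand = strand, protein = prot,
        role = quals[["gene"]] %||% NA_character_, stringsAsFactors = FALSE)
    }
  }
  if (!length(genes)) stopf("no CDS features found in '%s'", path)
  genome(genome_id, contigs, do.call(rbind, genes))
}

parse_gb_qualifiers <- function(qlines) {
  if (!length(qlines)) return(list())
  txt <- trimws(qlines)
  # merge continuation lines (those not starting with "/") into the previous
  starts <- grepl("^/", txt)
  grp <- cumsum(starts)
  merged <- vapply(split(txt, grp), paste, character(1), collapse = "")
  out <- list()
  for (m in merged) {
    m <- sub("^/", "", m)
    if (grepl("=", m, fixed = TRUE)) {
      key <- sub("=.*$", "", m)
      val <- gsub("^\"|\"$", "", sub("^[^=]+=", "", m))
      out[[key]] <- val
    } else out[[m]] <- TRUE
  }
  out
}

## ---------------------------------------------------------------------------
## Writers (plain-text FASTA + GFF3; site hits are exported by site_scan)

#' Write a genome as FASTA + GFF3
#'
#' @param g a [genome()].
#' @param fasta_path,gff_path output paths.
#' @return invisibly, the two paths. CDS rows carry `locus_tag`,
#'   `translation` and (when present) `role` attributes; coordinates are
#'   1-based inclusive per the GFF3 standard.
#' @export
write_genome <- function(g, fasta_path, gff_path) {
  stopifnot(inherits(g, "genome"))
  seqs <- Biostrings::DNAStringSet(g$contigs)
  Biostrings::writeXStringSet(seqs, fasta_path)
  gr <- GenomicRanges::GRanges(
    seqnames = g$genes$contig_id,
    ranges = IRanges::IRanges(start = g$genes$start + 1L, end = g$genes$end),
    strand = g$genes$strand)
  gr$type <- "CDS"
  gr$source <- "regulonscan"
  gr$phase <- 0L
  gr$ID <- g$genes$gene_id
  gr$locus_tag <- g$genes$gene_id
  gr$translation <- g$genes$protein
  gr$role <- g$genes$role
  rtracklayer::export(gr, gff_path, format = "gff3")
  invisible(c(fasta_path, gff_path))
}

## ---------------------------------------------------------------------------
## Operons

#' Group genes into operons
#'
#' Consecutive same-strand genes on one contig whose intergenic gap is at
#' most `max_gap_bp` are merged into one operon.  The operon leader is its
#' first gene in transcription order (leftmost for `+`, rightmost for `-`);
#' regulation is attributed to the leader's upstream region.
#'
#' @param g a [genome()].
#' @param max_gap_bp maximum intergenic gap in bp (default 150, a
#'   conventional prokaryotic operon gap).
#' @return data frame with columns `operon_id`, `gene_id`, `contig_id`,
#'   `strand`, `is_leader`, ordered by contig and coordinate.
#' @export
group_operons <- function(g, max_gap_bp = 150) {
  stopifnot(inherits(g, "genome"))
  genes <- g$genes[order(g$genes$contig_id, g$genes$start), , drop = FALSE]
  n <- nrow(genes)
  op <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    new_op <- i == 1L ||
      genes$contig_id[i] != genes$contig_id[i - 1L] ||
      genes$strand[i] != genes$strand[i - 1L] ||
      (genes$start[i] - genes$end[i - 1L]) > max_gap_bp
    if (new_op) cur <- cur + 1L
    op[i] <- cur
  }
  out <- data.frame(operon_id = sprintf("%s_op%04d", g$genome_id, op),
                    gene_id = genes$gene_id,
                    contig_id = genes$contig_id,
                    strand = genes$strand,
                    is_leader = FALSE,
                    stringsAsFactors = FALSE)
  for (o in split(seq_len(n), op)) {
    lead <- if (genes$strand[o[1]] == "+") o[1] else o[length(o)]
    out$is_leader[lead] <- TRUE
  }
  out
}

## ---------------------------------------------------------------------------
## Upstream regions

#' Extract the upstream window of a gene
#'
#' Returns the window around the annotated start codon (default -350..+50),
#' oriented 5'->3' relative to the gene (reverse-complemented for `-` strand
#' genes) and clipped at contig ends.  The window is deliberately not
#' truncated at the boundary of the preceding gene; overlap with upstream
#' coding sequence is flagged instead.
#'
#' @param g a [genome()].
#' @param gene_id gene identifier.
#' @param window integer length-2, offsets relative to the start codon
#'   (default `c(-350, 50)`).
#' @return list of class `upstream_region` with fields `gene_id`,
#'   `contig_id`, `abs_start`, `abs_end` (forward-strand genome coords),
#'   `strand`, `seq`, `offset_start_codon` (position in `seq` of the start
#'   codon; equals `nchar(seq) - window[2]` when no clipping occurred) and
#'   `overlaps_upstream_gene`.
#' @export
extract_upstream <- function(g, gene_id, window = c(-350, 50)) {
  stopifnot(inherits(g, "genome"), length(window) == 2L, window[1] < window[2])
  i <- match(gene_id, g$genes$gene_id)
  if (is.na(i)) stopf("gene '%s' not found in genome '%s'", gene_id, g$genome_id)
  gene <- g$genes[i, ]
  clen <- nchar(g$contigs[[gene$contig_id]])
  if (gene$strand == "+") {
    a <- gene$start + window[1]; b <- gene$start + window[2]
  } else {
    a <- gene$end - window[2]; b <- gene$end - window[1]
  }
  a0 <- max(0L, a); b0 <- min(clen, b)
  if (b0 <= a0) stopf("upstream window of '%s' lies entirely off the contig", gene_id)
  fwd <- substr(g$contigs[[gene$contig_id]], a0 + 1L, b0)
  seq <- if (gene$strand == "+") fwd else revcomp(fwd)
  offset <- if (gene$strand == "+") gene$start - a0 else b0 - gene$end
  other <- g$genes[-i, , drop = FALSE]
  other <- other[other$contig_id == gene$contig_id, , drop = FALSE]
  overlaps <- any(other$start < b0 & other$end > a0)
  structure(list(gene_id = gene$gene_id, contig_id = gene$contig_id,
                 abs_start = a0, abs_end = b0, strand = gene$strand,
                 seq = seq, offset_start_codon = offset,
                 overlaps_upstream_gene = overlaps),
            class = "upstream_region")
}

#' Upstream regions of all operon leaders
#'
#' @inheritParams extract_upstream
#' @param operons output of [group_operons()]; computed if `NULL`.
#' @return named list of `upstream_region` objects, one per operon leader.
#' @export
leader_upstream_regions <- function(g, operons = NULL, window = c(-350, 50),
                                    max_gap_bp = 150) {
  if (is.null(operons)) operons <- group_operons(g, max_gap_bp)
  leaders <- operons$gene_id[operons$is_leader]
  out <- lapply(leaders, function(id) extract_upstream(g, id, window))
  names(out) <- leaders
  out
}
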