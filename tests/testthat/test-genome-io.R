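test_that("GenBank and FASTA+GFF3 readers produce equivalent genomes", {
  gb <- withr::local_tempfile(fileext = ".gbk")
  writeLines(genbank_fixture_text(), gb)
  g1 <- load_genome(gb, format = "genbank", genome_id = "fix")
  expect_equal(nrow(g1$genes), 2L)
  expect_equal(g1$genes$strand[order(g1$genes$start)], c("+", "-"))
  expect_equal(g1$genes$start[order(g1$genes$start)], c(100L, 300L))
  expect_equal(g1$genes$end[order(g1$genes$start)], c(220L, 420L))
  expect_equal(sort(g1$genes$gene_id), c("GB_0001", "GB_0002"))
  expect_equal(g1$genes$role[g1$genes$gene_id == "GB_0001"], "araB")

  fa <- withr::local_tempfile(fileext = ".fasta")
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_genome(g1, fa, gff)
  g2 <- load_genome(fa, format = "fasta+gff3", gff_path = gff, genome_id = "fix")
  expect_equal(g2$genes[, c("gene_id", "contig_id", "start", "end", "strand")],
               g1$genes[, c("gene_id", "contig_id", "start", "end", "strand")])
  expect_equal(g2$contigs, g1$contigs)
})

test_that("GFF3 referencing a contig absent from the FASTA is an error naming it", {
  g <- toy_genome()
  fa <- withr::local_tempfile(fileext = ".fasta")
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_genome(g, fa, gff)
  bad <- sub("^chr\t", "ghost\t", readLines(gff))
  writeLines(bad, gff)
  expect_error(load_genome(fa, format = "fasta+gff3", gff_path = gff), "ghost")
})

test_that("missing translations are filled with bacterial-code translation", {
  gb <- withr::local_tempfile(fileext = ".gbk")
  writeLines(genbank_fixture_text(), gb)
  g <- load_genome(gb, format = "genbank")
  # GB_0002 has no /translation qualifier: protein must come from the DNA
  dna <- revcomp(substr(g$contigs[["ctgA"]], 301, 420))
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(dna),
    genetic.code = Biostrings::getGeneticCode("11")))
  expect_equal(g$genes$protein[g$genes$gene_id == "GB_0002"],
               sub("\\*$", "", aa))
})

test_that("operon grouping merges by strand and gap, and leaders face transcription", {
  mk <- function(starts, ends, strands) {
    seq <- strrep("A", 10000)
    genome("opA", c(c1 = seq),
           data.frame(gene_id = paste0("g", seq_along(starts)), contig_id = "c1",
                      start = starts, end = ends, strand = strands,
                      protein = "M", stringsAsFactors = FALSE))
  }
  # gaps 40 and 60, all +: one operon of three, leader leftmost
  g <- mk(c(100, 440, 800), c(400, 740, 1100), c("+", "+", "+"))
  op <- group_operons(g, max_gap_bp = 150)
  expect_equal(length(unique(op$operon_id)), 1L)
  expect_equal(op$gene_id[op$is_leader], "g1")
  # 500 bp gap: two single-gene operons
  g <- mk(c(100, 900), c(400, 1200), c("+", "+"))
  op <- group_operons(g, max_gap_bp = 150)
  expect_equal(length(unique(op$operon_id)), 2L)
  # divergent pair: two operons, both leaders face the shared region
  g <- mk(c(100, 900), c(400, 1200), c("-", "+"))
  op <- group_operons(g, max_gap_bp = 150)
  expect_equal(length(unique(op$operon_id)), 2L)
  expect_true(all(op$is_leader))
  # - strand run: leader is the rightmost gene
  g <- mk(c(100, 440), c(400, 740), c("-", "-"))
  op <- group_operons(g, max_gap_bp = 150)
  expect_equal(op$gene_id[op$is_leader], "g2")
})

test_that("operon grouping is idempotent and independent of input row order", {
  cl <- generate_clade(simulation_config(n_genomes = 2, seed = 31))
  g <- cl$genomes[[1]]
  op1 <- group_operons(g)
  g_shuf <- g
  g_shuf$genes <- g$genes[rev(seq_len(nrow(g$genes))), ]
  op2 <- group_operons(g_shuf)
  expect_equal(op1, op2)
})

test_that("upstream windows follow the -350..+50 rule with clipping", {
  g <- toy_genome()
  # + strand gene with start codon at 1000 on a 5 kb contig
  r <- extract_upstream(g, "gA")
  expect_equal(c(r$abs_start, r$abs_end), c(650L, 1050L))
  expect_equal(nchar(r$seq), 400L)
  expect_equal(r$offset_start_codon, 350L)
  expect_equal(r$seq, substr(g$contigs[["chr"]], 651, 1050))
  # - strand gene: start codon at the annotation end (3600)
  r <- extract_upstream(g, "gB")
  expect_equal(c(r$abs_start, r$abs_end), c(3550L, 3950L))
  # independent one-liner oracle: reverse complement of the forward slice
  expect_equal(r$seq, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(g$contigs[["chr"]], 3551, 3950)))))
  # clipping at the contig start
  gc <- genome("clip", c(c1 = strrep("ACGT", 500)),
               data.frame(gene_id = "g1", contig_id = "c1", start = 100L,
                          end = 400L, strand = "+", protein = "M",
                          stringsAsFactors = FALSE))
  r <- extract_upstream(gc, "g1")
  expect_equal(c(r$abs_start, r$abs_end), c(0L, 150L))
  expect_equal(r$offset_start_codon, 100L)
})

test_that("upstream extraction is symmetric under genome reverse complement", {
  cl <- generate_clade(simulation_config(n_genomes = 1, seed = 77))
  g <- cl$genomes[[1]]
  n <- nchar(g$contigs[["chr1"]])
  flipped <- genome(g$genome_id, c(chr1 = revcomp(g$contigs[["chr1"]])),
                    within(g$genes, {
                      s <- start; start <- n - end; end <- n - s; rm(s)
                      strand <- ifelse(strand == "+", "-", "+")
                    }))
  for (id in g$genes$gene_id[1:5]) {
    expect_equal(extract_upstream(flipped, id)$seq, extract_upstream(g, id)$seq)
  }
})
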