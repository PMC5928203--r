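# Shared fixtures, all built in code.

# A 5 kb two-gene toy genome: one gene per strand, known coordinates.
toy_genome <- function(seed = 101) {
  seq <- regulonscan:::with_seed(seed, regulonscan:::random_dna(5000, gc = 0.5))
  genome("toy", c(chr = seq),
         data.frame(gene_id = c("gA", "gB"), contig_id = "chr",
                    start = c(1000L, 3000L), end = c(1600L, 3600L),
                    strand = c("+", "-"),
                    protein = c("MAAA", "MCCC"),
                    role = NA_character_, stringsAsFactors = FALSE))
}

# Upstream regions of one target family across a clade.
family_regions <- function(clade, fam = "T1") {
  tr <- clade$truth$sites[clade$truth$sites$family == fam, , drop = FALSE]
  lapply(seq_len(nrow(tr)), function(i)
    extract_upstream(clade$genomes[[tr$genome_id[i]]], tr$gene_id[i]))
}

# Map ortholog group ids to generator family labels (majority vote).
group_families <- function(groups, truth_families) {
  m <- merge(groups, truth_families, by = c("genome_id", "gene_id"))
  vapply(split(m$family, m$group_id),
         function(x) names(sort(table(x), decreasing = TRUE))[1], character(1))
}

# A minimal two-CDS GenBank record (one gene per strand).
genbank_fixture_text <- function() {
  dna <- regulonscan:::with_seed(7, regulonscan:::random_dna(600, gc = 0.5))
  # gene1: + strand 101..220; gene2: - strand 301..420 (1-based inclusive)
  c("LOCUS       ctgA                 600 bp    DNA     linear   BCT 01-JAN-2020",
    "DEFINITION  synthetic test record.",
    "FEATURES             Location/Qualifiers",
    "     source          1..600",
    "                     /organism=\"synthetic\"",
    "     CDS             101..220",
    "                     /locus_tag=\"GB_0001\"",
    "                     /gene=\"araB\"",
    "                     /translation=\"MKLVVNPQWE\"",
    "     CDS             complement(301..420)",
    "                     /locus_tag=\"GB_0002\"",
    "ORIGIN",
    paste0("        1 ", tolower(substr(dna, 1, 60))),
    paste0("       61 ", tolower(substr(dna, 61, 120))),
    vapply(seq(121, 541, by = 60), function(i)
      sprintf("%9d %s", i, tolower(substr(dna, i, i + 59))), character(1)),
    "//")
}
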