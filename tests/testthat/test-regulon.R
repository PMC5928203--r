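cand_row <- function(id, gm, class, gs = FALSE) {
  data.frame(candidate_id = id, genome_id = gm, gene_id = paste0(gm, "_x"),
             target_gene = paste0(gm, "_x"), operon_id = paste0(gm, "_op"),
             score = if (class == "strong") 20 else 15, class = class,
             pos_vs_start_codon = -120L, region_offset = 230L,
             genome_specific = gs, stringsAsFactors = FALSE)
}

groups_fix <- function(sizes) {
  do.call(rbind, lapply(names(sizes), function(g)
    data.frame(group_id = g, genome_id = paste0("G", seq_len(sizes[[g]])),
               gene_id = paste0("G", seq_len(sizes[[g]]), "_x"),
               stringsAsFactors = FALSE)))
}

test_that("the consistency filter applies the recurrence and footprinting rules", {
  groups <- groups_fix(c(OGa = 6, OGb = 6, OGc = 3))
  # strong hits in 6/6 genomes: accepted with conservation 6
  cand <- do.call(rbind, lapply(paste0("G", 1:6), cand_row, id = "OGa",
                                class = "strong"))
  acc <- consistency_filter(cand, groups, min_genomes = 3)
  expect_equal(acc$conservation_count, 6L)
  # a single weak hit with no orthologous support is rejected
  acc <- consistency_filter(cand_row("OGb", "G1", "weak"), groups, 3)
  expect_equal(nrow(acc), 0L)
  # weak in one genome + strong in two others for the same group:
  # the weak hit gains footprinting support; carriers = 3 so the
  # 50%-of-carriers cap (2 strong) applies
  cand <- rbind(cand_row("OGc", "G1", "weak"),
                cand_row("OGc", "G2", "strong"),
                cand_row("OGc", "G3", "strong"))
  acc <- consistency_filter(cand, groups, min_genomes = 3)
  expect_equal(nrow(acc), 1L)
  expect_equal(acc$genomes_strong, 2L)
  expect_equal(acc$genomes_weak_supported, 1L)
  expect_equal(acc$conservation_count, 3L)
  # without support requirement the weak hit counts unconditionally
  acc2 <- consistency_filter(cand_row("OGc", "G1", "weak"), groups, 1,
                             weak_needs_support = FALSE)
  expect_equal(nrow(acc2), 0L)  # still no strong hit at all
  # genome-specific gene: one strong hit suffices, flagged
  acc3 <- consistency_filter(cand_row("GS:G1:g9", "G1", "strong", gs = TRUE),
                             groups, 3)
  expect_true(acc3$genome_specific)
})

test_that("filter acceptance is monotone in min_genomes", {
  cl <- generate_clade(simulation_config(seed = 41, max_mismatches = 1))
  m <- motif_model(cl$truth$sites$sequence, name = "TF")
  groups <- build_groups(cl$genomes)
  fams <- group_families(groups, cl$truth$families)
  tf_gid <- names(fams)[fams == "TF"][1]
  cand <- propagate(tf_gid, m, cl$genomes, groups)
  prev <- NULL
  for (k in 1:6) {
    acc <- sort(consistency_filter(cand, groups, min_genomes = k)$candidate_id)
    if (!is.null(prev)) expect_true(all(acc %in% prev))
    prev <- acc
  }
})

test_that("propagation restricts to TF-carrying genomes and keys by ortholog group", {
  cl <- generate_clade(simulation_config(
    n_genomes = 4, phenotypes = "0", seed = 43, max_mismatches = 1))
  m <- motif_model(cl$truth$sites$sequence, name = "TF")
  groups <- build_groups(cl$genomes)
  fams <- group_families(groups, cl$truth$families)
  tf_gid <- names(fams)[fams == "TF"][1]
  # drop genome G04 from the TF group: it must not be scanned
  groups2 <- groups[!(groups$group_id == tf_gid & groups$genome_id == "G04"), ]
  cand <- propagate(tf_gid, m, cl$genomes, groups2)
  expect_false("G04" %in% cand$genome_id)
  # every target family present as a candidate in the 3 scanned genomes
  target_gids <- names(fams)[fams %in% paste0("T", 1:4)]
  cc <- table(cand$candidate_id[cand$gene_id %in%
                                  cl$truth$families$gene_id])
  expect_true(all(target_gids %in% names(cc)))
  expect_error(propagate("NOPE", m, cl$genomes, groups), "no members")
})

test_that("core members are called at the conservation cutoff", {
  members <- data.frame(candidate_id = c("gap", "araE", "fucO"),
                        genomes_strong = c(24L, 8L, 7L),
                        genomes_weak_supported = 0L,
                        conservation_count = c(24L, 8L, 7L),
                        genome_specific = FALSE, stringsAsFactors = FALSE)
  out <- call_core(members, core_min = 20)
  expect_equal(out$class, c("core", "group-specific", "group-specific"))
  empty <- call_core(members[0, ], core_min = 20)
  expect_equal(nrow(empty), 0L)
})

test_that("local TF discovery reports regulator genes near pathway operons", {
  seq <- regulonscan:::with_seed(50, regulonscan:::random_dna(20000, 0.5))
  mk_genes <- function(roles, starts, strands) {
    data.frame(gene_id = sprintf("g%02d", seq_along(starts)), contig_id = "c1",
               start = starts, end = starts + 300L, strand = strands,
               protein = "M", role = roles, stringsAsFactors = FALSE)
  }
  # ROK regulator divergently transcribed from an ABC transporter operon
  g <- genome("loc", c(c1 = seq),
              mk_genes(c("araU", "aauA", "aauB", "aauC"),
                       c(1000L, 2000L, 2350L, 2700L),
                       c("-", "+", "+", "+")))
  hits <- local_tf_discovery(g)
  expect_equal(hits$gene_id, "g01")
  expect_equal(hits$family, "ROK")
  expect_lte(hits$distance_operons, 2L)
  # a regulator 20 operons away from any pathway gene is not reported
  far_starts <- c(1000L, seq(2000L, by = 700L, length.out = 20), 17000L)
  far_roles <- c("xsaR", rep(NA_character_, 20), "aauA")
  g2 <- genome("far", c(c1 = seq),
               mk_genes(far_roles, far_starts,
                        rep(c("+", "-"), length.out = 22)))
  expect_equal(nrow(local_tf_discovery(g2)), 0L)
  # no TF annotations at all
  g3 <- genome("none", c(c1 = seq),
               mk_genes(c("aauA", NA), c(1000L, 2000L), c("+", "+")))
  expect_equal(nrow(local_tf_discovery(g3)), 0L)
})
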