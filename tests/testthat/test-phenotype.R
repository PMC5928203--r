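role_row <- function(roles) {
  r <- stats::setNames(rep(FALSE, length(subsystem_roles())), subsystem_roles())
  r[roles] <- TRUE
  r
}

role_genome <- function(genome_id, roles) {
  n <- length(roles)
  seqs <- regulonscan:::with_seed(nchar(genome_id) + n,
                                  regulonscan:::random_dna(1000 * (n + 1), 0.5))
  genome(genome_id, c(c1 = seqs),
         data.frame(gene_id = sprintf("%s_r%02d", genome_id, seq_len(n)),
                    contig_id = "c1", start = 1000L * (seq_len(n) - 1L),
                    end = 1000L * (seq_len(n) - 1L) + 300L, strand = "+",
                    protein = "M", role = roles, stringsAsFactors = FALSE))
}

test_that("the subsystem is populated from role annotations with provenance", {
  g1 <- role_genome("A", c("araB", "araD", "araA", "araE"))
  g2 <- role_genome("B", c("araF", "araG"))   # incomplete araFGH
  sub <- populate_subsystem(list(g1, g2))
  expect_true(all(sub$presence["A", c("araB", "araD", "araA", "araE")]))
  expect_false(any(sub$presence["A", setdiff(subsystem_roles(),
                                             c("araB", "araD", "araA", "araE"))]))
  expect_true(all(sub$presence["B", c("araF", "araG")]))
  expect_false(sub$presence["B", "araH"])
  expect_equal(sub$genes$gene_id[sub$genes$genome_id == "A" &
                                   sub$genes$role == "araE"], "A_r04")
  # a role outside the vocabulary is rejected with its name
  expect_error(populate_subsystem(list(role_genome("C", "araZ"))), "araZ")
})

test_that("phenotype rules reproduce the canonical patterns", {
  expect_equal(assign_phenotype(role_row(c("araB", "araD", "araA", "araE")))$composite,
               "U1")
  # araFGH requires the complete system
  expect_equal(assign_phenotype(role_row(c("araB", "araD", "araA",
                                           "araF", "araG", "araH")))$composite, "U1")
  # an incomplete ABC system does not license uptake, but its subunits
  # still count as transporter genes, so this is "0", not the
  # transporter-less pattern
  expect_equal(assign_phenotype(role_row(c("araB", "araD", "araA",
                                           "araF", "araG")))$composite, "0")
  # catabolic genes without any transporter: the transporter-less pattern
  expect_equal(assign_phenotype(role_row(c("araB", "araD", "araA")))$composite,
               "unique")
  # the full role set carries all three labels
  full <- assign_phenotype(role_row(subsystem_roles()))
  expect_equal(full$composite, "U123")
  expect_equal(full$labels, c("U1", "U2", "U3"))
  expect_equal(assign_phenotype(role_row(character(0)))$composite, "0")
  # the xosABC/abfA alternative route is advisory only
  axos <- assign_phenotype(role_row(c("araB", "araD", "araA", "xosABC", "abfA")))
  expect_equal(axos$composite, "unique")
  expect_true(axos$axos_route_possible)
})

test_that("phenotype assignment is order-invariant and monotone in roles", {
  roles <- c("araB", "araD", "araA", "aauA", "aauB", "aauC", "abfII_1")
  expect_equal(assign_phenotype(role_row(roles))$composite,
               assign_phenotype(role_row(rev(roles)))$composite)
  # adding roles never removes a label
  regulonscan:::with_seed(90, {
    for (i in 1:25) {
      base <- sample(subsystem_roles(), sample(3:12, 1))
      extra <- union(base, sample(subsystem_roles(), 3))
      l1 <- assign_phenotype(role_row(base))$labels
      l2 <- assign_phenotype(role_row(extra))$labels
      expect_true(all(l1 %in% l2))
    }
  })
})

test_that("truth witnesses round-trip through the phenotype rules", {
  labels <- c("U1", "U2", "U3", "U123", "0", "unique")
  witnesses <- assign_truth_phenotypes(labels)
  got <- vapply(witnesses, function(w)
    assign_phenotype(role_row(w))$composite, character(1))
  expect_equal(unname(got), labels)
  expect_error(assign_truth_phenotypes("U9"), "unknown")
})

test_that("fermentation concordance counts matches in both directions", {
  calls <- data.frame(genome_id = sprintf("S%02d", 1:22),
                      U1 = c(rep(TRUE, 10), rep(FALSE, 12)),
                      stringsAsFactors = FALSE)
  # 2 discordant strains: fermenters predicted transporter-less
  ferm <- stats::setNames(c(rep("+", 10), rep("-", 10), "+", "+"),
                          calls$genome_id)
  cc <- concordance(calls, ferm)
  expect_equal(cc$n_match, 20L)
  expect_equal(cc$n_total, 22L)
  expect_equal(cc$fraction, 20 / 22)
  expect_equal(floor(100 * cc$fraction), 90)
  # perfect agreement
  expect_equal(concordance(calls, stats::setNames(
    ifelse(calls$U1, "+", "-"), calls$genome_id))$fraction, 1)
  # predicted U1 but fermentation negative is discordant too
  cc2 <- concordance(calls[1, ], stats::setNames("-", "S01"))
  expect_equal(cc2$n_match, 0L)
  expect_error(concordance(calls, c(ZZ = "+")), "no genomes")
})

test_that("clade genomes realize their requested phenotype labels", {
  cl <- generate_clade(simulation_config(n_genomes = 6, seed = 91))
  calls <- assign_phenotypes(populate_subsystem(cl$genomes))
  expect_equal(calls$composite, cl$truth$phenotypes$label)
})
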