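counts_mat <- function(...) {
  m <- matrix(c(...), nrow = 4)
  rownames(m) <- c("A", "C", "G", "T")
  m
}

test_that("symmetrization follows the mirror-average formula", {
  # single site "AA": column 1 A=1, column 2 A=1 -> each column A=T=0.5
  raw <- counts_mat(c(1, 0, 0, 0), c(1, 0, 0, 0))
  sym <- symmetrize_counts(raw)
  expect_equal(sym, counts_mat(c(0.5, 0, 0, 0.5), c(0.5, 0, 0, 0.5)))
  # palindromic input is a fixed point
  expect_equal(symmetrize_counts(sym), sym)
  # idempotence on arbitrary non-negative counts
  raw2 <- regulonscan:::with_seed(3, counts_mat(runif(16, 0, 10)))
  expect_equal(symmetrize_counts(symmetrize_counts(raw2)),
               symmetrize_counts(raw2))
  # total mass preserved; column sums preserved for site-count matrices
  # (all columns carry one count per aligned site)
  expect_equal(sum(symmetrize_counts(raw2)), sum(raw2))
  site_m <- regulonscan:::site_counts(c("ATGC", "GATC", "TTAA"), 4L)
  expect_equal(colSums(symmetrize_counts(site_m)), colSums(site_m))
  # reverse-complement mirror equality
  s2 <- symmetrize_counts(raw2)
  expect_equal(unname(s2), unname(s2[4:1, ncol(s2):1]))
  expect_error(symmetrize_counts(counts_mat(c(1, 0, 0, 0))), "even")
})

test_that("weight columns are zero-sum log counts", {
  w <- build_weights(counts_mat(c(4, 0, 0, 0), c(0, 0, 0, 4)))
  # w(A) = 0.75 ln 9, others -0.25 ln 9
  expect_equal(unname(w["A", 1]), 0.75 * log(9))
  expect_equal(unname(w["C", 1]), -0.25 * log(9))
  expect_equal(colSums(w), c(0, 0))
  # uniform column gives all-zero weights
  expect_equal(build_weights(counts_mat(rep(1, 4)))[, 1],
               c(A = 0, C = 0, G = 0, T = 0))
  # zero-sum holds for arbitrary counts
  m <- regulonscan:::with_seed(9, counts_mat(runif(24, 0, 20)))
  expect_equal(max(abs(colSums(build_weights(m)))), 0, tolerance = 1e-12)
})

test_that("information content matches hand-computed values and bounds", {
  expect_equal(information_content(counts_mat(rep(1e6, 4))), 0, tolerance = 1e-5)
  # n=4 fully conserved column, pseudocount 0.5:
  # f = (4.5, 0.5, 0.5, 0.5)/6; IC = 0.75*log2(3) + 3*(1/12)*log2(1/3)
  ic1 <- 0.75 * log2(0.75 / 0.25) + 3 * (0.5 / 6) * log2((0.5 / 6) / 0.25)
  expect_equal(information_content(counts_mat(c(4, 0, 0, 0))), ic1)
  expect_equal(ic1, 0.79248125, tolerance = 1e-7)
  # large-sample conserved column approaches the 2-bit ceiling
  expect_equal(information_content(counts_mat(c(1e8, 0, 0, 0))), 2,
               tolerance = 1e-5)
  m <- regulonscan:::with_seed(4, counts_mat(runif(16, 0, 50)))
  ic <- information_content(m)
  expect_true(ic >= 0 && ic <= 2 * ncol(m))
})

test_that("palindromic models score sequences and reverse complements identically", {
  sites <- c("ATGCAT", "ATGCAT", "AAGCTT", "ATTAAT")
  m <- motif_model(sites, name = "L6")
  seqs <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), 6)), 1, paste,
                collapse = "")
  expect_equal(score_site(m, seqs), score_site(m, revcomp(seqs)))
  # consensus sequence attains the maximal possible score
  expect_equal(score_site(m, consensus(m)), sum(apply(m$weights, 2, max)))
  # ambiguous bases yield the NA sentinel
  expect_true(is.na(score_site(m, "ATGNAT")))
})

test_that("threshold calibration anchors to training scores with the stated ratios", {
  sites <- c("ATGTTAGCGCTAACAT", "ATGATAGCGCTATCAT", "ATGTTACCGGTAACAT",
             "ATCTTAGCGCTAAGAT", "ATGTTAGGCCTAACAT", "TTGTTAGCGCTAACAA")
  m <- motif_model(sites, name = "cal")
  sc <- score_site(m, sites)
  expect_equal(m$strong_threshold, min(sc))
  expect_equal(m$weak_threshold, 0.95 * min(sc))
  m2 <- calibrate_thresholds(m, preset = "araq")
  expect_equal(m2$strong_threshold, 0.95 * min(sc))
  expect_equal(m2$weak_threshold, (4.5 / 4.75) * 0.95 * min(sc))
  expect_true(m2$strong_threshold >= m2$weak_threshold)
  # degenerate single-site training set: thresholds collapse with a warning
  expect_warning(m1 <- motif_model(sites[1], name = "one"), "single")
  expect_equal(m1$strong_threshold, score_site(m1, sites[1]))
})

test_that("discovery recovers a perfect implanted palindrome at every position", {
  cons <- "ATGTTAGCGCTAACAT"
  regions <- regulonscan:::with_seed(55, {
    lapply(1:10, function(i) {
      bg <- regulonscan:::random_dna(400, gc = 0.6)
      implant_site(bg, cons, 0, 40 + 20 * i)$seq
    })
  })
  m <- discover_palindromic_motif(regions, L = 16, n_restarts = 20, seed = 2)
  expect_equal(consensus(m), cons)
  expect_equal(nrow(m$training_sites), 10L)
  expect_equal(sort(m$training_sites$offset), 40 + 20 * (1:10))
})

test_that("discovery is strand-symmetric: reverse-complemented regions give the same consensus", {
  cons <- "ATGTTAGCGCTAACAT"
  regions <- regulonscan:::with_seed(56, lapply(1:8, function(i)
    implant_site(regulonscan:::random_dna(400, gc = 0.6), cons, 0, 100)$seq))
  m1 <- discover_palindromic_motif(regions, L = 16, n_restarts = 10, seed = 3)
  m2 <- discover_palindromic_motif(revcomp(unlist(regions)), L = 16,
                                   n_restarts = 10, seed = 3)
  expect_equal(consensus(m1), cons)
  expect_equal(consensus(m2), cons)
})

test_that("pure background yields no significant motif against the shuffle null", {
  # a ~5% false-confidence rate per draw is inherent to the 95th-percentile
  # null; a median-of-3 vote makes the check robust
  votes <- vapply(1:3, function(k) {
    regions <- regulonscan:::with_seed(600 + k, lapply(1:10, function(i)
      regulonscan:::random_dna(400, gc = 0.6)))
    m <- discover_palindromic_motif(regions, L = 16, n_restarts = 10,
                                    seed = 600 + k)
    motif_significant(m, regions, n_shuffles = 20, seed = 700 + k)$significant
  }, logical(1))
  expect_true(sum(votes) <= 1L)
  # and an implanted motif is significant
  cons <- "ATGTTAGCGCTAACAT"
  regions <- regulonscan:::with_seed(61, lapply(1:8, function(i)
    implant_site(regulonscan:::random_dna(400, gc = 0.6), cons, 0.05, 100)$seq))
  m <- discover_palindromic_motif(regions, L = 16, n_restarts = 10, seed = 8)
  expect_true(motif_significant(m, regions, n_shuffles = 20, seed = 9)$significant)
})

test_that("discovery refuses fewer than 4 regions", {
  expect_error(discover_palindromic_motif(list("ACGT"), L = 4, seed = 1),
               "at least 4")
})
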