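## Palindromic motif models: symmetrized count matrices, positional weight
## matrices, information content, de novo discovery in upstream-region sets.
##
## Matrices are 4 x L with rows A,C,G,T and one column per motif position.

COMP_IDX <- c(4L, 3L, 2L, 1L)  # A<->T, C<->G

#' Symmetrize a motif count matrix
#'
#' Averages each count with its reverse-complement mirror:
#' `N'(b, j) = (N(b, j) + N(complement(b), L + 1 - j)) / 2`.  The result
#' equals its own reverse-complement mirror and column sums are preserved,
#' so the matrix describes a palindromic (dyad-symmetric) operator, the
#' site architecture bound by homodimeric regulators of the LacI/TetR/ROK
#' families.
#'
#' @param counts 4 x L numeric matrix (rows A,C,G,T), L even, non-negative.
#' @return symmetrized 4 x L matrix.
#' @export
symmetrize_counts <- function(counts) {
  counts <- check_count_matrix(counts)
  L <- ncol(counts)
  if (L %% 2L != 0L) stopf("motif length must be even (got %d)", L)
  (counts + counts[COMP_IDX, L:1, drop = FALSE]) / 2
}

check_count_matrix <- function(counts) {
  if (!is.matrix(counts) || nrow(counts) != 4L)
    stopf("counts must be a 4 x L matrix (rows A,C,G,T)")
  if (any(counts < 0)) stopf("counts must be non-negative")
  rownames(counts) <- DNA_BASES
  counts
}

#' Build a positional weight matrix from counts
#'
#' `w(b, j) = ln(N(b, j) + pseudocount) - mean_b' ln(N(b', j) + pseudocount)`.
#' Each column of the result sums to zero, so the score of a sequence is a
#' log-ratio-like quantity centred on the column means.
#'
#' @param counts 4 x L count matrix (symmetrized for palindromic models).
#' @param pseudocount added to every cell before taking logs (default 0.5).
#' @return 4 x L weight matrix with zero-sum columns.
#' @export
build_weights <- function(counts, pseudocount = 0.5) {
  counts <- check_count_matrix(counts)
  w <- log(counts + pseudocount)
  sweep(w, 2, colMeans(w))
}

#' Information content of a motif in bits
#'
#' `IC = sum_j sum_b f(b, j) * log2(f(b, j) / 0.25)` with frequencies `f`
#' computed from pseudocounted counts.  Ranges from 0 (uniform) to 2 bits
#' per column (perfect conservation, in the large-sample limit).
#'
#' @inheritParams build_weights
#' @return total information content in bits.
#' @export
information_content <- function(counts, pseudocount = 0.5) {
  counts <- check_count_matrix(counts)
  f <- sweep(counts + pseudocount, 2, colSums(counts + pseudocount), "/")
  sum(f * log2(f / 0.25))
}

## Vectorized sliding-window PWM scores over integer-coded sequence.
## Windows containing any non-ACGT base are reported as NA.
scan_scores <- function(weights, codes) {
  L <- ncol(weights)
  n <- length(codes)
  m <- n - L + 1L
  if (m < 1L) return(numeric(0))
  bad <- is.na(codes)
  codes2 <- codes
  codes2[bad] <- 1L
  wv <- as.vector(weights)        # column-major: base + 4*(position-1)
  S <- numeric(m)
  for (j in seq_len(L))
    S <- S + wv[codes2[j:(j + m - 1L)] + (j - 1L) * 4L]
  if (any(bad)) {
    nb <- cumsum(c(0L, as.integer(bad)))
    S[(nb[seq_len(m) + L] - nb[seq_len(m)]) > 0L] <- NA_real_
  }
  S
}

## ---------------------------------------------------------------------------
## The motif_model class

#' Fit a palindromic motif model from aligned binding sites
#'
#' Builds the symmetrized count matrix, the zero-column-sum weight matrix,
#' the information content and calibrated strong/weak score thresholds from
#' a training set of equal-length sites.
#'
#' @param sites character vector of training-site sequences (equal even
#'   length, A/C/G/T), or a data frame with a `sequence` column (extra
#'   columns such as `genome_id`/`gene_id` are carried along).
#' @param name motif name (e.g. `"AraQ"`, `"AbfR"`).
#' @param pseudocount see [build_weights()].
#' @param preset threshold calibration preset, see [calibrate_thresholds()].
#' @return object of class `motif_model` with elements `name`, `counts`
#'   (symmetrized), `weights`, `training_sites`, `ic_bits`,
#'   `strong_threshold`, `weak_threshold`, `L`.
#' @export
motif_model <- function(sites, name = "motif", pseudocount = 0.5,
                        preset = c("default", "araq")) {
  if (is.data.frame(sites)) {
    stopifnot("sequence" %in% names(sites))
    site_df <- sites
  } else {
    site_df <- data.frame(sequence = as.character(sites), stringsAsFactors = FALSE)
  }
  seqs <- toupper(site_df$sequence)
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stopf("training sites must have equal length")
  if (L %% 2L != 0L) stopf("motif length must be even (got %d)", L)
  if (any(grepl("[^ACGT]", seqs))) stopf("training sites must be over A/C/G/T")
  counts <- site_counts(seqs, L)
  scounts <- symmetrize_counts(counts)
  m <- structure(list(name = name, L = L,
                      counts = scounts,
                      weights = build_weights(scounts, pseudocount),
                      training_sites = site_df,
                      ic_bits = information_content(scounts, pseudocount),
                      pseudocount = pseudocount,
                      strong_threshold = NA_real_,
                      weak_threshold = NA_real_),
                 class = "motif_model")
  calibrate_thresholds(m, preset = match.arg(preset))
}

site_counts <- function(seqs, L) {
  counts <- matrix(0, 4L, L, dimnames = list(DNA_BASES, NULL))
  for (s in seqs) {
    idx <- base_codes(s)
    counts[cbind(idx, seq_len(L))] <- counts[cbind(idx, seq_len(L))] + 1
  }
  counts
}

#' Calibrate strong/weak site-score thresholds from the training sites
#'
#' Absolute PWM score scales are model-specific, so thresholds are anchored
#' to the training sites: the strong threshold is the minimum training-site
#' score and the weak threshold is `weak_ratio` times it (default 0.95,
#' mirroring the conventional 4.75:5 strong:weak ratio).  The `"araq"`
#' preset reproduces the laxer global-regulon setting (4.75/4.5 on the same
#' scale): the strong threshold itself is relaxed by 0.95 and the weak one
#' uses ratio 4.5/4.75.  Both thresholds can be overridden explicitly.
#'
#' @param model a [motif_model()].
#' @param preset `"default"` or `"araq"`.
#' @param weak_ratio weak:strong ratio for the default policy.
#' @param strong,weak explicit absolute overrides (take precedence).
#' @return the model with `strong_threshold`/`weak_threshold` set.
#' @export
calibrate_thresholds <- function(model, preset = c("default", "araq"),
                                 weak_ratio = 0.95, strong = NULL, weak = NULL) {
  stopifnot(inherits(model, "motif_model"))
  preset <- match.arg(preset)
  sc <- score_site(model, model$training_sites$sequence)
  if (length(sc) < 2L)
    warnf("motif '%s': thresholds calibrated from a single training site", model$name)
  s <- min(sc)
  if (preset == "araq") {
    s <- 0.95 * s
    w <- (4.5 / 4.75) * s
  } else {
    w <- weak_ratio * s
  }
  model$strong_threshold <- strong %||% s
  model$weak_threshold <- weak %||% w
  if (model$weak_threshold > model$strong_threshold)
    stopf("weak threshold must not exceed strong threshold")
  model
}

#' Consensus sequence of a motif model
#'
#' Per-column majority base of the symmetrized counts (ties broken
#' alphabetically, deterministically).
#'
#' @param model a [motif_model()].
#' @return consensus string of length `model$L`.
#' @export
consensus <- function(model) {
  stopifnot(inherits(model, "motif_model"))
  paste(DNA_BASES[apply(model$counts, 2, which.max)], collapse = "")
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("<motif_model> %s: L=%d, %d training site(s), IC=%.2f bits\n",
              x$name, x$L, nrow(x$training_sites), x$ic_bits))
  cat(sprintf("  consensus: %s\n", consensus(x)))
  if (!is.na(x$strong_threshold))
    cat(sprintf("  thresholds: strong %.3f / weak %.3f\n",
                x$strong_threshold, x$weak_threshold))
  invisible(x)
}

#' @export
summary.motif_model <- function(object, ...) {
  ic_col <- vapply(seq_len(object$L), function(j)
    information_content(object$counts[, j, drop = FALSE], object$pseudocount),
    numeric(1))
  out <- list(name = object$name, L = object$L,
              n_sites = nrow(object$training_sites),
              consensus = consensus(object), ic_bits = object$ic_bits,
              ic_per_column = ic_col,
              strong_threshold = object$strong_threshold,
              weak_threshold = object$weak_threshold,
              training_scores = score_site(object, object$training_sites$sequence))
  class(out) <- "summary.motif_model"
  out
}

#' @export
print.summary.motif_model <- function(x, ...) {
  cat(sprintf("Palindromic motif model '%s' (L = %d, %d sites)\n",
              x$name, x$L, x$n_sites))
  cat(sprintf("  consensus          %s\n", x$consensus))
  cat(sprintf("  information        %.2f bits (%.2f bits/column)\n",
              x$ic_bits, x$ic_bits / x$L))
  cat(sprintf("  thresholds         strong %.3f / weak %.3f\n",
              x$strong_threshold, x$weak_threshold))
  cat(sprintf("  training scores    %.3f .. %.3f\n",
              min(x$training_scores), max(x$training_scores)))
  invisible(x)
}

#' @export
predict.motif_model <- function(object, newdata, ...) {
  score_site(object, newdata)
}

#' Plot per-column information content of a motif
#'
#' Base-graphics rendering: one bar per motif position, labelled with the
#' consensus base, bar height = column information content in bits.
#'
#' @param x a [motif_model()].
#' @param ... passed to [graphics::barplot()].
#' @export
plot.motif_model <- function(x, ...) {
  ic_col <- vapply(seq_len(x$L), function(j)
    information_content(x$counts[, j, drop = FALSE], x$pseudocount), numeric(1))
  cons <- strsplit(consensus(x), "")[[1]]
  graphics::barplot(ic_col, names.arg = cons, ylim = c(0, 2),
                    ylab = "information (bits)",
                    xlab = "motif position (consensus base)",
                    main = x$name, ...)
  invisible(x)
}

## ---------------------------------------------------------------------------
## De novo palindromic motif discovery

#' Discover a palindromic motif in a set of upstream regions
#'
#' Seeded greedy iteration.  Seed windows are ranked by
#' self-complementarity (the number of positions at which the window
#' matches its own reverse complement): a dyad-symmetric operator scores
#' at or near the maximum while background rarely does, so the top
#' `n_restarts` non-overlapping windows (ties shuffled under `seed`) are
#' strong starting points.  Each restart seeds the count matrix from its
#' window plus the reverse complement, then alternates between (i) scoring
#' every L-mer of every region with the current palindromic PWM and
#' keeping each region's best site, and (ii) rebuilding the symmetrized
#' counts and weights from those sites, until the site set is stable or
#' `max_iter` iterations.  The restart maximizing (IC per column) x
#' (fraction of regions whose best site scores at least `coverage_frac`
#' of the consensus score) wins; when several lengths are given the same
#' objective picks the length.  Deterministic given `seed`.
#'
#' @param regions list of `upstream_region` objects or character sequences
#'   (at least 4).
#' @param L candidate motif length(s), even; default `c(14, 16, 18, 20, 22)`.
#' @param n_restarts random restarts per length (default 20).
#' @param seed RNG seed (required; discovery is stochastic).
#' @param max_iter maximum refinement iterations per restart.
#' @param coverage_frac fraction of the consensus score a region's best site
#'   must reach to count as covered in the objective (default 0.6).
#' @param name motif name for the returned model.
#' @return a [motif_model()] fitted to the final site set, with
#'   `discovery` element recording per-region sites, objective, and seed.
#' @export
discover_palindromic_motif <- function(regions, L = c(14, 16, 18, 20, 22),
                                       n_restarts = 20, seed, max_iter = 50,
                                       coverage_frac = 0.6, name = "motif") {
  seqs <- region_seqs(regions)
  if (length(seqs) < 4L) stopf("motif discovery needs at least 4 regions (got %d)", length(seqs))
  if (missing(seed)) stopf("a seed is required for motif discovery")
  if (any(L %% 2L != 0L)) stopf("motif lengths must be even")
  codes <- lapply(seqs, base_codes)
  best <- NULL
  with_seed(seed, {
    for (len in L) {
      seeds <- palindromic_seeds(seqs, codes, len, n_restarts)
      for (r in seq_len(nrow(seeds))) {
        fit <- discover_one_restart(seqs, codes, len, max_iter, coverage_frac,
                                    seed_region = seeds$region[r],
                                    seed_pos = seeds$pos[r])
        if (!is.null(fit) && (is.null(best) || fit$objective > best$objective))
          best <- fit
      }
    }
  })
  if (is.null(best)) stopf("no valid motif could be seeded (regions too short?)")
  site_df <- data.frame(
    region = names(seqs)[best$sites$region] %||% as.character(best$sites$region),
    offset = best$sites$offset,
    sequence = best$sites$sequence,
    score = best$sites$score,
    stringsAsFactors = FALSE)
  model <- motif_model(site_df, name = name)
  model$discovery <- list(objective = best$objective, coverage = best$coverage,
                          seed = seed, L_tried = L, n_restarts = n_restarts)
  model
}

region_seqs <- function(regions) {
  if (is.character(regions)) regions <- as.list(regions)
  seqs <- vapply(regions, function(r) {
    if (inherits(r, "upstream_region")) r$seq else as.character(r)
  }, character(1))
  seqs <- toupper(seqs)
  if (is.null(names(seqs))) {
    nm <- vapply(regions, function(r)
      if (inherits(r, "upstream_region")) r$gene_id else NA_character_, character(1))
    if (!anyNA(nm)) names(seqs) <- nm
  }
  seqs
}

## Self-complementarity of every window: positions where the window
## equals its own reverse complement.  NA-containing windows score -1.
palin_scores <- function(codes, L) {
  n <- length(codes)
  m <- n - L + 1L
  if (m < 1L) return(integer(0))
  comp <- 5L - codes
  s <- integer(m)
  bad <- logical(m)
  idx <- seq_len(m)
  for (j in 0:(L - 1L)) {
    a <- codes[idx + j]
    b <- comp[idx + (L - 1L - j)]
    s <- s + (!is.na(a) & a == b)
    bad <- bad | is.na(a)
  }
  s[bad] <- -1L
  s
}

## Top non-overlapping seed windows across all regions, ranked by
## self-complementarity; ties broken by a seeded random jitter.
palindromic_seeds <- function(seqs, codes, L, n_seeds) {
  cand <- do.call(rbind, lapply(seq_along(codes), function(i) {
    s <- palin_scores(codes[[i]], L)
    if (!length(s)) return(NULL)
    data.frame(region = i, pos = seq_along(s), score = s)
  }))
  cand <- cand[cand$score >= 0L, , drop = FALSE]
  if (is.null(cand) || !nrow(cand)) return(data.frame(region = integer(0), pos = integer(0)))
  cand <- cand[order(-cand$score, stats::runif(nrow(cand))), ]
  chosen <- cand[0, ]
  for (r in seq_len(nrow(cand))) {
    row <- cand[r, ]
    clash <- chosen$region == row$region & abs(chosen$pos - row$pos) < L
    if (!any(clash)) chosen <- rbind(chosen, row)
    if (nrow(chosen) >= n_seeds) break
  }
  chosen
}

discover_one_restart <- function(seqs, codes, L, max_iter, coverage_frac,
                                 seed_region, seed_pos) {
  ok <- which(vapply(codes, length, integer(1)) >= L)
  if (length(ok) < 4L) return(NULL)
  lmer <- substr(seqs[seed_region], seed_pos, seed_pos + L - 1L)
  if (grepl("[^ACGT]", lmer)) return(NULL)
  counts <- symmetrize_counts(site_counts(c(lmer, revcomp(lmer)), L))
  W <- build_weights(counts)
  prev <- NULL
  for (iter in seq_len(max_iter)) {
    pick_pos <- integer(length(ok)); pick_score <- numeric(length(ok))
    for (k in seq_along(ok)) {
      S <- scan_scores(W, codes[[ok[k]]])
      if (!length(S) || all(is.na(S))) { pick_pos[k] <- NA_integer_; next }
      pick_pos[k] <- which.max(S)      # NA-safe: which.max ignores NA
      pick_score[k] <- S[pick_pos[k]]
    }
    if (!is.null(prev) && identical(prev, pick_pos)) break
    prev <- pick_pos
    use <- which(!is.na(pick_pos))
    if (length(use) < 4L) return(NULL)
    site_seqs <- vapply(use, function(k)
      substr(seqs[ok[k]], pick_pos[k], pick_pos[k] + L - 1L), character(1))
    counts <- symmetrize_counts(site_counts(site_seqs, L))
    W <- build_weights(counts)
  }
  cons_score <- sum(apply(W, 2, max))
  covered <- !is.na(pick_pos) & pick_score >= coverage_frac * cons_score
  ic <- information_content(counts)
  use <- which(!is.na(pick_pos))
  list(objective = (ic / L) * mean(covered),
       coverage = mean(covered),
       ic = ic, L = L,
       sites = data.frame(region = ok[use], offset = pick_pos[use] - 1L,
                          sequence = vapply(use, function(k)
                            substr(seqs[ok[k]], pick_pos[k], pick_pos[k] + L - 1L),
                            character(1)),
                          score = pick_score[use]))
}

#' Empirical significance of a discovered motif
#'
#' Compares the model's information content with the distribution of ICs
#' obtained by re-running discovery on letter-shuffled copies of the same
#' regions (composition-preserving null).  A motif whose IC falls below the
#' `q` quantile of the null is reported as not significant.
#'
#' @param model a discovered [motif_model()].
#' @param regions the regions it was discovered in.
#' @param n_shuffles null replicates (default 20).
#' @param q null quantile (default 0.95).
#' @param seed RNG seed.
#' @param n_restarts restarts per null discovery (default 5; the null only
#'   needs the bulk of the distribution, not the global optimum).
#' @return list with `significant` (logical), `ic`, `null_ic` (vector) and
#'   `null_quantile`.
#' @export
motif_significant <- function(model, regions, n_shuffles = 20, q = 0.95,
                              seed, n_restarts = 5) {
  stopifnot(inherits(model, "motif_model"))
  if (missing(seed)) stopf("a seed is required")
  seqs <- region_seqs(regions)
  null_ic <- with_seed(seed, vapply(seq_len(n_shuffles), function(i) {
    shuf <- vapply(seqs, shuffle_seq, character(1))
    m <- discover_palindromic_motif(shuf, L = model$L, n_restarts = n_restarts,
                                    seed = sample.int(.Machine$integer.max, 1L))
    m$ic_bits
  }, numeric(1)))
  thr <- stats::quantile(null_ic, q, names = FALSE)
  list(significant = model$ic_bits > thr, ic = model$ic_bits,
       null_ic = null_ic, null_quantile = thr)
}

#' Export a motif as a TRANSFAC-like plain-text count matrix
#'
#' @param model a [motif_model()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_motif <- function(model, path) {
  stopifnot(inherits(model, "motif_model"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("ID %s", model$name), "BF synthetic", "P0 A C G T"), con)
  cons <- strsplit(consensus(model), "")[[1]]
  for (j in seq_len(model$L))
    writeLines(sprintf("%02d %g %g %g %g %s", j,
                       model$counts[1, j], model$counts[2, j],
                       model$counts[3, j], model$counts[4, j], cons[j]), con)
  writeLines("XX", con)
  invisible(path)
}
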