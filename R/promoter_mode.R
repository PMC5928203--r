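## sigma70-style promoter element location and repressor/activator
## classification of binding sites from promoter geometry.

## Canonical hexamer consensus matrices (TTGACA / TATAAT), built as four
## pseudo-observations of the consensus with the standard pseudocount, so
## element scores live on the same log-count scale as motif scores.
promoter_weights <- function(consensus) {
  idx <- base_codes(consensus)
  counts <- matrix(0, 4L, length(idx), dimnames = list(DNA_BASES, NULL))
  counts[cbind(idx, seq_along(idx))] <- 4
  build_weights(counts)
}

PROMOTER_MINUS35 <- "TTGACA"
PROMOTER_MINUS10 <- "TATAAT"

sigma70_weights <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- list(m35 = promoter_weights(PROMOTER_MINUS35),
                     m10 = promoter_weights(PROMOTER_MINUS10))
    cache
  }
})

#' Locate -35/-10 promoter elements in an upstream region
#'
#' Scores every -35/spacer/-10 arrangement on the coding strand with fixed
#' consensus matrices (TTGACA, TATAAT; spacer 15-19 bp allowed, no penalty
#' inside the range, excluded outside).  The joint score of the best
#' arrangement is compared against an empirical cutoff, the `q` quantile of
#' best joint scores over letter-shuffled copies of the same region;
#' `confidence` is `"none"` below the cutoff.  Equal-scoring arrangements
#' are resolved toward the start codon (deterministically).
#'
#' @param region an `upstream_region` (length >= 60).
#' @param spacer_range allowed spacer lengths in bp (default 15:19).
#' @param n_shuffles null replicates for the cutoff (default 50).
#' @param q null quantile defining the cutoff (default 0.95).
#' @param seed RNG seed for the shuffle null (default 1; fixed so repeated
#'   calls on the same region agree).
#' @return object of class `promoter_annotation`: `minus35` and `minus10`
#'   (each `list(offset, seq, score)`, offsets 0-based in region
#'   coordinates), `spacer_len`, `joint_score`, `cutoff`, `confidence`
#'   (`"confident"`/`"none"`).
#' @export
find_promoter <- function(region, spacer_range = 15:19, n_shuffles = 50,
                          q = 0.95, seed = 1) {
  seq <- if (inherits(region, "upstream_region")) region$seq else as.character(region)
  if (nchar(seq) < 60) stopf("region too short for promoter search (%d < 60 bp)", nchar(seq))
  w35 <- sigma70_weights()$m35
  w10 <- sigma70_weights()$m10
  codes <- base_codes(seq)
  best <- best_promoter_arrangement(codes, w35, w10, spacer_range)
  null_best <- with_seed(seed, vapply(seq_len(n_shuffles), function(i) {
    best_promoter_arrangement(sample(codes), w35, w10, spacer_range)$joint
  }, numeric(1)))
  cutoff <- stats::quantile(null_best, q, names = FALSE)
  structure(list(
    minus35 = list(offset = best$p35, seq = substr(seq, best$p35 + 1L, best$p35 + 6L),
                   score = best$s35),
    minus10 = list(offset = best$p10, seq = substr(seq, best$p10 + 1L, best$p10 + 6L),
                   score = best$s10),
    spacer_len = best$p10 - (best$p35 + 6L),
    joint_score = best$joint,
    cutoff = cutoff,
    confidence = if (best$joint >= cutoff) "confident" else "none"),
    class = "promoter_annotation")
}

best_promoter_arrangement <- function(codes, w35, w10, spacer_range) {
  s35 <- scan_scores(w35, codes)
  s10 <- scan_scores(w10, codes)
  n35 <- length(s35)
  best <- list(joint = -Inf, p35 = NA_integer_, p10 = NA_integer_)
  for (sp in spacer_range) {
    # -10 element starts sp bp after the -35 element ends
    i35 <- seq_len(n35)
    i10 <- i35 + 6L + sp
    ok <- i10 <= length(s10)
    if (!any(ok)) next
    joint <- s35[i35[ok]] + s10[i10[ok]]
    joint[is.na(joint)] <- -Inf
    if (!any(is.finite(joint))) next
    # ties resolved toward the start codon: prefer the largest -10 offset
    j <- which(joint == max(joint))
    j <- j[length(j)]
    if (max(joint) > best$joint ||
        (max(joint) == best$joint && !is.na(best$p10) && (i10[ok][j] - 1L) > best$p10)) {
      best <- list(joint = max(joint),
                   p35 = i35[ok][j] - 1L, p10 = i10[ok][j] - 1L,
                   s35 = s35[i35[ok][j]], s10 = s10[i10[ok][j]])
    }
  }
  if (!is.finite(best$joint)) stopf("no valid promoter arrangement in region")
  best
}

#' @export
print.promoter_annotation <- function(x, ...) {
  cat(sprintf("<promoter> -35 %s@%d  -10 %s@%d  spacer %d bp  joint %.2f (%s)\n",
              x$minus35$seq, x$minus35$offset, x$minus10$seq, x$minus10$offset,
              x$spacer_len, x$joint_score, x$confidence))
  invisible(x)
}

#' Classify a binding site as repressing or activating
#'
#' Geometry rule: a site entirely upstream of the -35 element is an
#' `activator` (roadblock-free recruitment position); a site overlapping
#' either hexamer, lying downstream of the -10 element, or sitting inside
#' the spacer is a `repressor` (it occludes RNA-polymerase engagement);
#' `ND` when no confident promoter was found.  The rule set is exhaustive
#' and exclusive, and sliding a site downstream through a fixed promoter
#' can only switch the label activator -> repressor, never back.
#'
#' @param site one hit row from [scan_region()] (or any list with
#'   `region_offset` and the motif length deducible from `sequence`), whose
#'   offsets are in the same region coordinates as `promoter`.
#' @param promoter a [find_promoter()] annotation from the same region.
#' @return `"repressor"`, `"activator"` or `"ND"`.
#' @export
classify_mode <- function(site, promoter) {
  stopifnot(inherits(promoter, "promoter_annotation"))
  if (promoter$confidence == "none") return("ND")
  s <- site$region_offset
  e <- s + nchar(site$sequence)
  m35 <- c(promoter$minus35$offset, promoter$minus35$offset + 6L)
  if (e <= m35[1]) "activator" else "repressor"
}
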