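## Ortholog detection across genomes: pairwise protein similarity,
## reciprocal best hits, and single-linkage grouping with a synteny
## tie-breaker.  Regulons and TFs are propagated along these groups.

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' All-vs-all protein similarity between two proteomes
#'
#' Global pairwise alignment (BLOSUM62, affine gaps: open 11, extend 1)
#' of every protein in `proteomeA` against every protein in `proteomeB`.
#' Hits below the identity/coverage thresholds are dropped.
#'
#' @param proteomeA,proteomeB named character vectors of amino-acid
#'   sequences (names are gene ids).
#' @param min_identity minimum percent identity (default 30).
#' @param min_coverage minimum alignment coverage of **both** sequences,
#'   percent (default 70).
#' @return data frame with columns `query`, `hit`, `pid`, `cov_query`,
#'   `cov_hit`, `score`, `aln_length`.
#' @export
all_vs_all_similarity <- function(proteomeA, proteomeB,
                                  min_identity = 30, min_coverage = 70) {
  if (!length(proteomeA) || !length(proteomeB)) stopf("empty proteome")
  patt <- Biostrings::AAStringSet(proteomeA)
  res <- vector("list", length(proteomeB))
  for (j in seq_along(proteomeB)) {
    aln <- Biostrings::pairwiseAlignment(
      patt, Biostrings::AAString(proteomeB[[j]]),
      substitutionMatrix = blosum62(), gapOpening = 11, gapExtension = 1,
      type = "global")
    naln <- Biostrings::nmatch(aln) + Biostrings::nmismatch(aln)
    res[[j]] <- data.frame(
      query = names(proteomeA),
      hit = names(proteomeB)[j],
      pid = Biostrings::pid(aln, type = "PID1"),
      cov_query = 100 * naln / nchar(proteomeA),
      cov_hit = 100 * naln / nchar(proteomeB[[j]]),
      score = BiocGenerics::score(aln),
      aln_length = Biostrings::nchar(aln),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out <- out[out$pid >= min_identity & out$cov_query >= min_coverage &
               out$cov_hit >= min_coverage, , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$query, -out$score, -out$aln_length, out$hit), , drop = FALSE]
}

best_hit_per_query <- function(pairs) {
  if (!nrow(pairs)) return(pairs)
  # deterministic tie-break: score, then longer alignment, then gene id
  pairs <- pairs[order(pairs$query, -pairs$score, -pairs$aln_length, pairs$hit), ]
  pairs[!duplicated(pairs$query), , drop = FALSE]
}

#' Reciprocal best hits between two proteomes
#'
#' A pair (a, b) is kept iff b is a's best hit in B and a is b's best hit
#' in A, both passing the similarity thresholds already applied upstream.
#' Ties are broken by longer alignment, then lexicographic gene id, so the
#' result is deterministic and independent of input order.
#'
#' @param pairs_AB,pairs_BA outputs of [all_vs_all_similarity()] in the two
#'   directions, computed with identical parameters.
#' @return data frame of reciprocal pairs: `gene_a`, `gene_b`, `pid`,
#'   `score`, `aln_length`.
#' @export
reciprocal_best_hits <- function(pairs_AB, pairs_BA) {
  ab <- best_hit_per_query(pairs_AB)
  ba <- best_hit_per_query(pairs_BA)
  if (!nrow(ab) || !nrow(ba)) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      pid = numeric(0), score = numeric(0),
                      aln_length = integer(0), stringsAsFactors = FALSE))
  }
  back <- stats::setNames(ba$hit, ba$query)
  keep <- !is.na(back[ab$hit]) & back[ab$hit] == ab$query
  out <- data.frame(gene_a = ab$query[keep], gene_b = ab$hit[keep],
                    pid = ab$pid[keep], score = ab$score[keep],
                    aln_length = ab$aln_length[keep], stringsAsFactors = FALSE)
  out[order(out$gene_a), , drop = FALSE]
}

## ---------------------------------------------------------------------------
## Grouping

proteome_of <- function(g) stats::setNames(g$genes$protein, g$genes$gene_id)

## gene order index within each genome (by contig, then coordinate)
gene_order_index <- function(g) {
  genes <- g$genes[order(g$genes$contig_id, g$genes$start), ]
  stats::setNames(seq_len(nrow(genes)), genes$gene_id)
}

#' Build ortholog groups across a set of genomes
#'
#' Computes reciprocal best hits for every genome pair, then single-linkage
#' clusters them.  When one genome contributes more than one gene to a
#' cluster, the gene sharing at least one orthologous neighbor within
#' `synteny_window` genes of another cluster member is kept (gene
#' neighborhood analysis); failing that, the best-scoring gene.  Displaced
#' genes become singleton groups.  The result is invariant under genome
#' input order.
#'
#' @param genomes list of [genome()] objects.
#' @param min_identity,min_coverage similarity thresholds, see
#'   [all_vs_all_similarity()].
#' @param synteny_window neighborhood radius in genes (default 5).
#' @param precomputed optional ortholog table (data frame with `group_id`,
#'   `genome_id`, `gene_id`) that bypasses alignment entirely.
#' @return data frame with columns `group_id`, `genome_id`, `gene_id`,
#'   at most one gene per genome per group.
#' @export
build_groups <- function(genomes, min_identity = 30, min_coverage = 70,
                         synteny_window = 5, precomputed = NULL) {
  if (!is.null(precomputed)) {
    stopifnot(all(c("group_id", "genome_id", "gene_id") %in% names(precomputed)))
    return(precomputed)
  }
  stopifnot(length(genomes) >= 2L)
  gids <- vapply(genomes, function(g) g$genome_id, character(1))
  names(genomes) <- gids
  gids <- sort(gids)
  # reciprocal pairs for every genome pair, keyed "genome|gene"
  pair_rows <- list()
  for (i in seq_along(gids)) for (j in seq_along(gids)) {
    if (i >= j) next
    A <- genomes[[gids[i]]]; B <- genomes[[gids[j]]]
    ab <- all_vs_all_similarity(proteome_of(A), proteome_of(B), min_identity, min_coverage)
    # global alignment is symmetric: the reverse direction is the same hit
    # set with query/hit (and the two coverages) swapped
    ba <- data.frame(query = ab$hit, hit = ab$query, pid = ab$pid,
                     cov_query = ab$cov_hit, cov_hit = ab$cov_query,
                     score = ab$score, aln_length = ab$aln_length,
                     stringsAsFactors = FALSE)
    rbh <- reciprocal_best_hits(ab, ba)
    if (nrow(rbh))
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        a = paste(gids[i], rbh$gene_a, sep = "|"),
        b = paste(gids[j], rbh$gene_b, sep = "|"),
        score = rbh$score, stringsAsFactors = FALSE)
  }
  pairs <- if (length(pair_rows)) do.call(rbind, pair_rows)
           else data.frame(a = character(0), b = character(0), score = numeric(0))
  nodes <- sort(unique(unlist(lapply(genomes, function(g)
    paste(g$genome_id, g$genes$gene_id, sep = "|")))))
  comp <- union_find(nodes, pairs)
  order_idx <- lapply(genomes, gene_order_index)
  resolve_groups(comp, pairs, order_idx, synteny_window)
}

union_find <- function(nodes, pairs) {
  parent <- stats::setNames(seq_along(nodes), nodes)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(pairs)) {
    pairs <- pairs[order(pairs$a, pairs$b), ]
    for (r in seq_len(nrow(pairs))) {
      ra <- find(match(pairs$a[r], nodes)); rb <- find(match(pairs$b[r], nodes))
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_along(nodes), find, integer(1))
  split(nodes, nodes[roots])
}

resolve_groups <- function(comp, pairs, order_idx, synteny_window) {
  pair_key <- c(paste(pairs$a, pairs$b), paste(pairs$b, pairs$a))
  pair_score <- stats::setNames(c(pairs$score, pairs$score), pair_key)
  rows <- list(); singletons <- character(0)
  comp <- comp[order(vapply(comp, min, character(1)))]
  gid_of <- function(x) sub("\\|.*$", "", x)
  gene_of <- function(x) sub("^[^|]*\\|", "", x)
  for (members in comp) {
    members <- sort(members)
    by_genome <- split(members, gid_of(members))
    kept <- character(0)
    for (gm in names(by_genome)) {
      cand <- by_genome[[gm]]
      if (length(cand) == 1L) { kept <- c(kept, cand); next }
      others <- setdiff(members, cand)
      syntenic <- vapply(cand, function(x)
        has_syntenic_support(x, others, pairs, order_idx, synteny_window), logical(1))
      pick <- if (any(syntenic)) cand[syntenic][1]
              else cand[which.max(vapply(cand, function(x)
                sum(pair_score[paste(x, others)], na.rm = TRUE), numeric(1)))]
      kept <- c(kept, pick)
      singletons <- c(singletons, setdiff(cand, pick))
    }
    rows[[length(rows) + 1L]] <- kept
  }
  rows <- c(rows, as.list(singletons))
  out <- do.call(rbind, lapply(seq_along(rows), function(i) {
    data.frame(group_id = sprintf("OG%04d", i),
               genome_id = gid_of(rows[[i]]),
               gene_id = gene_of(rows[[i]]), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

## does candidate x share an RBH-linked neighbor (within the window) with a
## neighbor of any other member of the group?
has_syntenic_support <- function(x, others, pairs, order_idx, synteny_window) {
  if (!nrow(pairs)) return(FALSE)
  gidx <- function(node) {
    gm <- sub("\\|.*$", "", node); gn <- sub("^[^|]*\\|", "", node)
    order_idx[[gm]][gn]
  }
  near <- function(node) {
    gm <- sub("\\|.*$", "", node)
    idx <- order_idx[[gm]]
    i <- gidx(node)
    paste(gm, names(idx)[abs(idx - i) <= synteny_window & idx != i], sep = "|")
  }
  nx <- near(x)
  for (o in others) {
    no <- near(o)
    hit <- (pairs$a %in% nx & pairs$b %in% no) | (pairs$b %in% nx & pairs$a %in% no)
    if (any(hit)) return(TRUE)
  }
  FALSE
}

#' Read/write an ortholog table TSV
#'
#' Columns: `group_id`, `genome_id`, `gene_id`.  The same format is
#' accepted by [build_groups()] via `precomputed`.
#'
#' @param groups data frame of groups.
#' @param path file path.
#' @export
write_ortholog_table <- function(groups, path) {
  utils::write.table(groups, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ortholog_table
#' @export
read_ortholog_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
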