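## Propagation of candidate regulon members across ortholog groups, the
## cross-genome consistency-check / phylogenetic-footprinting filters, and
## core vs genome-specific partitioning.

#' Propagate candidate regulon members across genomes
#'
#' Scans every operon-leader upstream region in each genome carrying an
#' ortholog of the TF, and joins the hits to the ortholog groups of the
#' target-operon genes.  Candidates are keyed by ortholog group; an operon
#' leader whose group has members in only one genome yields a
#' genome-specific candidate key (`GS:<genome>:<gene>`).
#'
#' @param tf_group_id ortholog group id of the TF in `groups`.
#' @param model a calibrated [motif_model()].
#' @param genomes list of [genome()] objects.
#' @param groups ortholog table from [build_groups()].
#' @param window,max_gap_bp see [scan_genome()].
#' @return data frame of candidates: `candidate_id`, `genome_id`,
#'   `gene_id`, `target_gene` (operon leader), `operon_id`, `score`,
#'   `class`, `pos_vs_start_codon`, `region_offset`, `genome_specific`.
#' @export
propagate <- function(tf_group_id, model, genomes, groups,
                      window = c(-350, 50), max_gap_bp = 150) {
  tf_genomes <- groups$genome_id[groups$group_id == tf_group_id]
  if (!length(tf_genomes)) stopf("TF group '%s' has no members in any genome", tf_group_id)
  names(genomes) <- vapply(genomes, function(g) g$genome_id, character(1))
  group_size <- table(groups$group_id)
  gene_group <- stats::setNames(groups$group_id,
                                paste(groups$genome_id, groups$gene_id))
  rows <- list()
  for (gm in intersect(names(genomes), tf_genomes)) {
    g <- genomes[[gm]]
    operons <- group_operons(g, max_gap_bp)
    hits <- scan_genome(model, g, operons, window, max_gap_bp)
    if (!nrow(hits)) next
    op_of <- stats::setNames(operons$operon_id, operons$gene_id)
    genes_of_op <- split(operons$gene_id, operons$operon_id)
    for (leader in unique(hits$target_gene)) {
      h <- hits[hits$target_gene == leader, , drop = FALSE]
      h <- h[which.max(h$score), , drop = FALSE]   # best site per target
      for (gene in genes_of_op[[op_of[[leader]]]]) {
        grp <- gene_group[paste(gm, gene)]
        gs <- is.na(grp) || group_size[grp] <= 1L
        key <- if (gs) sprintf("GS:%s:%s", gm, gene) else unname(grp)
        rows[[length(rows) + 1L]] <- data.frame(
          candidate_id = key, genome_id = gm, gene_id = gene,
          target_gene = leader, operon_id = op_of[[leader]],
          score = h$score, class = h$class,
          pos_vs_start_codon = h$pos_vs_start_codon,
          region_offset = h$region_offset,
          genome_specific = gs, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_candidates()
  rownames(out) <- NULL
  out
}

empty_candidates <- function() {
  data.frame(candidate_id = character(0), genome_id = character(0),
             gene_id = character(0), target_gene = character(0),
             operon_id = character(0), score = numeric(0), class = character(0),
             pos_vs_start_codon = integer(0), region_offset = integer(0),
             genome_specific = logical(0), stringsAsFactors = FALSE)
}

#' Consistency-check and footprinting filter for candidate regulon members
#'
#' A candidate ortholog-group member is accepted when strong sites recur
#' upstream of its members in at least
#' `min(min_genomes, ceiling(n_carriers / 2))` genomes, where `n_carriers`
#' is the number of genomes carrying the gene: the full `min_genomes`
#' requirement applies to widely distributed genes, and genes carried by
#' few genomes fall back to a 50%-of-carriers rule.  (This cap is the
#' minimal relaxation that keeps acceptance monotone in `min_genomes`.)
#' Weak sites count toward conservation only when the same group has a
#' strong site in at least one other genome (orthologous footprinting
#' support).  Genome-specific candidates need a strong site and are
#' flagged.
#'
#' @param candidates data frame from [propagate()].
#' @param groups ortholog table (to count carriers per group).
#' @param min_genomes strong-site recurrence requirement (default 3).
#' @param weak_needs_support if `FALSE`, weak sites count unconditionally.
#' @return data frame of accepted members: `candidate_id`, `genomes_strong`,
#'   `genomes_weak_supported`, `conservation_count`, `genome_specific`.
#' @export
consistency_filter <- function(candidates, groups, min_genomes = 3,
                               weak_needs_support = TRUE) {
  if (!nrow(candidates))
    return(data.frame(candidate_id = character(0), genomes_strong = integer(0),
                      genomes_weak_supported = integer(0),
                      conservation_count = integer(0),
                      genome_specific = logical(0), stringsAsFactors = FALSE))
  group_size <- table(groups$group_id)
  rows <- lapply(split(candidates, candidates$candidate_id), function(cand) {
    strong_gm <- unique(cand$genome_id[cand$class == "strong"])
    weak_gm <- setdiff(unique(cand$genome_id[cand$class == "weak"]), strong_gm)
    if (weak_needs_support)
      weak_gm <- weak_gm[vapply(weak_gm, function(gm)
        length(setdiff(strong_gm, gm)) >= 1L, logical(1))]
    gs <- cand$genome_specific[1]
    n_carry <- if (gs) 1L else as.integer(group_size[cand$candidate_id[1]])
    need <- if (gs) 1L else min(min_genomes, max(1L, ceiling(n_carry / 2)))
    if (length(strong_gm) < need) return(NULL)
    data.frame(candidate_id = cand$candidate_id[1],
               genomes_strong = length(strong_gm),
               genomes_weak_supported = length(weak_gm),
               conservation_count = length(strong_gm) + length(weak_gm),
               genome_specific = gs, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    return(consistency_filter(empty_candidates(), groups, min_genomes))
  rownames(out) <- NULL
  out[order(-out$conservation_count, out$candidate_id), , drop = FALSE]
}

#' Partition accepted regulon members into core and specific classes
#'
#' @param members data frame from [consistency_filter()].
#' @param core_min conservation count defining the core regulon
#'   (default 20 genomes).
#' @return `members` with a `class` column: `"core"` when
#'   `conservation_count >= core_min`, `"genome-specific"` when flagged,
#'   else `"group-specific"`.
#' @export
call_core <- function(members, core_min = 20) {
  if (!nrow(members)) { members$class <- character(0); return(members) }
  members$class <- ifelse(members$conservation_count >= core_min, "core",
                          ifelse(members$genome_specific, "genome-specific",
                                 "group-specific"))
  members
}

#' Discover candidate local regulators by chromosomal co-localization
#'
#' Local TFs of sugar catabolic pathways tend to sit next to the genes
#' they control.  Reports genes annotated with a regulator role (or a bare
#' LacI/TetR/ROK family label) located within `k` operons of any
#' arabinose/AOS pathway gene on the same contig.
#'
#' @param g a [genome()] with role annotations.
#' @param operons output of [group_operons()]; computed if `NULL`.
#' @param k neighborhood radius in operons (default 2).
#' @return data frame: `gene_id`, `role`, `family`, `nearest_pathway_gene`,
#'   `distance_operons`.
#' @export
local_tf_discovery <- function(g, operons = NULL, k = 2) {
  if (is.null(operons)) operons <- group_operons(g)
  tf_roles <- names(TF_ROLE_FAMILY)
  pathway_roles <- setdiff(subsystem_roles(), tf_roles)
  roles <- stats::setNames(g$genes$role, g$genes$gene_id)
  op_index <- stats::setNames(match(operons$operon_id, unique(operons$operon_id)),
                              operons$gene_id)
  contig_of <- stats::setNames(g$genes$contig_id, g$genes$gene_id)
  tf_genes <- names(roles)[!is.na(roles) & roles %in% c(tf_roles, "LacI", "TetR", "ROK")]
  path_genes <- names(roles)[!is.na(roles) & roles %in% pathway_roles]
  rows <- list()
  for (tf in tf_genes) {
    same <- path_genes[contig_of[path_genes] == contig_of[tf]]
    if (!length(same)) next
    d <- abs(op_index[same] - op_index[tf])
    if (min(d) <= k) {
      j <- which.min(d)
      fam <- if (roles[tf] %in% tf_roles) TF_ROLE_FAMILY[[roles[tf]]] else roles[tf]
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = tf, role = roles[tf], family = fam,
        nearest_pathway_gene = same[j], distance_operons = unname(min(d)),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(gene_id = character(0), role = character(0),
                      family = character(0), nearest_pathway_gene = character(0),
                      distance_operons = integer(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a regulon report TSV
#'
#' One row per accepted member: tf_name, member id, conservation count,
#' class (core / group-specific / genome-specific) and regulation mode
#' when available.
#'
#' @param members output of [call_core()], optionally with a `mode` column.
#' @param tf_name regulator name for the first column.
#' @param path output file.
#' @export
write_regulon_tsv <- function(members, tf_name, path) {
  out <- data.frame(tf_name = tf_name,
                    member = members$candidate_id,
                    n_genomes_with_site = members$conservation_count,
                    class = members$class,
                    mode = if ("mode" %in% names(members)) members$mode else "ND",
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
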