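## End-to-end orchestration: genomes -> orthologs -> motif -> scan ->
## regulon -> mode -> phenotypes, with a run manifest and TSV reporters.

#' Pipeline configuration
#'
#' Collects every tunable of the analysis chain with its default: the
#' -350..+50 upstream window, the strong/weak threshold policy (see
#' [calibrate_thresholds()]; the `"araq"` preset reproduces the laxer
#' global-regulon scale), candidate motif lengths, orthology thresholds,
#' the consistency-check requirement (`min_genomes`), the core-regulon
#' cutoff (20 genomes), the operon gap, and the RNG seed.
#'
#' @param window upstream window relative to the start codon.
#' @param max_gap_bp operon gap threshold (bp).
#' @param min_genomes consistency-check requirement.
#' @param core_min core-regulon conservation cutoff.
#' @param motif_L candidate motif length(s) for discovery.
#' @param n_restarts discovery restarts.
#' @param threshold_preset `"default"` or `"araq"`.
#' @param min_identity,min_coverage,synteny_window orthology parameters.
#' @param seed RNG seed used for every stochastic stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(window = c(-350, 50), max_gap_bp = 150,
                            min_genomes = 3, core_min = 20,
                            motif_L = c(14, 16, 18, 20, 22), n_restarts = 20,
                            threshold_preset = c("default", "araq"),
                            min_identity = 30, min_coverage = 70,
                            synteny_window = 5, seed = 1) {
  stopifnot(length(window) == 2L, window[1] < window[2], max_gap_bp >= 0,
            min_genomes >= 1, core_min >= 1, all(motif_L %% 2 == 0),
            n_restarts >= 1)
  structure(list(window = window, max_gap_bp = max_gap_bp,
                 min_genomes = min_genomes, core_min = core_min,
                 motif_L = motif_L, n_restarts = n_restarts,
                 threshold_preset = match.arg(threshold_preset),
                 min_identity = min_identity, min_coverage = min_coverage,
                 synteny_window = synteny_window, seed = seed),
            class = "pipeline_config")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

#' Run the full regulon-reconstruction pipeline
#'
#' Known-TF path: supply `training_sites` (character vector or data frame
#' with a `sequence` column) and the PWM is built from them.  Novel-TF
#' path: supply `candidate_genes` (data frame `genome_id`, `gene_id` of
#' genes suspected to be regulated, e.g. from [local_tf_discovery()]
#' neighborhoods) and a palindromic motif is discovered de novo in their
#' upstream regions.
#'
#' @param genomes list of [genome()] objects.
#' @param tf_ref list `(genome_id, gene_id)` naming one TF gene; its
#'   ortholog group defines which genomes are scanned.
#' @param training_sites known binding sites (known-TF path).
#' @param candidate_genes candidate regulated genes (novel-TF path).
#' @param config a [pipeline_config()].
#' @param tf_name regulator name used in reports.
#' @param ortholog_table optional precomputed ortholog table (bypasses
#'   alignment).
#' @return list of class `pipeline_report`: `groups`, `tf_group_id`,
#'   `model`, `candidates`, `members` (with `class` and `mode`),
#'   `member_modes` (per-genome mode calls), `phenotypes`, `manifest`.
#' @export
run_pipeline <- function(genomes, tf_ref, training_sites = NULL,
                         candidate_genes = NULL, config = pipeline_config(),
                         tf_name = "TF", ortholog_table = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(training_sites) && is.null(candidate_genes))
    stopf("supply training_sites (known-TF path) or candidate_genes (novel-TF path)")
  names(genomes) <- vapply(genomes, function(g) g$genome_id, character(1))
  groups <- build_groups(genomes, config$min_identity, config$min_coverage,
                         config$synteny_window, precomputed = ortholog_table)
  tf_group_id <- groups$group_id[groups$genome_id == tf_ref$genome_id &
                                   groups$gene_id == tf_ref$gene_id]
  if (!length(tf_group_id))
    stopf("TF gene %s/%s is not in any ortholog group",
          tf_ref$genome_id, tf_ref$gene_id)
  model <- if (!is.null(training_sites)) {
    motif_model(training_sites, name = tf_name,
                preset = config$threshold_preset)
  } else {
    regions <- lapply(seq_len(nrow(candidate_genes)), function(i)
      extract_upstream(genomes[[candidate_genes$genome_id[i]]],
                       candidate_genes$gene_id[i], config$window))
    m <- discover_palindromic_motif(regions, L = config$motif_L,
                                    n_restarts = config$n_restarts,
                                    seed = config$seed, name = tf_name)
    calibrate_thresholds(m, preset = config$threshold_preset)
  }
  candidates <- propagate(tf_group_id, model, genomes, groups,
                          config$window, config$max_gap_bp)
  members <- call_core(consistency_filter(candidates, groups,
                                          config$min_genomes),
                       config$core_min)
  mode_calls <- member_modes(members, candidates, genomes, config, model$L)
  members$mode <- mode_calls$member_mode[members$candidate_id]
  phen <- assign_phenotypes(populate_subsystem(genomes))
  manifest <- list(config = unclass(config), config_hash = config_hash(config),
                   tf_name = tf_name, n_genomes = length(genomes),
                   path = if (is.null(training_sites)) "novel-TF" else "known-TF")
  structure(list(groups = groups, tf_group_id = tf_group_id, model = model,
                 candidates = candidates, members = members,
                 member_modes = mode_calls$per_genome, phenotypes = phen,
                 manifest = manifest),
            class = "pipeline_report")
}

## per-genome repressor/activator calls for accepted members, summarized
## to one label per member by majority (ties or all-ND -> ND)
member_modes <- function(members, candidates, genomes, config, motif_L) {
  per <- list()
  for (cid in members$candidate_id) {
    cand <- candidates[candidates$candidate_id == cid, , drop = FALSE]
    for (r in seq_len(nrow(cand))) {
      g <- genomes[[cand$genome_id[r]]]
      region <- extract_upstream(g, cand$target_gene[r], config$window)
      prom <- find_promoter(region)
      site <- list(region_offset = cand$region_offset[r],
                   sequence = substr(region$seq, cand$region_offset[r] + 1L,
                                     cand$region_offset[r] + motif_L))
      per[[length(per) + 1L]] <- data.frame(
        candidate_id = cid, genome_id = cand$genome_id[r],
        target_gene = cand$target_gene[r],
        mode = classify_mode(site, prom), stringsAsFactors = FALSE)
    }
  }
  per <- if (length(per)) do.call(rbind, per)
         else data.frame(candidate_id = character(0), genome_id = character(0),
                         target_gene = character(0), mode = character(0))
  summarize <- function(m) {
    m <- m[m != "ND"]
    if (!length(m)) return("ND")
    tab <- sort(table(m), decreasing = TRUE)
    if (length(tab) > 1L && tab[1] == tab[2]) "ND" else names(tab)[1]
  }
  member_mode <- vapply(split(per$mode, per$candidate_id), summarize, character(1))
  list(per_genome = per, member_mode = member_mode)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %s (%s path)\n", x$manifest$tf_name,
              x$manifest$path))
  cat(sprintf("  motif: %s (IC %.1f bits)\n", consensus(x$model),
              x$model$ic_bits))
  cat(sprintf("  accepted members: %d (%d core)\n", nrow(x$members),
              sum(x$members$class == "core")))
  cat(sprintf("  phenotypes: %s\n",
              paste(sprintf("%s=%s", x$phenotypes$genome_id,
                            x$phenotypes$composite), collapse = " ")))
  invisible(x)
}

#' Write the pipeline report bundle as TSVs
#'
#' Emits the regulon table, per-genome mode calls, phenotype table,
#' ortholog table, motif matrix and a JSON manifest (with the config
#' hash) into `dir`.
#'
#' @param report a `pipeline_report` from [run_pipeline()].
#' @param dir output directory.
#' @return invisibly, `dir`.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_regulon_tsv(report$members, report$manifest$tf_name,
                    file.path(dir, "regulon.tsv"))
  utils::write.table(report$member_modes, file.path(dir, "modes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_phenotype_tsv(report$phenotypes, file.path(dir, "phenotypes.tsv"))
  write_ortholog_table(report$groups, file.path(dir, "orthologs.tsv"))
  write_motif(report$model, file.path(dir, "motif.txt"))
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
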