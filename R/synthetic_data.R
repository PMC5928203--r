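## Ground-truthed synthetic clades: genomes sharing mutated ortholog
## families, upstream windows carrying implanted palindromic operators,
## sigma70 promoter layouts, and subsystem gene complements realizing
## requested utilization phenotypes.  Everything is deterministic given
## the config seed.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Simulation configuration for a synthetic clade
#'
#' Defaults describe the study conditions the pipeline is benchmarked
#' under: an 8-genome clade with ~60% GC intergenic background, a 16-bp
#' palindromic operator implanted at 10% per-position noise upstream of 4
#' target families, and one phenotype of each kind across the clade.
#'
#' @param n_genomes number of genomes (default 8).
#' @param n_target_families regulated target families (default 4).
#' @param n_filler_families unregulated families (default 4).
#' @param protein_length ancestor protein length in residues (default 120).
#' @param divergence per-branch amino-acid substitution probability per
#'   site, star topology (default 0.1).
#' @param motif_consensus even-length palindromic operator consensus
#'   (default a 16-bp palindrome).
#' @param mismatch_prob per-position site mutation probability in `[0,
#'   0.5)` (default 0.1).
#' @param max_mismatches optional cap on mutated half-site positions per
#'   implant (e.g. 1 for "at most one mismatch" benchmarks); `NULL` for
#'   unconstrained binomial noise.
#' @param regulon_design 0/1 matrix, target families x genomes: which
#'   genomes carry a site upstream of which family (default all ones).
#' @param site_offset site start relative to the start codon (default
#'   -120; used for the `"activator"` and `"none"` layouts).  The
#'   `"repressor"` layout overrides it with -50 so the site falls
#'   downstream of its -10 element, the occluding geometry.
#' @param promoter_layouts per-target layout, recycled:
#'   `"activator"` (promoter at -36/-13, site upstream of -35),
#'   `"repressor"` (promoter at -98/-75, site at -50, downstream of the
#'   -10 element) or `"none"` (no promoter).
#' @param phenotypes per-genome requested phenotype labels, recycled
#'   (default one each of U1, U2, U3, U123, 0, unique).
#' @param gc background G+C content (default 0.6).
#' @param flank_len intergenic flank per gene cassette, bp (default 450;
#'   must hold the full -350..+50 window).
#' @param seed RNG seed (required).
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_genomes = 8, n_target_families = 4,
                              n_filler_families = 4, protein_length = 120,
                              divergence = 0.1,
                              motif_consensus = "ATGTTAGCGCTAACAT",
                              mismatch_prob = 0.1, max_mismatches = NULL,
                              regulon_design = NULL,
                              site_offset = -120,
                              promoter_layouts = c("activator", "repressor", "none"),
                              phenotypes = c("U1", "U2", "U3", "U123", "0", "unique"),
                              gc = 0.6, flank_len = 450, seed) {
  if (missing(seed)) stopf("simulation_config() requires a seed")
  motif_consensus <- toupper(motif_consensus)
  if (!is_palindrome(motif_consensus))
    stopf("motif consensus must be its own reverse complement")
  if (nchar(motif_consensus) %% 2L != 0L) stopf("motif consensus length must be even")
  if (mismatch_prob < 0 || mismatch_prob >= 0.5)
    stopf("mismatch_prob must be in [0, 0.5)")
  if (is.null(regulon_design))
    regulon_design <- matrix(1L, n_target_families, n_genomes)
  if (!all(dim(regulon_design) == c(n_target_families, n_genomes)))
    stopf("regulon_design must be %d x %d", n_target_families, n_genomes)
  L <- nchar(motif_consensus)
  if (site_offset < -350 || site_offset + L > 50)
    stopf("site (offset %d, length %d) does not fit the -350..+50 window",
          site_offset, L)
  if (flank_len < 350) stopf("flank_len must be >= 350 to hold the upstream window")
  structure(list(n_genomes = n_genomes, n_target_families = n_target_families,
                 n_filler_families = n_filler_families,
                 protein_length = protein_length, divergence = divergence,
                 motif_consensus = motif_consensus,
                 mismatch_prob = mismatch_prob, max_mismatches = max_mismatches,
                 regulon_design = regulon_design, site_offset = site_offset,
                 promoter_layouts = rep(promoter_layouts,
                                        length.out = n_target_families),
                 phenotypes = rep(phenotypes, length.out = n_genomes),
                 gc = gc, flank_len = flank_len, seed = seed),
            class = "simulation_config")
}

#' Implant a palindromic site into a region
#'
#' Per-position noise: each consensus base is kept with probability
#' `1 - mismatch_prob`, else replaced by one of the three other bases
#' uniformly; the site is then re-palindromized by mirroring the first
#' half, so every emitted site is its own reverse complement.  Uses the
#' current RNG state (seed management belongs to the caller).
#'
#' @param region_seq region sequence (character).
#' @param consensus palindromic consensus to implant.
#' @param mismatch_prob per-position mutation probability.
#' @param position 0-based offset of the site start within `region_seq`.
#' @param max_mismatches optional cap on mutated half-site positions.
#' @return list with `seq` (modified region) and `site` (implanted site
#'   sequence).
#' @export
implant_site <- function(region_seq, consensus, mismatch_prob, position,
                         max_mismatches = NULL) {
  L <- nchar(consensus)
  if (position < 0 || position + L > nchar(region_seq))
    stopf("site position %d outside the region (length %d)", position,
          nchar(region_seq))
  site <- mutate_palindrome(consensus, mismatch_prob, max_mismatches)
  list(seq = paste0(substr(region_seq, 1, position),
                    site,
                    substr(region_seq, position + L + 1L, nchar(region_seq))),
       site = site)
}

mutate_palindrome <- function(consensus, p, max_mismatches = NULL) {
  L <- nchar(consensus)
  half <- strsplit(substr(consensus, 1, L / 2), "")[[1]]
  mut <- runif(length(half)) < p
  if (!is.null(max_mismatches) && sum(mut) > max_mismatches)
    mut <- seq_along(mut) %in% sample(which(mut), max_mismatches)
  half[mut] <- vapply(half[mut], function(b)
    sample(setdiff(DNA_BASES, b), 1L), character(1))
  first <- paste(half, collapse = "")
  paste0(first, revcomp(first))
}

#' Minimal role complements realizing requested phenotypes
#'
#' Inverts the phenotype rules: returns, per requested label, a role set
#' that [assign_phenotype()] maps back to exactly that label.
#'
#' @param labels character vector of requested labels (`U1`, `U2`, `U3`,
#'   `U123`, `U12`, `U13`, `U23`, `0`, `unique`).
#' @return named list of character role vectors.
#' @export
assign_truth_phenotypes <- function(labels) {
  w_u1 <- c("araB", "araD", "araA", "araE")
  w_u2 <- c("araB", "araD", "araA", "aauA", "aauB", "aauC", "abfII_1")
  w_u3 <- c("araB", "araD", "araA", "bauT", "hypBA1")
  witness <- function(lab) {
    switch(lab,
           "U1" = w_u1, "U2" = w_u2, "U3" = w_u3,
           "U12" = union(w_u1, w_u2), "U13" = union(w_u1, w_u3),
           "U23" = union(w_u2, w_u3),
           "U123" = Reduce(union, list(w_u1, w_u2, w_u3)),
           "0" = character(0),
           "unique" = c("araB", "araD", "araA"),
           stopf("unknown phenotype label '%s'", lab))
  }
  out <- lapply(labels, witness)
  names(out) <- make.unique(labels)
  out
}

## ---------------------------------------------------------------------------
## Clade generation

reverse_translate <- function(protein, codons_by_aa) {
  aas <- strsplit(protein, "")[[1]]
  codons <- vapply(aas, function(a) {
    cs <- codons_by_aa[[a]]
    cs[sample.int(length(cs), 1L)]
  }, character(1))
  paste0(paste(codons, collapse = ""), "TAA")
}

mutate_protein <- function(protein, divergence) {
  aas <- strsplit(protein, "")[[1]]
  mut <- runif(length(aas)) < divergence
  aas[mut] <- vapply(aas[mut], function(a)
    sample(setdiff(AA_ALPHABET, a), 1L), character(1))
  paste(aas, collapse = "")
}

#' Generate a ground-truthed synthetic clade
#'
#' Emits one genome per clade member plus complete truth records.  Gene
#' families evolve from random ancestor proteins along a star topology
#' (per-branch substitution rate `divergence`, no indels).  Each target
#' family occupies its own gene cassette: a background flank (configured
#' GC) carrying the implanted operator and promoter layout, followed by
#' the coding sequence (reverse-translated with random synonymous codons,
#' bacterial code).  Target strands alternate so both orientations are
#' exercised; the first target additionally carries a same-strand
#' follower gene 50 bp downstream, forming a two-gene operon.  Role genes
#' realizing the requested phenotype labels are appended.  For the
#' `"none"` promoter layout the flank is re-sampled (seeded) until the
#' assembled upstream window contains no confident promoter arrangement,
#' so ND truth labels are guaranteed correct.
#'
#' @param config a [simulation_config()].
#' @return list with `genomes` (list of [genome()]), `truth` (lists
#'   `sites`, `families`, `regulon`, `promoters`, `modes`, `phenotypes`)
#'   and `config`.
#' @export
generate_clade <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  code <- Biostrings::getGeneticCode("11")
  codons_by_aa <- split(names(code), code)
  with_seed(config$seed, {
    n_t <- config$n_target_families
    fam_names <- c("TF", paste0("T", seq_len(n_t)), "T1b",
                   if (config$n_filler_families > 0)
                     paste0("F", seq_len(config$n_filler_families)))
    role_sets <- assign_truth_phenotypes(config$phenotypes)
    all_roles <- sort(unique(unlist(role_sets)))
    role_fams <- if (length(all_roles)) paste0("role_", all_roles) else character(0)
    ancestors <- stats::setNames(
      vapply(c(fam_names, role_fams), function(f)
        paste(sample(AA_ALPHABET, config$protein_length, replace = TRUE),
              collapse = ""), character(1)),
      c(fam_names, role_fams))
    genomes <- vector("list", config$n_genomes)
    sites <- list(); families <- list(); promoters <- list(); modes <- list()
    for (gi in seq_len(config$n_genomes)) {
      gm <- sprintf("G%02d", gi)
      bld <- clade_genome(gm, gi, config, ancestors, codons_by_aa,
                          role_sets[[gi]])
      genomes[[gi]] <- bld$genome
      sites[[gi]] <- bld$sites; families[[gi]] <- bld$families
      promoters[[gi]] <- bld$promoters; modes[[gi]] <- bld$modes
    }
    names(genomes) <- vapply(genomes, function(g) g$genome_id, character(1))
    truth <- list(
      sites = do.call(rbind, sites),
      families = do.call(rbind, families),
      regulon = config$regulon_design,
      promoters = do.call(rbind, promoters),
      modes = do.call(rbind, modes),
      phenotypes = data.frame(
        genome_id = vapply(genomes, function(g) g$genome_id, character(1)),
        label = config$phenotypes,
        roles = vapply(role_sets, paste, character(1), collapse = ","),
        stringsAsFactors = FALSE))
    list(genomes = genomes, truth = truth, config = config)
  })
}

## Build one genome of the clade (assumes RNG state is set by the caller).
clade_genome <- function(gm, gi, config, ancestors, codons_by_aa, roles) {
  L <- nchar(config$motif_consensus)
  flank_len <- config$flank_len
  prot <- vapply(ancestors, mutate_protein, character(1),
                 divergence = config$divergence)
  parts <- character(0); cursor <- 0L
  genes <- list(); sites <- list(); families <- list()
  promoters <- list(); modes <- list()
  gene_n <- 0L
  new_gene_id <- function() { gene_n <<- gene_n + 1L; sprintf("%s_g%03d", gm, gene_n) }
  add_cassette <- function(fam, strand, role = NA_character_,
                           implant = FALSE, layout = "none",
                           follower_fam = NULL) {
    cds <- reverse_translate(prot[[fam]], codons_by_aa)
    follower_cds <- if (!is.null(follower_fam))
      reverse_translate(prot[[follower_fam]], codons_by_aa)
    site_off <- if (layout == "repressor") -50L else config$site_offset
    make_flank <- function() {
      fl <- random_dna(flank_len, config$gc)
      if (layout != "none") {
        offs <- promoter_layout_offsets(layout)
        substr(fl, flank_len + offs$m35 + 1L, flank_len + offs$m35 + 6L) <- PROMOTER_MINUS35
        substr(fl, flank_len + offs$m10 + 1L, flank_len + offs$m10 + 6L) <- PROMOTER_MINUS10
      }
      fl
    }
    flank <- make_flank()
    site_seq <- NA_character_
    if (implant) {
      imp <- implant_site(flank, config$motif_consensus, config$mismatch_prob,
                          flank_len + site_off, config$max_mismatches)
      flank <- imp$seq; site_seq <- imp$site
    }
    if (layout == "none") {
      # guarantee the ND truth label: re-sample background until the
      # upstream window holds no confident promoter arrangement
      for (try in 1:20) {
        win <- paste0(substr(flank, flank_len - 350 + 1L, flank_len),
                      substr(cds, 1, 50))
        if (find_promoter(win)$confidence == "none") break
        flank <- make_flank()
        if (implant) {
          imp <- implant_site(flank, config$motif_consensus,
                              config$mismatch_prob,
                              flank_len + site_off, config$max_mismatches)
          flank <- imp$seq; site_seq <- imp$site
        }
      }
    }
    oriented <- paste0(flank, cds,
                       if (!is.null(follower_fam))
                         paste0(random_dna(50, config$gc), follower_cds))
    n <- nchar(oriented)
    lead_id <- new_gene_id()
    foll_id <- if (!is.null(follower_fam)) new_gene_id()
    rel <- list(c(flank_len, flank_len + nchar(cds)))
    if (!is.null(follower_fam))
      rel[[2]] <- c(flank_len + nchar(cds) + 50L,
                    flank_len + nchar(cds) + 50L + nchar(follower_cds))
    ids <- c(lead_id, foll_id)
    fams <- c(fam, follower_fam)
    prots <- c(prot[[fam]], if (!is.null(follower_fam)) prot[[follower_fam]])
    if (strand == "+") {
      seq_out <- oriented
      coords <- lapply(rel, function(r) r + cursor)
      site_abs <- cursor + flank_len + site_off
    } else {
      seq_out <- revcomp(oriented)
      coords <- lapply(rel, function(r) cursor + c(n - r[2], n - r[1]))
      site_abs <- cursor + n - (flank_len + site_off) - L
    }
    for (k in seq_along(ids)) {
      genes[[length(genes) + 1L]] <<- data.frame(
        gene_id = ids[k], contig_id = "chr1",
        start = coords[[k]][1], end = coords[[k]][2], strand = strand,
        protein = prots[k], role = if (k == 1L) role else NA_character_,
        stringsAsFactors = FALSE)
      families[[length(families) + 1L]] <<- data.frame(
        genome_id = gm, gene_id = ids[k], family = fams[k],
        stringsAsFactors = FALSE)
    }
    if (implant)
      sites[[length(sites) + 1L]] <<- data.frame(
        genome_id = gm, gene_id = lead_id, family = fam, contig_id = "chr1",
        abs_start = site_abs, abs_end = site_abs + L, sequence = site_seq,
        offset = site_off, stringsAsFactors = FALSE)
    if (fam != "TF" && !startsWith(fam, "F") && !startsWith(fam, "role_")) {
      offs <- promoter_layout_offsets(layout)
      promoters[[length(promoters) + 1L]] <<- data.frame(
        genome_id = gm, gene_id = lead_id, layout = layout,
        minus35_offset = if (layout == "none") NA_integer_ else offs$m35,
        minus10_offset = if (layout == "none") NA_integer_ else offs$m10,
        stringsAsFactors = FALSE)
      modes[[length(modes) + 1L]] <<- data.frame(
        genome_id = gm, gene_id = lead_id, family = fam,
        mode = switch(layout, activator = "activator",
                      repressor = "repressor", none = "ND"),
        stringsAsFactors = FALSE)
    }
    parts[[length(parts) + 1L]] <<- seq_out
    cursor <<- cursor + n + 20L
    parts[[length(parts) + 1L]] <<- random_dna(20, config$gc)
    invisible(NULL)
  }
  add_cassette("TF", "+")
  for (t in seq_len(config$n_target_families)) {
    add_cassette(paste0("T", t), if (t %% 2L == 1L) "+" else "-",
                 implant = config$regulon_design[t, gi] == 1L,
                 layout = config$promoter_layouts[t],
                 follower_fam = if (t == 1L) "T1b")
  }
  for (f in seq_len(config$n_filler_families))
    add_cassette(paste0("F", f), "+")
  for (r in roles)
    add_cassette(paste0("role_", r), "+", role = r)
  g <- genome(gm, c(chr1 = paste(parts, collapse = "")),
              do.call(rbind, genes))
  list(genome = g,
       sites = if (length(sites)) do.call(rbind, sites) else NULL,
       families = do.call(rbind, families),
       promoters = if (length(promoters)) do.call(rbind, promoters) else NULL,
       modes = if (length(modes)) do.call(rbind, modes) else NULL)
}

promoter_layout_offsets <- function(layout) {
  switch(layout,
         activator = list(m35 = -36L, m10 = -13L),
         repressor = list(m35 = -98L, m10 = -75L),
         none = list(m35 = NA_integer_, m10 = NA_integer_))
}

#' Write a synthetic clade to disk
#'
#' Emits FASTA + GFF3 per genome, truth TSVs (sites, families, regulon
#' design matrix, promoters, modes, phenotypes) and a `manifest.json`
#' recording the configuration and seed.
#'
#' @param clade output of [generate_clade()].
#' @param dir output directory (created if absent).
#' @return invisibly, `dir`.
#' @export
write_clade <- function(clade, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in clade$genomes)
    write_genome(g, file.path(dir, paste0(g$genome_id, ".fasta")),
                 file.path(dir, paste0(g$genome_id, ".gff3")))
  tr <- clade$truth
  wt <- function(x, f) utils::write.table(x, file.path(dir, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  wt(tr$sites, "truth_sites.tsv")
  wt(tr$families, "truth_families.tsv")
  wt(as.data.frame(tr$regulon), "truth_regulon_design.tsv")
  wt(tr$promoters, "truth_promoters.tsv")
  wt(tr$modes, "truth_modes.tsv")
  wt(tr$phenotypes, "truth_phenotypes.tsv")
  cfg <- clade$config
  class(cfg) <- NULL
  cfg$regulon_design <- as.data.frame(cfg$regulon_design)
  jsonlite::write_json(cfg, file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}
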