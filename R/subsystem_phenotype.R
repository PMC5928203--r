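## The arabinose/arabino-oligosaccharide (AOS) functional-role subsystem
## and per-genome utilization phenotype calls.

#' Controlled vocabulary of arabinose/AOS subsystem roles
#'
#' Covers the arabinose catabolic operon (araB/araD/araA), arabinose
#' transporters (araE permease, araFGH ABC system), the local and global
#' regulators, the alpha- and beta-L-arabinofuranosidases and
#' arabinanases, and the AOS transport systems.
#'
#' @return character vector of accepted role labels.
#' @export
subsystem_roles <- function() {
  c("araA", "araB", "araD", "araE", "araF", "araG", "araH", "araQ", "araU",
    "abfR", "aauR", "aauU1", "aauU2", "bauR1", "bauR2", "xsaR",
    "abfB2", "afuB-H1", "abfII_1", "abfII_2", "abnA1", "abnA2", "abfC",
    "abfBad", "abfA", "axh-d3", "abfA2", "axh-m23", "abfE1", "abfE2",
    "abfB", "xsa", "hypBA1", "hypBA2",
    "araNt", "araPt", "araQt", "aauA", "aauB", "aauC",
    "abfT1", "abfT2", "xsaT", "bauA", "bauB", "bauC", "bauT",
    "xosABC", "xynB")
}

## regulator roles and their TF families (used by local TF discovery)
TF_ROLE_FAMILY <- c(araQ = "LacI", araU = "ROK", abfR = "LacI", aauR = "LacI",
                    aauU1 = "LacI", aauU2 = "LacI", bauR1 = "LacI",
                    bauR2 = "LacI", xsaR = "TetR")

## roles encoding intracellular alpha-L-arabinofuranosidases (the catabolic
## half of the alpha-AOS pathway once the oligosaccharide is internalized)
INTRACELLULAR_ABF_ROLES <- c("abfB2", "afuB-H1", "abfII_1", "abfII_2",
                             "abfC", "abfBad", "abfB", "xsa")

## known arabinose/AOS transporter roles; a genome with araBDA but none of
## these is the transporter-less "unique" pattern.  xosABC is deliberately
## excluded: it is a xylo-oligosaccharide uptake system and only supports
## the advisory AXOS route, not a recognized arabinose/AOS transporter.
TRANSPORTER_ROLES <- c("araE", "araF", "araG", "araH",
                       "araNt", "araPt", "araQt", "aauA", "aauB", "aauC",
                       "abfT1", "abfT2", "xsaT", "bauA", "bauB", "bauC",
                       "bauT")

#' Populate the arabinose/AOS subsystem across genomes
#'
#' Projects annotated functional roles into a genome x role presence
#' matrix with the supporting gene id recorded per cell.
#'
#' @param genomes list of [genome()] objects whose gene tables carry a
#'   `role` column (NA for genes outside the subsystem; TF-family labels
#'   `LacI`/`TetR`/`ROK` are accepted as generic regulator annotations and
#'   ignored here).
#' @return list with `presence` (logical genome x role matrix) and
#'   `genes` (data frame genome_id, role, gene_id).
#' @export
populate_subsystem <- function(genomes) {
  roles <- subsystem_roles()
  gids <- vapply(genomes, function(g) g$genome_id, character(1))
  rows <- list()
  for (g in genomes) {
    tab <- g$genes[!is.na(g$genes$role), c("gene_id", "role"), drop = FALSE]
    tab <- tab[!tab$role %in% c("LacI", "TetR", "ROK"), , drop = FALSE]
    unknown <- setdiff(unique(tab$role), roles)
    if (length(unknown))
      stopf("genome '%s': role(s) outside the subsystem vocabulary: %s",
            g$genome_id, paste(unknown, collapse = ", "))
    dup <- tab$gene_id[duplicated(tab$gene_id)]
    if (length(dup))
      stopf("genome '%s': conflicting role assignments for gene(s): %s",
            g$genome_id, paste(unique(dup), collapse = ", "))
    if (nrow(tab))
      rows[[length(rows) + 1L]] <- data.frame(genome_id = g$genome_id,
                                              role = tab$role,
                                              gene_id = tab$gene_id,
                                              stringsAsFactors = FALSE)
  }
  genes <- if (length(rows)) do.call(rbind, rows)
           else data.frame(genome_id = character(0), role = character(0),
                           gene_id = character(0), stringsAsFactors = FALSE)
  presence <- matrix(FALSE, length(gids), length(roles),
                     dimnames = list(gids, roles))
  if (nrow(genes)) presence[cbind(genes$genome_id, genes$role)] <- TRUE
  list(presence = presence, genes = genes)
}

has_all <- function(row, roles) all(row[roles])
has_any <- function(row, roles) any(row[roles])

#' Assign an arabinose/AOS utilization phenotype from a role row
#'
#' Pure function of role presence:
#' * `U1` (arabinose): araB+araD+araA catabolic genes and an arabinose
#'   transporter (araE, or the complete araFGH ABC system).
#' * `U2` (alpha-AOS): araBDA, at least one alpha-AOS uptake system
#'   (complete araNt/araPt/araQt, complete aauABC, abfT1, abfT2 or xsaT)
#'   and at least one intracellular alpha-L-arabinofuranosidase.
#' * `U3` (beta-AOS): araBDA, a beta-AOS transporter (complete bauABC or
#'   bauT) and the intracellular beta-L-arabinofuranosidase hypBA1.
#' * composite `"0"` when no label applies and araBDA is absent or
#'   incomplete; `"unique"` when araBDA is present but the genome has no
#'   transporter role at all (arabinose release must then come from an
#'   intracellular route, e.g. AXOS imported via xosABC).
#'
#' Adding roles can never remove a label (the rule set is monotone).
#'
#' @param row logical vector named by [subsystem_roles()] (one genome's row
#'   of the presence matrix).
#' @param completeness_frac fraction of subunits of a multi-subunit
#'   transporter that must be present for it to count (default 1: strict).
#' @return list of class `phenotype_call`: `labels` (subset of U1/U2/U3),
#'   `composite` (`"U1"`, `"U12"`, ..., `"0"` or `"unique"`), `evidence`
#'   (role sets satisfied per label) and `axos_route_possible` (advisory
#'   flag for the xosABC/abfA alternative arabinose route).
#' @export
assign_phenotype <- function(row, completeness_frac = 1) {
  roles <- subsystem_roles()
  if (is.null(names(row)) || !all(roles %in% names(row)))
    stopf("row must be a logical vector named by subsystem_roles()")
  row <- as.logical(row[roles]); names(row) <- roles
  complete <- function(sub) mean(row[sub]) >= completeness_frac
  ara_cat <- has_all(row, c("araB", "araD", "araA"))
  labels <- character(0); evidence <- list()
  if (ara_cat && (row["araE"] || complete(c("araF", "araG", "araH")))) {
    labels <- c(labels, "U1")
    evidence$U1 <- c("araB", "araD", "araA",
                     if (row["araE"]) "araE" else c("araF", "araG", "araH"))
  }
  alpha_uptake <- complete(c("araNt", "araPt", "araQt")) ||
    complete(c("aauA", "aauB", "aauC")) ||
    row["abfT1"] || row["abfT2"] || row["xsaT"]
  if (ara_cat && alpha_uptake && has_any(row, INTRACELLULAR_ABF_ROLES)) {
    labels <- c(labels, "U2")
    evidence$U2 <- c("araB", "araD", "araA",
                     names(row)[row & names(row) %in%
                                  c("araNt", "araPt", "araQt", "aauA", "aauB",
                                    "aauC", "abfT1", "abfT2", "xsaT",
                                    INTRACELLULAR_ABF_ROLES)])
  }
  if (ara_cat && (complete(c("bauA", "bauB", "bauC")) || row["bauT"]) &&
      row["hypBA1"]) {
    labels <- c(labels, "U3")
    evidence$U3 <- c("araB", "araD", "araA", "hypBA1",
                     names(row)[row & names(row) %in% c("bauA", "bauB", "bauC", "bauT")])
  }
  composite <- if (length(labels)) {
    paste0("U", paste(sort(as.integer(sub("U", "", labels))), collapse = ""))
  } else if (ara_cat && !has_any(row, TRANSPORTER_ROLES)) {
    "unique"
  } else "0"
  structure(list(labels = sort(labels), composite = composite,
                 evidence = evidence,
                 axos_route_possible = ara_cat && row["xosABC"] &&
                   (row["abfA"] || row["xynB"])),
            class = "phenotype_call")
}

#' @export
print.phenotype_call <- function(x, ...) {
  cat(sprintf("<phenotype> %s%s\n", x$composite,
              if (x$axos_route_possible) " [AXOS-route possible]" else ""))
  invisible(x)
}

#' Phenotype calls for every genome of a populated subsystem
#'
#' @param subsystem output of [populate_subsystem()].
#' @inheritParams assign_phenotype
#' @return data frame: `genome_id`, `U1`, `U2`, `U3` (logical),
#'   `composite`, `axos_route_possible`.
#' @export
assign_phenotypes <- function(subsystem, completeness_frac = 1) {
  calls <- lapply(rownames(subsystem$presence), function(g)
    assign_phenotype(subsystem$presence[g, ], completeness_frac))
  data.frame(genome_id = rownames(subsystem$presence),
             U1 = vapply(calls, function(x) "U1" %in% x$labels, logical(1)),
             U2 = vapply(calls, function(x) "U2" %in% x$labels, logical(1)),
             U3 = vapply(calls, function(x) "U3" %in% x$labels, logical(1)),
             composite = vapply(calls, function(x) x$composite, character(1)),
             axos_route_possible = vapply(calls, function(x) x$axos_route_possible, logical(1)),
             stringsAsFactors = FALSE)
}

#' Concordance between predicted arabinose phenotypes and fermentation data
#'
#' A genome matches when the predicted ability to utilize arabinose
#' (label U1) agrees with the fermentation call (`"+"`/`"-"`).
#'
#' @param calls data frame from [assign_phenotypes()] (needs `genome_id`
#'   and `U1`).
#' @param fermentation named character vector (`"+"` or `"-"`) keyed by
#'   genome id.
#' @return list `n_match`, `n_total`, `fraction`.
#' @export
concordance <- function(calls, fermentation) {
  common <- intersect(calls$genome_id, names(fermentation))
  if (!length(common)) stopf("no genomes shared between calls and fermentation data")
  pred <- stats::setNames(calls$U1, calls$genome_id)[common]
  obs <- fermentation[common] == "+"
  n_match <- sum(pred == obs)
  list(n_match = n_match, n_total = length(common),
       fraction = n_match / length(common))
}

#' Write the subsystem matrix / phenotype table as TSV
#'
#' @param subsystem output of [populate_subsystem()].
#' @param path output file.
#' @export
write_subsystem_tsv <- function(subsystem, path) {
  m <- subsystem$presence
  gene_lookup <- split(subsystem$genes$gene_id,
                       paste(subsystem$genes$genome_id, subsystem$genes$role))
  out <- data.frame(genome_id = rownames(m), stringsAsFactors = FALSE)
  for (r in colnames(m)) {
    out[[r]] <- vapply(rownames(m), function(g) {
      ids <- gene_lookup[[paste(g, r)]]
      if (is.null(ids)) "0" else paste(ids, collapse = ",")
    }, character(1))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_subsystem_tsv
#' @param calls data frame from [assign_phenotypes()].
#' @export
write_phenotype_tsv <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
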