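#' Spearman rank correlation
#'
#' Pearson correlation of average-fractional ranks (ties get the average
#' rank). Returns `NA` (not 0) when either ranked vector has zero variance.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return rho in [-1, 1], or `NA_real_`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  stats::cor(rx, ry)
}

#' Correlate one gene's read counts with every species' abundance
#'
#' Overall mode uses all aligned samples. Conditional mode restricts to the
#' samples in which the gene was detected (read count > 0) — the natural
#' test for accessory genes, which are absent from some strains but should
#' track their species where present. With fewer than `min_detected`
#' detected samples the conditional result is all-`NA` with a warning.
#'
#' @param gene_counts named numeric vector of per-sample read counts.
#' @param species_relabund [abund_matrix()] of kind `species_relabund`
#'   sharing `gene_counts`' samples.
#' @param conditional logical; restrict to detected samples?
#' @param min_detected minimum detected samples for the conditional test.
#' @return named numeric vector of Spearman rho per species (NA where
#'   undefined).
#' @export
correlate_gene <- function(gene_counts, species_relabund, conditional = FALSE,
                           min_detected = 5L) {
  samp <- colnames(species_relabund)
  if (is.null(names(gene_counts)) || !setequal(names(gene_counts), samp)) {
    stop("gene_counts samples must match the species matrix")
  }
  gene_counts <- gene_counts[samp]
  out <- stats::setNames(rep(NA_real_, nrow(species_relabund)),
                         rownames(species_relabund))
  if (conditional) {
    keep <- gene_counts > 0
    if (sum(keep) < min_detected) {
      warning("conditional test skipped: gene detected in ", sum(keep),
              " < ", min_detected, " samples")
      return(out)
    }
    gene_counts <- gene_counts[keep]
    species_relabund <- species_relabund[, keep, drop = FALSE]
  }
  if (length(gene_counts) < 3L) return(out)
  for (sp in rownames(species_relabund)) {
    out[sp] <- spearman_rho(gene_counts, unclass(species_relabund)[sp, ])
  }
  out
}

#' Rank species by descending correlation
#'
#' Competition ("min") ranks: tied rho values share the smallest rank of the
#' tie group; within a tie, species are listed lexicographically so the
#' output is deterministic. `NA` rho values are excluded.
#'
#' @param rho named numeric vector as from [correlate_gene()].
#' @return data.frame `species_id`, `rho`, `rank` (possibly 0 rows).
#' @export
rank_species <- function(rho) {
  keep <- !is.na(rho)
  rho <- rho[keep]
  if (!length(rho)) {
    return(data.frame(species_id = character(), rho = numeric(),
                      rank = integer(), stringsAsFactors = FALSE))
  }
  ord <- order(-rho, names(rho))
  rho <- rho[ord]
  rnk <- rank(-rho, ties.method = "min")
  data.frame(species_id = names(rho), rho = unname(rho), rank = as.integer(rnk),
             stringsAsFactors = FALSE)
}

# lineage of one species as a named character(7); error when absent
.get_lineage <- function(lineages, species_id) {
  i <- match(species_id, lineages$species_id)
  if (is.na(i)) stop("species not in taxonomy table: ", species_id)
  unlist(lineages[i, LINEAGE_RANKS])
}

#' Best correlation rank with a matching lineage
#'
#' The smallest rank in the ranked species list whose lineage matches the
#' pangenome species' lineage at `level` (`family` or `species`). For a
#' non-contaminant gene this is typically 1 (the species itself, or a
#' family member, correlates best); a large value means the gene's signal
#' tracks foreign taxa.
#'
#' @param ranked data.frame from [rank_species()].
#' @param lineages taxonomy table from [read_lineage()].
#' @param pangenome_species species ID the gene is catalogued under.
#' @param level `"family"` or `"species"`.
#' @return integer rank, or `NA_integer_` if no species in the list matches.
#' @export
lineage_match_rank <- function(ranked, lineages, pangenome_species,
                               level = c("family", "species")) {
  level <- match.arg(level)
  target <- .get_lineage(lineages, pangenome_species)[[level]]
  if (!nzchar(target)) stop("pangenome species ", pangenome_species,
                            " has an empty ", level, " rank")
  if (!nrow(ranked)) return(NA_integer_)
  vals <- lineages[[level]][match(ranked$species_id, lineages$species_id)]
  hit <- which(!is.na(vals) & vals == target)
  if (!length(hit)) return(NA_integer_) else ranked$rank[hit[1]]
}

#' Correlation lineage test over a set of significant genes
#'
#' For each gene, read counts are Spearman-correlated with every species'
#' relative abundance; species are ranked by descending correlation; and
#' the best rank whose lineage matches the gene's pangenome species is
#' reported at both family and species level, for the overall and the
#' conditional (detected-samples-only) variants. Genes whose overall
#' family-match rank exceeds `flag_rank` — or that have no family match at
#' all (treated as worse than any finite rank) — are flagged as putative
#' contaminants.
#'
#' @param gene_ids character vector of genes to test.
#' @param gene_reads [abund_matrix()] of kind `gene_reads` containing them.
#' @param species_relabund [abund_matrix()] of kind `species_relabund`.
#' @param lineages taxonomy table from [read_lineage()].
#' @param pangenome_map data.frame from [read_pangenome_map()].
#' @param flag_rank family-rank threshold above which a gene is flagged.
#' @param min_detected passed to [correlate_gene()].
#' @return data.frame, one row per gene: pangenome species, top correlated
#'   species and rho, family/species match ranks (overall and conditional),
#'   sample counts, `flagged`.
#' @export
run_lineage_test <- function(gene_ids, gene_reads, species_relabund, lineages,
                             pangenome_map, flag_rank = 50L, min_detected = 5L) {
  aligned <- align_samples(list(gene_reads, species_relabund),
                           data.frame(sample_id = colnames(species_relabund),
                                      group = "case", stringsAsFactors = FALSE))
  gene_reads <- aligned[[1]]; species_relabund <- aligned[[2]]
  missing_genes <- setdiff(gene_ids, rownames(gene_reads))
  if (length(missing_genes)) {
    stop("gene(s) absent from the reads matrix: ",
         paste(missing_genes, collapse = ", "))
  }
  rows <- lapply(gene_ids, function(g) {
    sp <- pangenome_map$species_id[match(g, pangenome_map$gene_id)]
    if (is.na(sp)) stop("gene not in pangenome map: ", g)
    counts <- unclass(gene_reads)[g, ]
    rho_all <- correlate_gene(counts, species_relabund, conditional = FALSE)
    rho_con <- suppressWarnings(
      correlate_gene(counts, species_relabund, conditional = TRUE,
                     min_detected = min_detected))
    rk_all <- rank_species(rho_all)
    rk_con <- rank_species(rho_con)
    fam <- lineage_match_rank(rk_all, lineages, sp, "family")
    spc <- lineage_match_rank(rk_all, lineages, sp, "species")
    famc <- lineage_match_rank(rk_con, lineages, sp, "family")
    spcc <- lineage_match_rank(rk_con, lineages, sp, "species")
    data.frame(
      gene_id = g, pangenome_species = sp,
      top_corr_species = if (nrow(rk_all)) rk_all$species_id[1] else NA_character_,
      top_rho = if (nrow(rk_all)) rk_all$rho[1] else NA_real_,
      family_rank = fam, species_rank = spc,
      family_rank_conditional = famc, species_rank_conditional = spcc,
      n_samples_total = length(counts),
      n_samples_detected = sum(counts > 0),
      flagged = is.na(fam) || fam > flag_rank,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
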