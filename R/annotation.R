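#' Look up a gene's EggNOG annotation via its UHGP-90 cluster
#'
#' @param gene_id gene to annotate.
#' @param pangenome_map data.frame from [read_pangenome_map()] (must carry
#'   `uhgp90_cluster_id`).
#' @param annotations data.frame from [read_annotations()].
#' @return list `tax_scope`, `predicted_name`, `description` (each possibly
#'   `NA`); a gene without a UHGP-90 mapping or an unknown cluster yields
#'   all-`NA` (lookups never fail).
#' @export
annotate_gene <- function(gene_id, pangenome_map, annotations) {
  none <- list(tax_scope = NA_character_, predicted_name = NA_character_,
               description = NA_character_)
  cl <- pangenome_map$uhgp90_cluster_id[match(gene_id, pangenome_map$gene_id)]
  if (length(cl) != 1L || is.na(cl)) return(none)
  i <- match(cl, annotations$uhgp90_cluster_id)
  if (is.na(i)) return(none)
  list(tax_scope = annotations$eggnog_tax_scope[i],
       predicted_name = annotations$predicted_name[i],
       description = annotations$description[i])
}

#' Default taxon rule table for a Lachnospiraceae target
#'
#' Classifies EggNOG taxonomic scopes relative to the Lachnospiraceae:
#' scopes that cannot contain any Lachnospiraceae member are
#' contamination-indicating; scopes that do (or historically did, under
#' NCBI naming) contain Lachnospiraceae — including genus-level scopes
#' inside the family — are consistent; `Bacteria` is uninformative.
#'
#' @return data.frame `taxon`, `class` in
#'   `{contaminant, consistent, ambiguous}`.
#' @export
default_rule_table <- function() {
  path <- system.file("extdata", "rule_lachnospiraceae.tsv",
                      package = "pansift", mustWork = TRUE)
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    colClasses = "character", quote = "", comment.char = "")
}

#' Score an EggNOG taxonomic scope for lineage consistency
#'
#' Contamination-indicating scopes score 1, lineage-consistent scopes score
#' 0, and uninformative evidence — a missing annotation, a scope of
#' `Bacteria`, any scope classed ambiguous, or a scope absent from the rule
#' table (with a warning) — scores 0.5.
#'
#' @param tax_scope scope string, or `NA`.
#' @param rule_table data.frame `taxon`, `class`; default
#'   [default_rule_table()] (Lachnospiraceae target).
#' @return 0, 0.5 or 1.
#' @export
range_score <- function(tax_scope, rule_table = default_rule_table()) {
  if (is.na(tax_scope) || !nzchar(tax_scope) || tax_scope == "Bacteria") {
    return(0.5)
  }
  cls <- rule_table$class[match(tax_scope, rule_table$taxon)]
  if (is.na(cls)) {
    warning("taxon scope not in rule table, scored 0.5: ", tax_scope)
    return(0.5)
  }
  switch(cls, contaminant = 1, consistent = 0, ambiguous = 0.5,
         stop("invalid rule class: ", cls))
}
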