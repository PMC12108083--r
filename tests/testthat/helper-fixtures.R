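# in-code fixture builders shared across test files

toy_matrix <- function(values, kind, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- genes %||% sprintf("g%d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%d", seq_len(ncol(m)))
  abund_matrix(m, kind)
}

toy_metadata <- function(n_case, n_control) {
  data.frame(sample_id = sprintf("s%d", seq_len(n_case + n_control)),
             group = rep(c("case", "control"), c(n_case, n_control)),
             stringsAsFactors = FALSE)
}

toy_lineage <- function(species, family) {
  data.frame(species_id = species, domain = "Bacteria", phylum = "P",
             class = "C", order = "O", family = family,
             genus = paste0("g_", family), species = species,
             stringsAsFactors = FALSE)
}

# a fast, scaled-down scenario for tests that need the generator but not
# the full default size
small_scenario <- function(seed = 7L, ...) {
  defaults <- list(n_case = 30L, n_control = 30L, n_species = 8L,
                   n_families = 4L, genes_per_species = 12L,
                   n_contaminants = 3L, seed = seed)
  do.call(scenario_config, utils::modifyList(defaults, list(...)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
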