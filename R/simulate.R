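#' Scenario configuration for the synthetic community generator
#'
#' Describes a case/control metagenomic world with planted pangenome
#' contamination: species are assigned to families; the target family is
#' depleted in cases while a designated foreign-family source species is
#' enriched; each species carries core and accessory genes; and a chosen
#' number of genes in the target species' pangenome are contaminants whose
#' reads actually track the source species (the mis-binned-contig
#' scenario).
#'
#' @param n_case,n_control samples per group.
#' @param n_species number of species.
#' @param n_families number of families the species are spread over.
#' @param genes_per_species genes in each species' pangenome.
#' @param core_fraction fraction of each pangenome carried by every strain.
#' @param accessory_prob carriage probability of an accessory gene per
#'   sample.
#' @param n_contaminants planted contaminant genes in the target species'
#'   pangenome.
#' @param target_lfc log-fold depletion of the target family in cases
#'   (applied as -target_lfc to the case log-mean).
#' @param source_lfc log-fold enrichment of the source species in cases.
#' @param source_base_lfc baseline log-shift of the source species relative
#'   to the community average, applied to both groups. The default -2
#'   emulates the published scenario: the contamination source is a taxon
#'   that is rare in healthy controls (so the contaminant gene falls below
#'   the copy-number presence cutoff there) and enriched in cases.
#' @param sigma log-normal between-sample spread of species abundances.
#' @param depth expected sequencing reads per sample.
#' @param seed RNG seed.
#' @return a `scenario_config` list; validated.
#' @export
scenario_config <- function(n_case = 100L, n_control = 100L, n_species = 30L,
                            n_families = 4L, genes_per_species = 50L,
                            core_fraction = 0.5, accessory_prob = 0.6,
                            n_contaminants = 10L, target_lfc = 1,
                            source_lfc = 1.5, source_base_lfc = -2,
                            sigma = 1, depth = 1e6, seed = 42L) {
  cfg <- list(n_case = as.integer(n_case), n_control = as.integer(n_control),
              n_species = as.integer(n_species),
              n_families = as.integer(n_families),
              genes_per_species = as.integer(genes_per_species),
              core_fraction = core_fraction, accessory_prob = accessory_prob,
              n_contaminants = as.integer(n_contaminants),
              target_lfc = target_lfc, source_lfc = source_lfc,
              source_base_lfc = source_base_lfc,
              sigma = sigma, depth = depth, seed = as.integer(seed))
  with(cfg, {
    if (n_case <= 0 || n_control <= 0) stop("need samples in both groups")
    if (n_species < 2 || n_families < 2) stop("need >= 2 species and families")
    if (n_families > n_species) stop("more families than species")
    if (genes_per_species < 1) stop("need >= 1 gene per species")
    if (core_fraction < 0 || core_fraction > 1) stop("core_fraction in [0,1]")
    if (accessory_prob < 0 || accessory_prob > 1) stop("accessory_prob in [0,1]")
    if (n_contaminants < 0 || n_contaminants > genes_per_species) {
      stop("n_contaminants must be in [0, genes_per_species]")
    }
    if (depth <= 0) stop("depth must be positive")
    if (sigma <= 0) stop("sigma must be positive")
  })
  class(cfg) <- "scenario_config"
  cfg
}

#' Default validation scenario
#'
#' 200 samples (100 cases / 100 controls), 30 species in 4 families,
#' 50 genes per species, 10 planted contaminants in the target species'
#' pangenome sourced from a case-enriched foreign-family species, at
#' 10^6 reads per sample, seed 42.
#'
#' @return a [scenario_config()].
#' @export
default_scenario <- function() scenario_config()

# deterministic species/family bookkeeping for a config:
# species S01.. assigned round-robin to families F1..; species 1 is the
# contamination target (family F1), the source is the first species of F2
.scenario_layout <- function(config) {
  sp <- sprintf("S%02d", seq_len(config$n_species))
  fam <- sprintf("F%d", rep_len(seq_len(config$n_families), config$n_species))
  target <- sp[1]
  source <- sp[which(fam != fam[1])[1]]
  list(species = sp, family = fam, target_species = target,
       source_species = source)
}

#' Taxonomy table of the synthetic community
#'
#' @param config a [scenario_config()].
#' @return data.frame in the [read_lineage()] layout (seven ranks; family
#'   and species filled, higher ranks shared).
#' @export
simulate_lineage <- function(config) {
  lay <- .scenario_layout(config)
  data.frame(species_id = lay$species,
             domain = "Bacteria", phylum = "SynPhylum", class = "SynClass",
             order = "SynOrder", family = lay$family,
             genus = paste0("g_", lay$family),
             species = lay$species,
             stringsAsFactors = FALSE)
}

#' Simulate species relative abundances for cases and controls
#'
#' Per-sample species abundances are drawn log-normal around species-level
#' baselines, with the case group's log-mean shifted by `-target_lfc` for
#' every target-family species and `+source_lfc` for the source species,
#' then normalized so each sample sums to 1.
#'
#' @param config a [scenario_config()].
#' @return list: `species_relabund` ([abund_matrix()]), `metadata`
#'   (data.frame), `layout` (species/family assignment).
#' @export
simulate_community <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  lay <- .scenario_layout(config)
  n <- config$n_case + config$n_control
  samples <- sprintf("samp%03d", seq_len(n))
  group <- rep(c("case", "control"), c(config$n_case, config$n_control))
  base_mu <- stats::rnorm(config$n_species, mean = log(1 / config$n_species), sd = 0.5)
  base_mu[lay$species == lay$source_species] <- base_mu[lay$species == lay$source_species] +
    config$source_base_lfc
  lfc <- numeric(config$n_species)
  lfc[lay$family == lay$family[1]] <- -config$target_lfc
  lfc[lay$species == lay$source_species] <- config$source_lfc
  mu <- matrix(base_mu, config$n_species, n) +
    outer(lfc, as.numeric(group == "case"))
  raw <- matrix(stats::rlnorm(config$n_species * n, meanlog = mu,
                              sdlog = config$sigma),
                config$n_species, n)
  rel <- sweep(raw, 2, colSums(raw), "/")
  dimnames(rel) <- list(lay$species, samples)
  list(species_relabund = abund_matrix(rel, "species_relabund"),
       metadata = data.frame(sample_id = samples, group = group,
                             stringsAsFactors = FALSE),
       layout = lay)
}

#' Simulate gene read counts, copy numbers and presence with planted truth
#'
#' Every species gets `genes_per_species` genes (a core fraction carried in
#' all samples, the rest accessory with per-sample Bernoulli carriage). The
#' first `n_contaminants` accessory slots of the *target* species are
#' replaced by contaminant genes: they sit in the target pangenome but
#' their reads are generated from the *source* species' abundance —
#' exactly what a mis-binned contig produces. Observed reads are Poisson
#' with mean `depth x origin-species abundance x carriage`; copy number is
#' reads normalized by `depth x pangenome-species abundance` (so a
#' contaminant's copy number diverges when source and target move apart);
#' presence is reads > 0.
#'
#' @param community result of [simulate_community()].
#' @param config the same [scenario_config()].
#' @return list: `gene_reads`, `gene_copynum`, `gene_presence`
#'   ([abund_matrix()]s), `pangenome_map` (data.frame gene_id, species_id),
#'   `truth` (data.frame gene_id, pangenome_species, origin_species,
#'   is_contaminant, is_core).
#' @export
simulate_gene_reads <- function(community, config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed + 1L)
  rel <- unclass(community$species_relabund)
  lay <- community$layout
  n <- ncol(rel)
  g_per <- config$genes_per_species
  n_core <- round(config$core_fraction * g_per)

  gene_id <- character(0); pan_sp <- character(0); origin <- character(0)
  is_core <- logical(0); contaminant <- logical(0)
  for (s in lay$species) {
    ids <- sprintf("%s_g%03d", s, seq_len(g_per))
    core <- seq_len(g_per) <= n_core
    contam <- rep(FALSE, g_per)
    if (s == lay$target_species && config$n_contaminants > 0) {
      # plant contaminants in accessory slots (or beyond core if few)
      slots <- which(!core)
      if (length(slots) < config$n_contaminants) slots <- seq_len(g_per)
      contam[slots[seq_len(config$n_contaminants)]] <- TRUE
    }
    gene_id <- c(gene_id, ids)
    pan_sp <- c(pan_sp, rep(s, g_per))
    org <- rep(s, g_per); org[contam] <- lay$source_species
    origin <- c(origin, org)
    is_core <- c(is_core, core & !contam)
    contaminant <- c(contaminant, contam)
  }
  m <- length(gene_id)
  carriage <- matrix(1, m, n)
  acc <- !is_core & !contaminant
  carriage[acc, ] <- stats::rbinom(sum(acc) * n, 1, config$accessory_prob)
  # contaminants behave like core genes of their source species: carried
  # wherever the source is
  lambda <- config$depth * rel[origin, , drop = FALSE] * carriage
  reads <- matrix(stats::rpois(m * n, lambda), m, n)
  dimnames(reads) <- list(gene_id, colnames(rel))
  copynum <- reads / (config$depth * rel[pan_sp, , drop = FALSE])
  presence <- (reads > 0) * 1
  list(
    gene_reads = abund_matrix(reads, "gene_reads"),
    gene_copynum = abund_matrix(copynum, "gene_copynum"),
    gene_presence = abund_matrix(presence, "gene_presence"),
    pangenome_map = data.frame(gene_id = gene_id, species_id = pan_sp,
                               uhgp90_cluster_id = NA_character_,
                               stringsAsFactors = FALSE),
    truth = data.frame(gene_id = gene_id, pangenome_species = pan_sp,
                       origin_species = origin, is_contaminant = contaminant,
                       is_core = is_core, stringsAsFactors = FALSE))
}

#' Run the full generator for a scenario
#'
#' @param config a [scenario_config()]; default [default_scenario()].
#' @return list combining [simulate_community()] and
#'   [simulate_gene_reads()] outputs plus `lineage`.
#' @export
simulate_scenario <- function(config = default_scenario()) {
  comm <- simulate_community(config)
  genes <- simulate_gene_reads(comm, config)
  c(comm["species_relabund"], comm["metadata"], list(layout = comm$layout),
    genes, list(lineage = simulate_lineage(config), config = config))
}
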