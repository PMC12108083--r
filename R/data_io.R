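#' Read sample metadata (case/control groups)
#'
#' @param path TSV with columns `sample_id`, `group` (values `case` or
#'   `control`) and optionally `subject_id`.
#' @return data.frame with one row per sample.
#' @export
read_metadata <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = "character", quote = "", comment.char = "")
  need <- c("sample_id", "group")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  validate_metadata(df)
}

validate_metadata <- function(df) {
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  bad <- setdiff(unique(df$group), c("case", "control"))
  if (length(bad)) stop("metadata group values must be case/control; got: ",
                        paste(bad, collapse = ", "))
  df
}

LINEAGE_RANKS <- c("domain", "phylum", "class", "order", "family", "genus", "species")

#' Read a species taxonomy table
#'
#' Accepts either wide form (columns `species_id` plus the seven ranks
#' `domain` ... `species`) or two columns `species_id`, `lineage` with a
#' GTDB-style semicolon-separated string (`d__...;p__...;...;s__...`).
#'
#' @param path TSV path.
#' @return data.frame: `species_id` plus seven rank columns (empty string
#'   where a rank is unassigned).
#' @export
read_lineage <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = "character", quote = "", comment.char = "")
  if (!"species_id" %in% names(df)) stop("taxonomy table needs a species_id column")
  if ("lineage" %in% names(df)) {
    parts <- strsplit(df$lineage, ";", fixed = TRUE)
    mat <- t(vapply(parts, function(p) {
      p <- sub("^[a-z]__", "", trimws(p))
      length(p) <- 7L
      p[is.na(p)] <- ""
      p
    }, character(7)))
    colnames(mat) <- LINEAGE_RANKS
    df <- data.frame(species_id = df$species_id, mat,
                     check.names = FALSE, stringsAsFactors = FALSE)
  }
  miss <- setdiff(LINEAGE_RANKS, names(df))
  if (length(miss)) stop("taxonomy table missing rank columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$species_id)) stop("duplicate species_id in taxonomy table")
  df[LINEAGE_RANKS][is.na(df[LINEAGE_RANKS])] <- ""
  df[c("species_id", LINEAGE_RANKS)]
}

#' Read a gene-to-pangenome map
#'
#' @param path TSV with columns `gene_id`, `species_id` and optionally
#'   `uhgp90_cluster_id`.
#' @return data.frame, one row per gene.
#' @export
read_pangenome_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = "character", quote = "", comment.char = "")
  need <- c("gene_id", "species_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("pangenome map missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$gene_id)) {
    stop("gene mapped to more than one pangenome species: ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  }
  if (!"uhgp90_cluster_id" %in% names(df)) df$uhgp90_cluster_id <- NA_character_
  df$uhgp90_cluster_id[!is.na(df$uhgp90_cluster_id) & df$uhgp90_cluster_id == ""] <- NA_character_
  df
}

#' Read a UHGP-90 cluster annotation table
#'
#' TSV or (if the arrow package is installed) Parquet, with columns
#' `uhgp90_cluster_id`, `eggnog_tax_scope`, `predicted_name`, `description`
#' (the latter three optional; absent or empty fields become `NA`).
#'
#' @param path file path; `.parquet` is dispatched to arrow.
#' @return data.frame keyed by `uhgp90_cluster_id`.
#' @export
read_annotations <- function(path) {
  if (grepl("\\.parquet$", path, ignore.case = TRUE)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("reading Parquet requires the 'arrow' package; ",
           "convert the table to TSV or install arrow")
    }
    df <- as.data.frame(arrow::read_parquet(path))
    df[] <- lapply(df, as.character)
  } else {
    df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                            colClasses = "character", quote = "", comment.char = "")
  }
  if (!"uhgp90_cluster_id" %in% names(df)) {
    stop("annotation table needs a uhgp90_cluster_id column")
  }
  for (col in c("eggnog_tax_scope", "predicted_name", "description")) {
    if (!col %in% names(df)) df[[col]] <- NA_character_
    df[[col]][!is.na(df[[col]]) & df[[col]] == ""] <- NA_character_
  }
  df[c("uhgp90_cluster_id", "eggnog_tax_scope", "predicted_name", "description")]
}

#' Restrict matrices to a common, metadata-covered sample set
#'
#' All returned matrices share the same sample order: the intersection of
#' every matrix's samples and the metadata's samples, in the relative order
#' of the first matrix. Samples dropped from any input are reported via
#' `message()`. MIDAS2 per-species matrices only contain samples passing
#' coverage, so intersection (not union) mirrors per-species varying n.
#'
#' @param matrices a list of [abund_matrix()] objects (length >= 1).
#' @param metadata data.frame as from [read_metadata()].
#' @return list of matrices restricted to the shared samples.
#' @export
align_samples <- function(matrices, metadata) {
  if (!length(matrices)) stop("need at least one matrix")
  common <- colnames(matrices[[1]])
  for (m in matrices[-1]) common <- intersect(common, colnames(m))
  common <- common[common %in% metadata$sample_id]
  if (!length(common)) stop("no samples shared by all matrices and metadata")
  all_samp <- unique(unlist(lapply(matrices, colnames)))
  dropped <- setdiff(all_samp, common)
  if (length(dropped)) {
    message("align_samples: dropped ", length(dropped), " sample(s): ",
            paste(utils::head(dropped, 10), collapse = ", "),
            if (length(dropped) > 10) ", ...")
  }
  lapply(matrices, function(m) m[, common, drop = FALSE])
}

#' Packaged cirrhosis case-study gene results
#'
#' An 86-gene table from a published case-control cirrhosis analysis of
#' Lachnospiraceae pangenomes: for each gene that was significantly
#' differentially prevalent between cirrhosis cases and controls, the number
#' of isolate and MAG genomes carrying it, its EggNOG taxonomic scope and
#' predicted protein name, the discrete-FDR q-value, the pangenome species,
#' the most-correlated species, the family- and species-level correlation
#' lineage ranks, and whether BLAST confirmed the gene as a contaminant.
#' This table is the package's reference evaluation set: every published
#' performance metric is recomputed from it by [evaluate_results()].
#'
#' @return data.frame with 86 rows; `fdr_q`, `n_isolate`, `n_mag`,
#'   `family_rank`, `species_rank` numeric, the rest character
#'   (empty annotation fields as `NA`).
#' @export
load_case_study <- function() {
  path <- system.file("extdata", "cirrhosis_gene_results.tsv",
                      package = "pansift", mustWork = TRUE)
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = "character", quote = "", comment.char = "")
  for (col in c("n_isolate", "n_mag", "family_rank", "species_rank", "fdr_q")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  for (col in c("eggnog_group", "eggnog_name", "notes")) {
    df[[col]][df[[col]] == ""] <- NA_character_
  }
  stopifnot(nrow(df) == 86L, all(df$blast_contam %in% c("yes", "no")),
            all(df$family_rank >= 1), all(df$species_rank >= 1),
            all(df$fdr_q > 0 & df$fdr_q <= 0.05))
  df
}
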