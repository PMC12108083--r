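#' Run the full contamination-flagging workflow
#'
#' Executes, in order: (1) differential prevalence (Fisher + discrete FDR)
#' of every gene, per pangenome species, with one pooled FDR adjustment;
#' (2) the correlation lineage test on the significant genes, flagging
#' putative contaminants; (3) EggNOG range scoring when annotations are
#' supplied; (4) for each species with >= 3 significant genes, the Jaccard
#' co-occurrence matrix, its clustered heatmap order, and 2-D ordinations.
#' All tables are written as TSV, figures as PNG, plus a static HTML report
#' and a machine-readable JSON run log.
#'
#' @param species_relabund [abund_matrix()] of kind `species_relabund`.
#' @param gene_reads [abund_matrix()] of kind `gene_reads`.
#' @param metadata data.frame as from [read_metadata()].
#' @param lineage taxonomy table as from [read_lineage()].
#' @param pangenome_map data.frame as from [read_pangenome_map()].
#' @param gene_presence optional [abund_matrix()] of kind `gene_presence`;
#'   when `NULL`, derived from `gene_copynum` at `presence_threshold`.
#' @param gene_copynum optional [abund_matrix()] of kind `gene_copynum`.
#' @param annotations optional data.frame from [read_annotations()].
#' @param rule_table taxon rule table for [range_score()].
#' @param outdir output directory (created if absent); `NULL` = no files.
#' @param alpha FDR level for significance.
#' @param presence_threshold copy-number presence cutoff.
#' @param flag_rank family-rank threshold for the contamination flag.
#' @param min_detected minimum detected samples for the conditional test.
#' @param ordination_methods subset of `c("NMDS", "PCoA", "UMAP")`.
#' @param seed RNG seed (ordinations).
#' @return list: `prevalence`, `lineage_test`, `cooccurrence` (per-species
#'   list of Jaccard + heatmap order + ordinations), `outdir`.
#' @export
run_pipeline <- function(species_relabund, gene_reads, metadata, lineage,
                         pangenome_map, gene_presence = NULL,
                         gene_copynum = NULL, annotations = NULL,
                         rule_table = default_rule_table(), outdir = NULL,
                         alpha = 0.05, presence_threshold = 0.35,
                         flag_rank = 50L, min_detected = 5L,
                         ordination_methods = c("NMDS", "PCoA"),
                         seed = 42L) {
  if (is.null(gene_presence)) {
    if (is.null(gene_copynum)) {
      stop("supply gene_presence or gene_copynum to derive it from")
    }
    gene_presence <- presence_from_copynum(gene_copynum, presence_threshold)
  }
  unmapped <- setdiff(rownames(gene_presence), pangenome_map$gene_id)
  if (length(unmapped)) {
    stop("genes missing from the pangenome map: ",
         paste(utils::head(unmapped, 5), collapse = ", "))
  }
  sp_of <- pangenome_map$species_id[match(rownames(gene_presence),
                                          pangenome_map$gene_id)]
  per_species <- lapply(split(rownames(gene_presence), sp_of),
                        function(g) gene_presence[g, , drop = FALSE])

  message("stage: differential prevalence")
  prev <- differential_prevalence(per_species, metadata, alpha = alpha)

  sig <- prev$gene_id[prev$significant]
  message("stage: correlation lineage test (", length(sig), " genes)")
  lin <- if (length(sig)) {
    run_lineage_test(sig, gene_reads, species_relabund, lineage,
                     pangenome_map, flag_rank = flag_rank,
                     min_detected = min_detected)
  } else {
    NULL
  }

  if (!is.null(lin) && !is.null(annotations)) {
    message("stage: annotation scoring")
    ann <- lapply(lin$gene_id, annotate_gene, pangenome_map = pangenome_map,
                  annotations = annotations)
    lin$eggnog_tax_scope <- vapply(ann, `[[`, character(1), "tax_scope")
    lin$eggnog_name <- vapply(ann, `[[`, character(1), "predicted_name")
    lin$range_score <- vapply(lin$eggnog_tax_scope, range_score,
                              numeric(1), rule_table = rule_table)
  }

  message("stage: co-occurrence / ordination")
  cooc <- list()
  if (!is.null(lin)) {
    for (sp in unique(lin$pangenome_species)) {
      genes <- lin$gene_id[lin$pangenome_species == sp]
      if (length(genes) < 3L) {
        message("species ", sp, ": ", length(genes),
                " significant gene(s) < 3, skipping co-occurrence")
        next
      }
      jm <- jaccard_matrix(gene_presence[genes, , drop = FALSE])
      ords <- lapply(ordination_methods, function(m) {
        ordinate(jm$dissimilarity, method = m, seed = seed)
      })
      names(ords) <- ordination_methods
      cooc[[sp]] <- list(jaccard = jm, heatmap_order = heatmap_order(jm$similarity),
                         ordinations = ords)
    }
  }

  res <- list(prevalence = prev, lineage_test = lin, cooccurrence = cooc,
              outdir = outdir)
  if (!is.null(outdir)) {
    write_report_bundle(res, outdir, config = list(
      alpha = alpha, presence_threshold = presence_threshold,
      flag_rank = flag_rank, min_detected = min_detected,
      ordination_methods = ordination_methods, seed = seed))
  }
  res
}

# TSV/figure/HTML/log emission for a pipeline result
write_report_bundle <- function(res, outdir, config = list()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  tsv(res$prevalence, "prevalence.tsv")
  if (!is.null(res$lineage_test)) tsv(res$lineage_test, "lineage_test.tsv")
  for (sp in names(res$cooccurrence)) {
    cc <- res$cooccurrence[[sp]]
    utils::write.table(cc$jaccard$similarity,
                       file.path(outdir, paste0("jaccard_", sp, ".tsv")),
                       sep = "\t", quote = FALSE)
    for (m in names(cc$ordinations)) {
      o <- cc$ordinations[[m]]
      df <- data.frame(gene_id = rownames(o$coords), o$coords,
                       stringsAsFactors = FALSE)
      if (!is.null(o$stress)) df$stress <- o$stress
      tsv(df, paste0("ordination_", sp, "_", m, ".tsv"))
    }
    # figures: clustered similarity heatmap + first ordination scatter
    ord_ids <- cc$heatmap_order
    grDevices::png(file.path(outdir, paste0("heatmap_", sp, ".png")),
                   width = 720, height = 720)
    graphics::image(cc$jaccard$similarity[ord_ids, rev(ord_ids)],
                    axes = FALSE, main = paste("Jaccard similarity:", sp),
                    col = grDevices::hcl.colors(64, "viridis"))
    grDevices::dev.off()
    o1 <- cc$ordinations[[1]]
    grDevices::png(file.path(outdir, paste0("ordination_", sp, ".png")),
                   width = 720, height = 720)
    graphics::plot(o1$coords, main = paste0(names(cc$ordinations)[1], ": ", sp),
                   xlab = "axis 1", ylab = "axis 2", pch = 19)
    graphics::text(o1$coords, labels = rownames(o1$coords), pos = 3, cex = 0.6)
    grDevices::dev.off()
  }
  write_html_report(res, outdir)
  write_run_log(outdir, config)
  invisible(outdir)
}

html_table <- function(df, max_rows = 500L) {
  df <- utils::head(df, max_rows)
  esc <- function(x) gsub("<", "&lt;", gsub("&", "&amp;", as.character(x)))
  head_row <- paste0("<tr>", paste0("<th>", esc(names(df)), "</th>",
                                    collapse = ""), "</tr>")
  body <- apply(df, 1, function(r) {
    paste0("<tr>", paste0("<td>", esc(r), "</td>", collapse = ""), "</tr>")
  })
  paste0("<table border='1' cellspacing='0' cellpadding='3'>\n",
         head_row, "\n", paste(body, collapse = "\n"), "\n</table>")
}

write_html_report <- function(res, outdir) {
  sig <- res$prevalence[res$prevalence$significant, , drop = FALSE]
  parts <- c(
    "<html><head><title>pansift report</title></head><body>",
    "<h1>pansift contamination report</h1>",
    sprintf("<p>%d genes tested; %d significant; %s flagged as putative contaminants.</p>",
            nrow(res$prevalence), nrow(sig),
            if (is.null(res$lineage_test)) "0" else sum(res$lineage_test$flagged)),
    "<h2>1. Differentially prevalent genes</h2>", html_table(sig),
    "<h2>2. Correlation lineage test</h2>",
    if (is.null(res$lineage_test)) "<p>no significant genes</p>"
    else html_table(res$lineage_test))
  for (sp in names(res$cooccurrence)) {
    parts <- c(parts,
               sprintf("<h2>3. Co-occurrence: %s</h2>", sp),
               sprintf("<img src='heatmap_%s.png' width='480'>", sp),
               sprintf("<h2>4. Ordination: %s</h2>", sp),
               sprintf("<img src='ordination_%s.png' width='480'>", sp))
  }
  parts <- c(parts, "</body></html>")
  writeLines(parts, file.path(outdir, "report.html"))
}

write_run_log <- function(outdir, config) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE)
  tmp <- tempfile(); writeLines(cfg_json, tmp); on.exit(unlink(tmp))
  log <- list(
    package = "pansift",
    package_version = as.character(utils::packageVersion("pansift")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config = config,
    config_md5 = unname(tools::md5sum(tmp)))
  jsonlite::write_json(log, file.path(outdir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}
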