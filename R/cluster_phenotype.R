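#' Pearson correlation distance between gene copy-number profiles
#'
#' d(g, h) = 1 - cor(g, h), so perfectly correlated genes are at distance
#' 0 and anti-correlated genes at distance 2. A zero-variance gene has no
#' defined correlation; it is placed at distance 1 (the uncorrelated value)
#' to every other gene, with a warning.
#'
#' @param copynum [abund_matrix()] of kind `gene_copynum`, or any plain
#'   genes-by-samples numeric matrix (>= 2 genes, >= 3 samples).
#' @return symmetric gene-by-gene distance matrix, zero diagonal.
#' @export
correlation_distance <- function(copynum) {
  m <- unclass(as.matrix(copynum))
  if (nrow(m) < 2L || ncol(m) < 3L) stop("need >= 2 genes and >= 3 samples")
  sds <- apply(m, 1, stats::sd)
  flat <- sds == 0
  if (any(flat)) {
    warning("zero-variance gene(s) set to distance 1 from all others: ",
            paste(rownames(m)[flat], collapse = ", "))
  }
  cc <- suppressWarnings(stats::cor(t(m)))
  cc[is.na(cc)] <- 0
  D <- 1 - cc
  diag(D) <- 0
  D
}

#' Partitioning around medoids at a fixed k
#'
#' Classical PAM (deterministic BUILD initialization, then SWAP until no
#' improving swap), via `cluster::pam` on the precomputed dissimilarity.
#'
#' @param D square dissimilarity matrix with dimnames.
#' @param k number of clusters, `2 <= k < n`.
#' @return list: `clustering` (named integer vector), `medoids` (gene IDs),
#'   `k`, `cost` (sum of distances to assigned medoid), `asw` (average
#'   silhouette width).
#' @export
pam_cluster <- function(D, k) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (k < 2 || k >= n) stop("k must satisfy 2 <= k < n")
  fit <- cluster::pam(stats::as.dist(D), k = k, diss = TRUE,
                      variant = "original")
  cl <- fit$clustering
  cost <- sum(D[cbind(seq_len(n), match(fit$medoids, rownames(D))[cl])])
  list(clustering = cl, medoids = fit$medoids, k = k, cost = cost,
       asw = fit$silinfo$avg.width)
}

#' Select the number of clusters by average silhouette width
#'
#' Runs [pam_cluster()] for each k in `k_min:k_max` and returns the k with
#' the largest ASW (smallest k on ties), the full ASW curve, and the
#' winning model.
#'
#' @param D square dissimilarity matrix.
#' @param k_min,k_max scan range (default 2..25, capped at n - 1).
#' @return list: `k`, `asw` (named vector over the scan), `model`.
#' @export
select_k_by_asw <- function(D, k_min = 2L, k_max = 25L) {
  n <- nrow(as.matrix(D))
  if (n <= 3L) stop("need more than 3 genes to scan k")
  k_max <- min(k_max, n - 1L)
  ks <- seq.int(k_min, k_max)
  models <- lapply(ks, function(k) pam_cluster(D, k))
  asw <- vapply(models, `[[`, numeric(1), "asw")
  names(asw) <- ks
  best <- which.max(asw)  # which.max takes the first (smallest k) on ties
  list(k = ks[best], asw = asw, model = models[[best]])
}

#' Eigengene of a gene-cluster copy-number submatrix
#'
#' The first right-singular vector of the genes-by-samples submatrix: a
#' unit-norm per-sample summary profile of the cluster. The SVD sign is
#' arbitrary, so the sign is fixed to make the eigengene non-negatively
#' correlated with the mean per-sample profile of the cluster.
#'
#' @param X numeric matrix, genes x samples (>= 1 gene).
#' @return named numeric vector over samples, unit Euclidean norm.
#' @export
eigengene <- function(X) {
  X <- as.matrix(X)
  if (all(X == 0)) stop("all-zero submatrix has no eigengene")
  v <- svd(X, nu = 0, nv = 1)$v[, 1]
  m <- colMeans(X)
  if (sum(v * m) < 0) v <- -v
  stats::setNames(v / sqrt(sum(v^2)), colnames(X))
}

#' Cluster-phenotype association with eigengenes
#'
#' For each cluster with >= 3 genes (smaller clusters are discarded): the
#' eigengene is tested for a case/control difference with a two-sided
#' Wilcoxon rank-sum test (exact when both groups have <= 50 samples and no
#' ties, normal approximation with continuity correction otherwise);
#' p-values are Benjamini-Hochberg adjusted across the retained clusters
#' and called significant at `fdr`. Per gene, a quantitative case/control
#' enrichment is reported as the mean two-sample t-statistic over
#' `boot_reps` bootstrap resamples of the samples (a zero-variance gene in
#' a replicate contributes t = 0).
#'
#' @param model list from [pam_cluster()] or `select_k_by_asw()$model`.
#' @param copynum [abund_matrix()] of kind `gene_copynum`, genes matching
#'   the model, samples aligned with `metadata`.
#' @param metadata data.frame as from [read_metadata()].
#' @param fdr FDR level (default 0.05).
#' @param boot_reps bootstrap replicates for the per-gene t (default 500).
#' @param seed RNG seed for the bootstrap.
#' @return list: `clusters` (data.frame cluster_id, n_genes, wilcoxon_p,
#'   bh_q, significant, direction), `eigengenes` (sample x cluster matrix),
#'   `gene_t` (data.frame gene_id, cluster_id, mean_boot_t), `discarded`
#'   (cluster ids with < 3 genes).
#' @export
cluster_association <- function(model, copynum, metadata, fdr = 0.05,
                                boot_reps = 500L, seed = 1L) {
  mat <- unclass(align_samples(list(copynum), metadata)[[1]])
  grp <- metadata$group[match(colnames(mat), metadata$sample_id)]
  i_case <- which(grp == "case"); i_ctrl <- which(grp == "control")
  if (length(i_case) < 2 || length(i_ctrl) < 2) {
    stop("each group needs >= 2 samples")
  }
  cl <- model$clustering[rownames(mat)]
  if (anyNA(cl)) stop("model does not cover all genes in the matrix")
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= 3]
  discarded <- setdiff(names(sizes), keep)

  eg <- sapply(keep, function(k) eigengene(mat[cl == as.integer(k), , drop = FALSE]))
  exact_ok <- max(length(i_case), length(i_ctrl)) <= 50
  pvals <- apply(eg, 2, function(v) {
    suppressWarnings(stats::wilcox.test(v[i_case], v[i_ctrl],
                                        exact = exact_ok, correct = TRUE))$p.value
  })
  qvals <- stats::p.adjust(pvals, method = "BH")
  direction <- apply(eg, 2, function(v) {
    if (mean(v[i_case]) >= mean(v[i_ctrl])) "case" else "control"
  })
  clusters <- data.frame(cluster_id = as.integer(keep),
                         n_genes = as.integer(sizes[keep]),
                         wilcoxon_p = unname(pvals), bh_q = unname(qvals),
                         significant = unname(qvals <= fdr),
                         direction = unname(direction),
                         stringsAsFactors = FALSE)

  # per-gene mean bootstrap t: resample samples within each group
  set.seed(seed)
  tsum <- numeric(nrow(mat))
  for (r in seq_len(boot_reps)) {
    bc <- sample(i_case, replace = TRUE)
    bk <- sample(i_ctrl, replace = TRUE)
    xc <- mat[, bc, drop = FALSE]; xk <- mat[, bk, drop = FALSE]
    m1 <- rowMeans(xc); m2 <- rowMeans(xk)
    v1 <- apply(xc, 1, stats::var); v2 <- apply(xk, 1, stats::var)
    se <- sqrt(v1 / length(bc) + v2 / length(bk))
    t_r <- ifelse(se == 0, 0, (m1 - m2) / se)
    tsum <- tsum + t_r
  }
  gene_t <- data.frame(gene_id = rownames(mat),
                       cluster_id = as.integer(cl),
                       mean_boot_t = tsum / boot_reps,
                       stringsAsFactors = FALSE)
  list(clusters = clusters, eigengenes = eg, gene_t = gene_t,
       discarded = as.integer(discarded))
}

#' Select genes by free-text annotation match
#'
#' Case-insensitive substring filter on the EggNOG free-text description
#' (default pattern `"flag"`, selecting flagellar genes), plus any explicit
#' additions — the gene universe for a copy-number cluster analysis.
#'
#' @param pangenome_map data.frame from [read_pangenome_map()].
#' @param annotations data.frame from [read_annotations()].
#' @param pattern fixed substring to match (case-insensitive).
#' @param extra_genes gene IDs to include regardless of annotation.
#' @return character vector of gene IDs.
#' @export
select_genes_by_annotation <- function(pangenome_map, annotations,
                                       pattern = "flag",
                                       extra_genes = character()) {
  ann <- lapply(pangenome_map$gene_id, annotate_gene,
                pangenome_map = pangenome_map, annotations = annotations)
  desc <- vapply(ann, function(a) {
    paste(stats::na.omit(c(a$description, a$predicted_name)), collapse = " ")
  }, character(1))
  hit <- grepl(pattern, desc, fixed = FALSE, ignore.case = TRUE)
  union(pangenome_map$gene_id[hit], extra_genes)
}
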