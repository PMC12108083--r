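#' Jaccard similarity of gene presence/absence profiles
#'
#' J(g, h) = |samples with both| / |samples with either|. Genes that
#' co-occur because they sit on the same contig (or mobile element) — the
#' typical signature of a block of contaminant genes — form high-J blocks.
#' Computed only for species with >= 3 significant genes.
#'
#' A pair with an empty union (both genes absent everywhere) has undefined
#' similarity; it is set to 0 with a warning so that it cannot create
#' spurious clusters.
#'
#' @param presence [abund_matrix()] of kind `gene_presence`, rows restricted
#'   to one species' significant genes (>= 3 rows).
#' @return list with `similarity` (square matrix, unit diagonal) and
#'   `dissimilarity` (1 - similarity).
#' @export
jaccard_matrix <- function(presence) {
  if (matrix_kind(presence) != "gene_presence") {
    stop("`presence` must be an abund_matrix of kind gene_presence")
  }
  if (nrow(presence) < 3L) stop("need >= 3 genes (skip smaller species)")
  m <- unclass(presence)
  inter <- tcrossprod(m)
  tot <- rowSums(m)
  union <- outer(tot, tot, "+") - inter
  empty <- union == 0
  if (any(empty & upper.tri(empty))) {
    warning("gene pair(s) with empty union; Jaccard set to 0")
  }
  J <- ifelse(empty, 0, inter / pmax(union, 1))
  diag(J) <- 1
  dimnames(J) <- list(rownames(m), rownames(m))
  list(similarity = J, dissimilarity = 1 - J)
}

#' Heatmap leaf order for a Jaccard similarity matrix
#'
#' Hierarchical clustering of the rows of the *similarity* matrix under
#' Euclidean distance with complete linkage; returns the dendrogram leaf
#' order, which places co-occurring gene blocks contiguously.
#'
#' @param J square similarity matrix (as `$similarity` of [jaccard_matrix()]).
#' @return character vector of gene IDs in leaf order.
#' @export
heatmap_order <- function(J) {
  hc <- stats::hclust(stats::dist(J, method = "euclidean"), method = "complete")
  rownames(J)[hc$order]
}

#' Two-dimensional ordination of a gene dissimilarity matrix
#'
#' * `PCoA`: classical metric scaling ([stats::cmdscale()]); exact for
#'   Euclidean-embeddable distances.
#' * `NMDS`: Kruskal stress-1 minimization (vegan's `monoMDS`) from
#'   `n_starts` random starts under a fixed seed; the best (lowest-stress)
#'   solution is returned with stress on the 0-1 scale.
#' * `UMAP`: delegated to the Python `umap-learn` package (run through the
#'   `python` on `PATH`) on the precomputed distance matrix;
#'   `n_neighbors` must lie in `[2, ceiling(n/3)]` and `min_dist` in
#'   `[0.1, 0.9]`, mirroring the intended exploratory parameter ranges.
#'
#' @param D square symmetric dissimilarity matrix with dimnames.
#' @param method `"PCoA"`, `"NMDS"` or `"UMAP"`.
#' @param n_neighbors,min_dist UMAP parameters.
#' @param n_starts,max_iter NMDS parameters.
#' @param seed integer seed for the stochastic methods.
#' @return list: `method`, `coords` (n x 2, rownames = gene IDs), `seed`,
#'   plus `stress` (NMDS), `eigenvalues` (PCoA, descending) and
#'   `parameters`.
#' @export
ordinate <- function(D, method = c("PCoA", "NMDS", "UMAP"),
                     n_neighbors = NULL, min_dist = 0.1,
                     n_starts = 20L, max_iter = 300L, seed = 42L) {
  method <- match.arg(method)
  D <- as.matrix(D)
  n <- nrow(D)
  ids <- rownames(D)
  out <- list(method = method, seed = seed, parameters = list())
  if (method == "PCoA") {
    sc <- suppressWarnings(stats::cmdscale(stats::as.dist(D), k = 2, eig = TRUE))
    coords <- sc$points
    # degenerate inputs (e.g. all-identical profiles) can yield < 2
    # positive eigenvalues; pad with zero axes
    if (ncol(coords) < 2) {
      coords <- cbind(coords, matrix(0, n, 2 - ncol(coords)))
    }
    out$eigenvalues <- sort(sc$eig, decreasing = TRUE)
  } else if (method == "NMDS") {
    set.seed(seed)
    dd <- stats::as.dist(D)
    # first start from the default (metric scaling) configuration, then
    # random configurations; keep the lowest-stress solution
    best <- vegan::monoMDS(dd, k = 2, model = "global", maxit = max_iter)
    for (i in seq_len(max(0L, n_starts - 1L))) {
      y0 <- matrix(stats::rnorm(n * 2), n, 2)
      fit <- vegan::monoMDS(dd, y = y0, k = 2, model = "global",
                            maxit = max_iter)
      if (fit$stress < best$stress) best <- fit
    }
    coords <- best$points
    out$stress <- best$stress
    out$parameters <- list(n_starts = n_starts, max_iter = max_iter)
  } else {
    if (is.null(n_neighbors)) n_neighbors <- min(15L, ceiling(n / 3))
    nn_max <- ceiling(n / 3)
    if (n_neighbors < 2 || n_neighbors > nn_max) {
      stop("UMAP n_neighbors must be in [2, ", nn_max, "] (ceiling(n/3))")
    }
    if (min_dist < 0.1 || min_dist > 0.9) {
      stop("UMAP min_dist must be in [0.1, 0.9]")
    }
    coords <- .umap_python(D, n_neighbors, min_dist, seed)
    out$parameters <- list(n_neighbors = n_neighbors, min_dist = min_dist)
  }
  colnames(coords) <- c("axis1", "axis2")
  rownames(coords) <- ids
  if (!all(is.finite(coords))) stop("ordination produced non-finite coordinates")
  out$coords <- coords
  out
}

# run umap-learn on a precomputed distance matrix via the python on PATH
.umap_python <- function(D, n_neighbors, min_dist, seed) {
  din <- tempfile(fileext = ".tsv"); dout <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(din, dout)), add = TRUE)
  utils::write.table(D, din, sep = "\t", row.names = FALSE, col.names = FALSE)
  script <- sprintf(paste0(
    "import warnings, numpy as np\n",
    "warnings.filterwarnings('ignore')\n",
    "import umap\n",
    "D = np.loadtxt(%s, delimiter='\\t')\n",
    "emb = umap.UMAP(n_components=2, metric='precomputed', n_neighbors=%d,\n",
    "                min_dist=%f, random_state=%d).fit_transform(D)\n",
    "np.savetxt(%s, emb, delimiter='\\t')\n"),
    deparse(din), as.integer(n_neighbors), min_dist, as.integer(seed),
    deparse(dout))
  sf <- tempfile(fileext = ".py")
  on.exit(unlink(sf), add = TRUE)
  writeLines(script, sf)
  status <- system2("python", sf, stdout = FALSE, stderr = FALSE)
  if (status != 0 || !file.exists(dout)) {
    stop("UMAP failed: python with the umap-learn package must be on PATH")
  }
  as.matrix(utils::read.table(dout, sep = "\t"))
}
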