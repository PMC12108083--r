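test_that("correlation_distance has the expected geometry", {
  set.seed(6)
  g <- rnorm(10)
  m <- rbind(g, -g, 2 * g + 7, rnorm(10))
  rownames(m) <- c("a", "neg", "affine", "other")
  colnames(m) <- sprintf("s%d", 1:10)
  D <- correlation_distance(m)
  expect_equal(D["a", "a"], 0)
  expect_equal(D["a", "neg"], 2)
  expect_equal(D["a", "affine"], 0, tolerance = 1e-12)
  # zero-variance gene sits at distance 1 from everything, with a warning
  mf <- rbind(m, flat = rep(3, 10))
  expect_warning(Df <- correlation_distance(mf), "zero-variance")
  expect_true(all(Df["flat", setdiff(rownames(mf), "flat")] == 1))
})

test_that("pam_cluster recovers separated blobs and matches brute force", {
  set.seed(10)
  pts <- rbind(matrix(rnorm(10, 0, 0.3), 5), matrix(rnorm(10, 10, 0.3), 5))
  rownames(pts) <- sprintf("p%d", 1:10)
  D <- as.matrix(dist(pts))
  fit <- pam_cluster(D, 2)
  expect_identical(length(unique(fit$clustering[1:5])), 1L)
  expect_identical(length(unique(fit$clustering[6:10])), 1L)
  expect_false(fit$clustering[1] == fit$clustering[6])
  # toy n = 5 distance: total cost equals the exhaustive medoid optimum
  set.seed(13)
  for (i in 1:10) {
    x <- matrix(rnorm(10), 5, 2)
    D5 <- as.matrix(dist(x))
    dimnames(D5) <- list(sprintf("q%d", 1:5), sprintf("q%d", 1:5))
    expect_equal(pam_cluster(D5, 2)$cost, oracle_pam_cost(D5, 2),
                 tolerance = 1e-10)
  }
  # duplicated points always co-cluster
  xd <- rbind(c(0, 0), c(0, 0), c(5, 5), c(5.2, 5), c(9, 0))
  Dd <- as.matrix(dist(xd))
  dimnames(Dd) <- list(sprintf("d%d", 1:5), sprintf("d%d", 1:5))
  cld <- pam_cluster(Dd, 2)$clustering
  expect_equal(cld[["d1"]], cld[["d2"]])
  expect_error(pam_cluster(Dd, 5), "k must satisfy")
})

test_that("select_k_by_asw maximizes silhouette over the scan", {
  set.seed(20)
  pts <- rbind(matrix(rnorm(12, 0, 0.2), 6), matrix(rnorm(12, 6, 0.2), 6),
               matrix(rnorm(12, c(0, 12), 0.2), 6))
  rownames(pts) <- sprintf("p%d", 1:18)
  D <- as.matrix(dist(pts))
  sel <- select_k_by_asw(D, 2, 6)
  expect_equal(sel$k, 3L)
  expect_gt(max(sel$asw), 0.8)
  # ASW agrees with the hand silhouette formula on a 6-point toy set
  x6 <- matrix(c(0, 0, 0.5, 0, 4, 0, 4.5, 0, 8, 0, 8.5, 0), 6, 2, byrow = TRUE)
  rownames(x6) <- sprintf("t%d", 1:6)
  D6 <- as.matrix(dist(x6))
  fit <- pam_cluster(D6, 3)
  expect_equal(fit$asw, oracle_asw(D6, fit$clustering), tolerance = 1e-10)
  expect_error(select_k_by_asw(D6[1:3, 1:3]), "more than 3")
})

test_that("PAM cost never increases with extra medoids on the same data", {
  set.seed(25)
  x <- matrix(rnorm(24), 12, 2)
  rownames(x) <- sprintf("r%d", 1:12)
  D <- as.matrix(dist(x))
  costs <- vapply(2:6, function(k) pam_cluster(D, k)$cost, numeric(1))
  expect_true(all(diff(costs) <= 1e-9))
})

test_that("eigengene is the unit-norm first right-singular vector", {
  set.seed(30)
  # rank-1 matrix u v^T recovers v exactly
  v <- rnorm(8); v <- v / sqrt(sum(v^2)); if (mean(v) < 0) v <- -v
  u <- abs(rnorm(5))
  X <- u %*% t(v)
  colnames(X) <- sprintf("s%d", 1:8)
  expect_equal(unname(eigengene(X)), v, tolerance = 1e-8)
  # single gene: its own normalized profile
  g <- abs(rnorm(6)); names(g) <- sprintf("s%d", 1:6)
  expect_equal(eigengene(matrix(g, 1, dimnames = list("g", names(g)))),
               g / sqrt(sum(g^2)))
  # random matrix vs power-iteration oracle
  X2 <- matrix(abs(rnorm(40)), 5, 8,
               dimnames = list(sprintf("g%d", 1:5), sprintf("s%d", 1:8)))
  expect_equal(unname(eigengene(X2)), oracle_eigengene(X2), tolerance = 1e-6)
  expect_equal(sum(eigengene(X2)^2), 1, tolerance = 1e-12)
  # invariant (up to coordinates permuting) under row/column permutation
  pg <- sample(5); ps <- sample(8)
  e1 <- eigengene(X2)
  e2 <- eigengene(X2[pg, ps])
  expect_equal(e2, e1[ps], tolerance = 1e-9)
  expect_error(eigengene(matrix(0, 2, 3)), "all-zero")
})

test_that("cluster_association tests eigengenes and bootstraps gene t", {
  set.seed(40)
  md <- toy_metadata(40, 40)
  n <- 80
  grp_eff <- rep(c(3, 0), c(40, 40))
  # cluster A: 5 genes strongly shifted up in cases; cluster B: 5 null genes;
  # cluster C: 2 genes (must be discarded)
  mk <- function(k, eff) t(sapply(seq_len(k), function(i) abs(eff + rnorm(n))))
  mat <- rbind(mk(5, grp_eff), mk(5, 0), mk(2, 0))
  rownames(mat) <- sprintf("g%02d", 1:12)
  colnames(mat) <- md$sample_id
  cn <- abund_matrix(mat, "gene_copynum")
  model <- list(clustering = setNames(rep(1:3, c(5, 5, 2)), rownames(mat)))
  res <- cluster_association(model, cn, md, boot_reps = 200, seed = 99)
  expect_identical(res$discarded, 3L)
  expect_identical(nrow(res$clusters), 2L)
  c1 <- res$clusters[res$clusters$cluster_id == 1, ]
  expect_true(c1$significant)
  expect_identical(c1$direction, "case")
  # shifted genes have positive mean bootstrap t
  expect_true(all(res$gene_t$mean_boot_t[1:5] > 0))
  # eigengenes are unit norm
  expect_equal(unname(colSums(res$eigengenes^2)), rep(1, 2), tolerance = 1e-9)
  # determinism under a fixed seed
  res2 <- cluster_association(model, cn, md, boot_reps = 200, seed = 99)
  expect_identical(res$gene_t, res2$gene_t)
  # an eigengene with identical values across groups gives p = 1
  half <- abs(rnorm(40))
  sym <- matrix(rep(c(half, half), 4), 4, byrow = TRUE)
  rownames(sym) <- sprintf("h%d", 1:4); colnames(sym) <- md$sample_id
  res3 <- cluster_association(list(clustering = setNames(rep(1L, 4), rownames(sym))),
                              abund_matrix(sym, "gene_copynum"), md,
                              boot_reps = 10, seed = 1)
  expect_equal(res3$clusters$wilcoxon_p, 1)
})

test_that("mean bootstrap t stabilizes as replicates grow", {
  set.seed(50)
  md <- toy_metadata(20, 20)
  mat <- matrix(abs(rnorm(40 * 3, mean = rep(c(2, 1), c(20, 20)))), 3, 40,
                byrow = TRUE,
                dimnames = list(sprintf("g%d", 1:3), md$sample_id))
  cn <- abund_matrix(mat, "gene_copynum")
  model <- list(clustering = setNames(rep(1L, 3), rownames(mat)))
  spread <- function(reps, seeds) {
    ts <- vapply(seeds, function(s) {
      cluster_association(model, cn, md, boot_reps = reps, seed = s)$gene_t$mean_boot_t[1]
    }, numeric(1))
    sd(ts)
  }
  expect_lt(spread(400, 1:6), spread(25, 1:6))
})

test_that("select_genes_by_annotation filters free text case-insensitively", {
  pmap <- data.frame(gene_id = c("g1", "g2", "g3"), species_id = "sp",
                     uhgp90_cluster_id = c("C1", "C2", "C3"),
                     stringsAsFactors = FALSE)
  ann <- data.frame(uhgp90_cluster_id = c("C1", "C2", "C3"),
                    eggnog_tax_scope = NA_character_,
                    predicted_name = c("fliQ", NA, "tkt"),
                    description = c("FLAGellar hook protein", "transketolase",
                                    NA),
                    stringsAsFactors = FALSE)
  expect_identical(select_genes_by_annotation(pmap, ann, "flag"), "g1")
  expect_setequal(select_genes_by_annotation(pmap, ann, "flag",
                                             extra_genes = "g2"),
                  c("g1", "g2"))
})
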