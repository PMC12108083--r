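test_that("presence_from_copynum thresholds inclusively", {
  cn <- toy_matrix(matrix(c(0, 0.34, 0.35, 2.0), 1, 4), "gene_copynum")
  expect_equal(as.vector(unclass(presence_from_copynum(cn, 0.35))),
               c(0, 0, 1, 1))
  expect_equal(as.vector(unclass(presence_from_copynum(cn, 0))),
               c(1, 1, 1, 1))
  zero <- toy_matrix(matrix(0, 2, 3), "gene_copynum")
  expect_true(all(unclass(presence_from_copynum(zero)) == 0))
  expect_error(presence_from_copynum(cn, -1), "non-negative")
  expect_error(presence_from_copynum(toy_matrix(matrix(1, 1, 4), "gene_reads")),
               "gene_copynum")
})

test_that("two-sided Fisher p matches known values and the enumeration oracle", {
  expect_equal(fisher_two_sided(5, 5, 5, 5), 1.0)
  # 0/51 cases vs 20/77 controls (the FliW pattern)
  expect_lt(fisher_two_sided(0, 51, 20, 57), 1e-3)
  expect_equal(fisher_two_sided(0, 51, 20, 57),
               oracle_fisher_p(0, 51, 20, 57), tolerance = 1e-10)
  expect_equal(fisher_two_sided(10, 0, 0, 10),
               oracle_fisher_p(10, 0, 0, 10), tolerance = 1e-10)
  expect_error(fisher_two_sided(0, 0, 1, 1), "margins")
})

test_that("Fisher p is invariant under group swap and present/absent swap", {
  set.seed(11)
  for (i in 1:25) {
    cells <- as.integer(rmultinom(1, sample(6:40, 1), rep(0.25, 4)))
    a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
    if (a + b == 0 || c + d == 0) next
    p <- fisher_two_sided(a, b, c, d)
    expect_equal(p, fisher_two_sided(c, d, a, b), tolerance = 1e-12)
    if (a + c > 0 && b + d > 0) {
      expect_equal(p, fisher_two_sided(b, a, d, c), tolerance = 1e-12)
    }
  }
})

test_that("fisher_support enumerates the attainable p-values", {
  expect_equal(fisher_support(1, 1, 1), 1.0)
  expect_equal(fisher_support(5, 5, 5), oracle_fisher_support(5, 5, 5),
               tolerance = 1e-10)
  # support contains the p of every observable table, max element is 1
  for (k in c(0, 3, 7, 12)) {
    sup <- fisher_support(7, 5, k)
    expect_equal(max(sup), 1)
    for (a in max(0, k - 5):min(k, 7)) {
      p <- fisher_two_sided(a, 7 - a, k - a, 5 - (k - a))
      expect_true(any(abs(sup - p) < 1e-10))
    }
  }
})

test_that("discrete BH matches closed form, oracle, and dominates BH", {
  # all raw p = 1
  sup1 <- list(c(0.2, 1), c(0.5, 1), 1)
  expect_equal(discrete_fdr_adjust(rep(1, 3), sup1), rep(1, 3))
  # m = 1: q = F(p) for the only hypothesis
  s <- c(0.01, 0.3, 1)
  expect_equal(discrete_fdr_adjust(0.01, list(s)), 0.01)
  expect_equal(discrete_fdr_adjust(0.3, list(s)), 0.3)
  # 3 hypotheses with 3-point supports vs the literal step-up oracle
  sup3 <- list(c(0.02, 0.4, 1), c(0.05, 0.5, 1), c(0.01, 0.3, 1))
  p3 <- c(0.02, 0.5, 0.01)
  expect_equal(discrete_fdr_adjust(p3, sup3), oracle_dbh(p3, sup3),
               tolerance = 1e-12)
  # random small instances: equals oracle and never exceeds classical BH
  set.seed(21)
  for (i in 1:20) {
    m <- sample(2:6, 1)
    sups <- replicate(m, sort(unique(c(runif(sample(1:4, 1)), 1))),
                      simplify = FALSE)
    p <- vapply(sups, function(s) sample(s, 1), numeric(1))
    q <- discrete_fdr_adjust(p, sups)
    expect_equal(q, oracle_dbh(p, sups), tolerance = 1e-12)
    expect_true(all(q <= stats::p.adjust(p, "BH") + 1e-12))
    expect_true(all(q > 0 & q <= 1))
  }
})

test_that("rejection set is monotone in alpha", {
  set.seed(31)
  sups <- lapply(1:8, function(i) fisher_support(6, 6, sample(0:12, 1)))
  p <- vapply(sups, function(s) sample(s, 1), numeric(1))
  q <- discrete_fdr_adjust(p, sups)
  prev <- 0L
  for (alpha in c(0.01, 0.05, 0.1, 0.2, 0.5, 1)) {
    n_rej <- sum(q <= alpha)
    expect_gte(n_rej, prev)
    prev <- n_rej
  }
})

test_that("differential_prevalence tests every gene and flags real effects", {
  md <- toy_metadata(51, 77)
  set.seed(5)
  # 99 group-balanced genes + one with the 41/51 vs 37/77 pattern
  base <- t(sapply(1:99, function(i) {
    k <- sample(20:108, 1)
    pres <- rep(0, 128)
    pres[sample(128, k)] <- 1
    pres
  }))
  target <- c(rep(1, 41), rep(0, 10), rep(1, 37), rep(0, 40))
  mat <- rbind(base, target)
  pres <- toy_matrix(mat, "gene_presence",
                     genes = c(sprintf("null%02d", 1:99), "fliq_like"))
  res <- differential_prevalence(pres, md)
  row <- res[res$gene_id == "fliq_like", ]
  expect_identical(c(row$a, row$b, row$c, row$d), c(41L, 10L, 37L, 40L))
  expect_true(row$significant)
  # a gene present everywhere has p = 1, never significant
  allpres <- toy_matrix(matrix(1, 1, 128), "gene_presence", genes = "core")
  res2 <- differential_prevalence(allpres, md)
  expect_equal(res2$p_raw, 1)
  expect_false(res2$significant)
  # sorted by q then gene_id
  expect_false(is.unsorted(res$q))
})

test_that("label permutation on null data yields few rejections", {
  set.seed(9)
  mat <- matrix(rbinom(60 * 120, 1, 0.4), 60, 120)
  rownames(mat) <- sprintf("g%02d", 1:60)
  colnames(mat) <- sprintf("s%03d", 1:120)
  pres <- abund_matrix(mat, "gene_presence")
  n_sig <- vapply(1:8, function(i) {
    md <- data.frame(sample_id = colnames(mat),
                     group = sample(rep(c("case", "control"), 60)),
                     stringsAsFactors = FALSE)
    sum(differential_prevalence(pres, md)$significant)
  }, numeric(1))
  expect_lte(mean(n_sig), 0.05 * 60)
})
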