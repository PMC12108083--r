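# Independent oracles used to freeze expected values. Each is a separate
# code path from the implementation it checks.

# exhaustive two-sided Fisher p: enumerate all tables with fixed margins
# via stats::fisher.test (base R's independent implementation)
oracle_fisher_p <- function(a, b, c, d) {
  stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))$p.value
}

# attainable p-values by direct per-table enumeration
oracle_fisher_support <- function(n1, n2, k) {
  lo <- max(0, k - n2); hi <- min(k, n1)
  sort(unique(vapply(lo:hi, function(a) {
    oracle_fisher_p(a, n1 - a, k - a, n2 - (k - a))
  }, numeric(1))))
}

# O(n^2) pair-counting AUROC with ties credited 0.5
oracle_auroc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]; neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# discrete-BH step-up by literal evaluation of the rejection rule over a
# grid of candidate levels: q_j = smallest level at which j is rejected
oracle_dbh <- function(p_raw, supports) {
  m <- length(p_raw)
  Fi <- function(i, t) {
    s <- supports[[i]]
    ok <- s[s <= t]
    if (length(ok)) max(ok) else 0
  }
  S_at <- function(t) sum(vapply(seq_len(m), Fi, numeric(1), t = t))
  p_sorted <- sort(p_raw)
  S_sorted <- vapply(p_sorted, S_at, numeric(1))
  alphas <- sort(unique(pmin(1, S_sorted / seq_len(m))))
  reject_at <- function(alpha) {
    ks <- which(S_sorted <= seq_len(m) * alpha)
    if (!length(ks)) return(rep(FALSE, m))
    p_raw <= p_sorted[max(ks)]
  }
  vapply(seq_len(m), function(j) {
    for (a in alphas) if (reject_at(a)[j]) return(a)
    1
  }, numeric(1))
}

# brute-force optimal k-medoid cost: minimum over all medoid subsets
oracle_pam_cost <- function(D, k) {
  n <- nrow(D)
  best <- Inf
  for (med in utils::combn(n, k, simplify = FALSE)) {
    cost <- sum(apply(D[, med, drop = FALSE], 1, min))
    best <- min(best, cost)
  }
  best
}

# silhouette widths from the textbook formula
oracle_asw <- function(D, cl) {
  n <- nrow(D)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(cl == cl[i] & seq_len(n) != i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(cl), cl[i]),
                    function(g) mean(D[i, cl == g]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# dominant right-singular vector by power iteration on t(X) %*% X
oracle_eigengene <- function(X, iters = 2000) {
  G <- crossprod(X)
  v <- rep(1, ncol(X)) / sqrt(ncol(X))
  for (i in seq_len(iters)) {
    v <- G %*% v
    v <- v / sqrt(sum(v^2))
  }
  v <- unname(drop(v))
  if (sum(v * colMeans(X)) < 0) v <- -v
  v
}

# rank-then-Pearson Spearman oracle
oracle_spearman <- function(x, y) stats::cor(rank(x), rank(y))
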