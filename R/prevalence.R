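#' Derive a presence/absence matrix from copy numbers
#'
#' A gene is called present in a sample when its estimated copy number is at
#' or above `threshold`. The default 0.35 is the conventional MIDAS
#' copy-number presence cutoff; supply the MIDAS2 presence matrix directly
#' when available.
#'
#' @param copynum an [abund_matrix()] of kind `gene_copynum`.
#' @param threshold non-negative copy-number cutoff (inclusive).
#' @return an [abund_matrix()] of kind `gene_presence`.
#' @export
presence_from_copynum <- function(copynum, threshold = 0.35) {
  if (!inherits(copynum, "abund_matrix") || matrix_kind(copynum) != "gene_copynum") {
    stop("`copynum` must be an abund_matrix of kind gene_copynum")
  }
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0) {
    stop("`threshold` must be a single non-negative number")
  }
  pres <- (unclass(copynum) >= threshold) * 1
  abund_matrix(pres, "gene_presence")
}

# hypergeometric point probabilities of all tables with margins
# (n1 = a+b, n2 = c+d, k = a+c); returns probs indexed by a = lo..hi
.fisher_table_probs <- function(n1, n2, k) {
  lo <- max(0L, k - n2)
  hi <- min(k, n1)
  a <- lo:hi
  list(a = a, prob = stats::dhyper(a, n1, n2, k))
}

# relative tolerance when comparing table probabilities to the observed
# one; avoids float-order artifacts in the two-sided summation rule
.FISHER_REL_TOL <- 1e-7

#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' Classical convention: the p-value is the sum of hypergeometric
#' probabilities (margins fixed) of all tables no more probable than the
#' observed one, with a relative tolerance of 1e-7 on the comparison.
#'
#' @param a,b,c,d non-negative integer cell counts: present/absent in cases
#'   (`a`, `b`) and in controls (`c`, `d`).
#' @return p-value in (0, 1].
#' @export
fisher_two_sided <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers")
  }
  n1 <- a + b; n2 <- c + d
  if (n1 == 0 || n2 == 0) stop("both group margins must be positive")
  tp <- .fisher_table_probs(n1, n2, a + c)
  obs <- tp$prob[match(a, tp$a)]
  min(1, sum(tp$prob[tp$prob <= obs * (1 + .FISHER_REL_TOL)]))
}

#' Attainable two-sided Fisher p-values for fixed margins
#'
#' The support of the p-value under the null for a 2x2 table with `n_cases`
#' and `n_controls` group sizes and `k_present` total present calls. These
#' supports are the input to the discrete FDR adjustment.
#'
#' @param n_cases,n_controls positive group sizes.
#' @param k_present total number of samples in which the gene is present,
#'   between 0 and `n_cases + n_controls`.
#' @return sorted ascending numeric vector of attainable p-values; the
#'   largest element is 1.
#' @export
fisher_support <- function(n_cases, n_controls, k_present) {
  if (n_cases <= 0 || n_controls <= 0) stop("both group margins must be positive")
  if (k_present < 0 || k_present > n_cases + n_controls) {
    stop("k_present out of range")
  }
  tp <- .fisher_table_probs(n_cases, n_controls, k_present)
  ord <- order(tp$prob)
  p_sorted <- tp$prob[ord]
  cum <- cumsum(p_sorted)
  # p-value of the table with the j-th smallest prob = sum of probs <= it
  # (within tolerance); ties collapse to the same cumulative sum
  pvals <- vapply(seq_along(p_sorted), function(j) {
    cum[max(which(p_sorted <= p_sorted[j] * (1 + .FISHER_REL_TOL)))]
  }, numeric(1))
  sort(unique(pmin(pvals, 1)))
}

# F_i(t) = P(p_i <= t | H0) for a discrete support = largest attainable
# p-value <= t, or 0 when none is
.support_cdf <- function(support, t) {
  idx <- findInterval(t, support)
  c(0, support)[idx + 1L]
}

#' Discrete Benjamini-Hochberg step-up adjustment
#'
#' Non-adaptive discrete BH: with null CDFs \eqn{F_i} evaluated on the
#' attainable p-value supports of each (exact) test, the raw p-values are
#' replaced in the BH step-up by the surrogate \eqn{\sum_i F_i(p)}, i.e.
#' each hypothesis contributes its largest attainable p-value at or below
#' the candidate threshold (0 if none). Because \eqn{F_i(t) \le t}, the
#' adjusted values never exceed (and typically undercut) classical BH,
#' which is the power gain of exploiting discreteness.
#'
#' @param p_raw numeric vector of raw p-values.
#' @param supports list (same length) of sorted attainable-p vectors, as
#'   from [fisher_support()].
#' @return adjusted q-values in (0, 1], same order as `p_raw`.
#' @export
discrete_fdr_adjust <- function(p_raw, supports) {
  m <- length(p_raw)
  if (length(supports) != m) stop("one support per hypothesis required")
  if (m == 0L) return(numeric(0))
  ord <- order(p_raw)
  p_sorted <- p_raw[ord]
  # sum_i F_i(p_(k)) for every k; group identical supports for speed
  key <- vapply(supports, function(s) paste(s, collapse = ","), character(1))
  surr <- numeric(m)
  for (grp in split(seq_len(m), key)) {
    surr <- surr + length(grp) * .support_cdf(supports[[grp[1]]], p_sorted)
  }
  q_sorted <- rev(cummin(rev(pmin(1, surr / seq_len(m)))))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

#' Differentially prevalent genes between cases and controls
#'
#' Per gene: a 2x2 present/absent by case/control table, a two-sided Fisher
#' exact p-value, and a discrete-FDR adjusted q-value. Genes present (or
#' absent) in every sample are still tested (their only attainable p is 1).
#'
#' Pass a single presence matrix, or a named list of per-species presence
#' matrices. With a list, each species is tested over its own samples (the
#' intersection with `metadata`; MIDAS2 emits per-species sample sets) and,
#' by default, all genes of all species enter one joint FDR adjustment
#' (`pool_fdr = FALSE` adjusts within species instead).
#'
#' @param presence an [abund_matrix()] of kind `gene_presence`, or a named
#'   list of them (names = species IDs).
#' @param metadata data.frame as from [read_metadata()].
#' @param alpha FDR level for the `significant` flag.
#' @param method `"dbh"` (discrete BH, default) or `"bh"` (classical).
#' @param pool_fdr adjust across all species jointly (default `TRUE`).
#' @return data.frame: `gene_id`, `species_id`, `a`, `b`, `c`, `d`,
#'   `p_raw`, `q`, `significant`, sorted by `q` then `gene_id`.
#' @export
differential_prevalence <- function(presence, metadata, alpha = 0.05,
                                    method = c("dbh", "bh"), pool_fdr = TRUE) {
  method <- match.arg(method)
  if (inherits(presence, "abund_matrix")) presence <- list(`NA` = presence)
  if (is.null(names(presence))) stop("per-species presence list must be named")

  per_species <- lapply(names(presence), function(sp) {
    mat <- presence[[sp]]
    if (matrix_kind(mat) != "gene_presence") {
      stop("presence matrix for ", sp, " has kind ", matrix_kind(mat))
    }
    mat <- align_samples(list(mat), metadata)[[1]]
    grp <- metadata$group[match(colnames(mat), metadata$sample_id)]
    n_case <- sum(grp == "case"); n_ctrl <- sum(grp == "control")
    if (n_case == 0 || n_ctrl == 0) {
      stop("species ", sp, ": one of the groups has no samples")
    }
    a <- as.integer(rowSums(mat[, grp == "case", drop = FALSE]))
    cc <- as.integer(rowSums(mat[, grp == "control", drop = FALSE]))
    data.frame(gene_id = rownames(mat), species_id = sp,
               a = a, b = n_case - a, c = cc, d = n_ctrl - cc,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, per_species)
  res$p_raw <- mapply(fisher_two_sided, res$a, res$b, res$c, res$d)

  adjust <- function(d) {
    if (method == "bh") return(stats::p.adjust(d$p_raw, method = "BH"))
    sup <- mapply(function(a, b, c, cd) fisher_support(a + b, c + cd, a + c),
                  d$a, d$b, d$c, d$d, SIMPLIFY = FALSE)
    discrete_fdr_adjust(d$p_raw, sup)
  }
  if (pool_fdr) {
    res$q <- adjust(res)
  } else {
    res$q <- NA_real_
    for (sp in unique(res$species_id)) {
      i <- res$species_id == sp
      res$q[i] <- adjust(res[i, ])
    }
  }
  res$significant <- res$q <= alpha
  res <- res[order(res$q, res$gene_id), ]
  rownames(res) <- NULL
  res
}
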