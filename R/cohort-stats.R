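# Cohort-level utilities over per-eye parameter tables: tie-corrected
# Spearman correlation matrix, Wilcoxon rank-sum comparison (exact for small
# samples), and two-cluster variable clustering.

#' Spearman correlation matrix with p-values
#'
#' Pairwise Spearman rho with tie-corrected (average) ranks, computed on
#' pairwise-complete observations. Two-sided p-values use the t
#' approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees
#' of freedom. All-constant columns yield `NA` entries.
#'
#' @param table data frame or matrix, rows = eyes, columns = parameters.
#' @param min_pairs minimum complete pairs per cell (default 3).
#' @return list with matrices `rho` (unit diagonal) and `p`.
#' @export
spearman_matrix <- function(table, min_pairs = 3L) {
  x <- as.matrix(as.data.frame(table))
  storage.mode(x) <- "double"
  p <- ncol(x)
  rho <- matrix(NA_real_, p, p, dimnames = list(colnames(x), colnames(x)))
  pval <- rho
  diag(rho) <- 1
  diag(pval) <- 0
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (j >= i) next
      ok <- stats::complete.cases(x[, i], x[, j])
      n <- sum(ok)
      if (n < min_pairs) next
      xi <- x[ok, i]; xj <- x[ok, j]
      if (stats::sd(xi) == 0 || stats::sd(xj) == 0) next
      r <- stats::cor(rank(xi), rank(xj))
      rho[i, j] <- rho[j, i] <- r
      if (abs(r) >= 1) {
        pval[i, j] <- pval[j, i] <- 0
      } else {
        tstat <- r * sqrt((n - 2) / (1 - r^2))
        pval[i, j] <- pval[j, i] <- 2 * stats::pt(-abs(tstat), df = n - 2)
      }
    }
  }
  list(rho = rho, p = pval)
}

#' Wilcoxon rank-sum test
#'
#' Rank-sum statistic of sample `a` within the pooled ranking (ties get
#' average ranks). For small samples (`length(a) <= 10`, `length(b) <= 10`)
#' without ties the two-sided p-value is computed by exhaustive enumeration
#' of all `choose(na + nb, na)` rank assignments; otherwise the normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param a,b numeric samples (nonempty).
#' @return list with `statistic` (rank sum of `a`), `p_value`, and `method`.
#' @export
rank_sum_test <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("both samples must be nonempty")
  na <- length(a); nb <- length(b); n <- na + nb
  pooled <- c(a, b)
  rk <- rank(pooled)
  w <- sum(rk[seq_len(na)])
  ties <- any(duplicated(pooled))
  if (!ties && na <= 10 && nb <= 10) {
    combos <- utils::combn(n, na)
    sums <- colSums(matrix(seq_len(n)[combos], nrow = na))
    p <- 2 * min(mean(sums <= w), mean(sums >= w))
    return(list(statistic = w, p_value = min(1, p), method = "exact"))
  }
  mu <- na * (n + 1) / 2
  tie_tab <- table(pooled)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
  sig2 <- na * nb / 12 * ((n + 1) - tie_corr)
  if (sig2 <= 0) {
    return(list(statistic = w, p_value = 1, method = "normal"))
  }
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sig2)
  list(statistic = w, p_value = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal")
}

#' Two-cluster variable clustering
#'
#' Clusters variables on their correlation profiles: variable i is
#' represented by the vector of absolute Spearman-free Pearson correlations
#' `|cor(x_i, x_j)|` over all variables j and partitioned with k-means
#' (50 restarts, deterministically seeded). Absolute values make the
#' grouping sign-invariant, as in variable-clustering procedures, so a
#' variable correlated negatively with its cluster peers (e.g. a
#' surface-to-volume ratio against volume measures) still joins them. For
#' each variable the squared correlation with the first principal component
#' of its own cluster is reported ("R-square with own cluster"). Variables
#' are sorted by name internally so the result does not depend on column
#' order; cluster ids are relabelled so cluster 1 has the larger
#' explained-variation share.
#'
#' @param table data frame or matrix, rows = eyes, columns = variables
#'   (complete cases used).
#' @param k number of clusters (default 2).
#' @param seed RNG seed for the k-means restarts.
#' @param nstart number of k-means restarts.
#' @return data frame with columns `variable`, `cluster`, `r2_own_cluster`,
#'   plus attribute `proportion_explained` (per-cluster share of total
#'   variation explained by its first principal component).
#' @export
cluster_variables <- function(table, k = 2L, seed = 20220906L, nstart = 50L) {
  x <- as.matrix(as.data.frame(table))
  storage.mode(x) <- "double"
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (k < 1) stop("k must be at least 1")
  if (k > ncol(x)) stop("k (", k, ") exceeds the number of variables (",
                        ncol(x), ")")
  ord <- order(colnames(x))
  x <- x[, ord, drop = FALSE]
  xs <- scale(x)
  constant <- apply(x, 2, stats::sd) == 0
  if (any(constant)) {
    stop("constant variable(s): ", paste(colnames(x)[constant], collapse = ", "))
  }
  vars <- abs(stats::cor(xs))            # sign-invariant correlation profiles
  if (k == 1L) {
    assign <- stats::setNames(rep(1L, ncol(x)), colnames(x))
  } else {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                     envir = globalenv())
    })
    set.seed(as.integer(seed))
    km <- stats::kmeans(vars, centers = k, nstart = nstart, iter.max = 100)
    assign <- stats::setNames(km$cluster, colnames(x))
  }
  total_var <- ncol(x)                              # standardized variables
  r2 <- numeric(ncol(x))
  explained <- numeric(k)
  for (cl in seq_len(k)) {
    members <- which(assign == cl)
    sub <- xs[, members, drop = FALSE]
    if (length(members) == 1L) {
      pc1 <- sub[, 1]
    } else {
      pc1 <- stats::prcomp(sub, center = FALSE, scale. = FALSE)$x[, 1]
    }
    r2[members] <- vapply(members, function(m) {
      stats::cor(xs[, m], pc1)^2
    }, numeric(1))
    explained[cl] <- sum(r2[members]) / total_var
  }
  # relabel so cluster 1 explains the most
  relabel <- order(explained, decreasing = TRUE)
  new_id <- match(assign, relabel)
  out <- data.frame(variable = colnames(x), cluster = new_id,
                    r2_own_cluster = r2, stringsAsFactors = FALSE)
  out <- out[order(out$cluster, -out$r2_own_cluster), ]
  rownames(out) <- NULL
  attr(out, "proportion_explained") <- explained[relabel]
  out
}
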