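#' Build a performance matrix
#'
#' N subjects x k conditions matrix of a metric (e.g. AUC), the input to the
#' rank-based comparison suite.
#'
#' @param values numeric matrix, subjects in rows, conditions in columns
#' @param conditions,subjects optional dimension names
#' @return a validated `performance_matrix`
#' @export
performance_matrix <- function(values, conditions = colnames(values),
                               subjects = rownames(values)) {
  values <- as.matrix(values)
  if (nrow(values) < 2 || ncol(values) < 2)
    stop("size error: need at least 2 subjects and 2 conditions")
  if (any(!is.finite(values)))
    stop("performance matrix has missing or non-finite cells")
  if (is.null(conditions)) conditions <- paste0("cond", seq_len(ncol(values)))
  if (is.null(subjects)) subjects <- paste0("subj", seq_len(nrow(values)))
  dimnames(values) <- list(subjects, conditions)
  structure(values, class = c("performance_matrix", "matrix"))
}

#' Friedman rank test across conditions
#'
#' Ranks the k conditions within each subject (average ranks on ties) and
#' tests for consistent differences. The statistic uses the standard tie
#' correction, so it agrees with `stats::friedman.test` exactly; the
#' p-value comes from the chi-square distribution with k-1 degrees of
#' freedom.
#'
#' @param M a `performance_matrix` (or plain N x k matrix)
#' @param larger_is_better rank direction; TRUE ranks the largest value k
#'   (best). The statistic is direction-invariant.
#' @return list: `chi2`, `df`, `p`, `mean_ranks` (named, best = highest)
#' @export
friedman_test <- function(M, larger_is_better = TRUE) {
  M <- unclass(as.matrix(M))
  n <- nrow(M); k <- ncol(M)
  if (n < 2 || k < 2) stop("size error: need N >= 2 and k >= 2")
  R <- t(apply(if (larger_is_better) M else -M, 1, rank))
  col_r <- colSums(R)
  ties <- sum(apply(R, 1, function(r) {
    tab <- table(r); sum(tab^3 - tab)
  }))
  denom <- n * k * (k + 1) - ties / (k - 1)
  # every row fully tied -> no evidence of differences at all
  chi2 <- if (denom <= 0) 0 else
    12 * sum((col_r - n * (k + 1) / 2)^2) / denom
  df <- k - 1
  list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE),
       mean_ranks = setNames(col_r / n, colnames(M)))
}

#' Nemenyi critical difference
#'
#' `CD = q_alpha(k) * sqrt(k (k+1) / (6 N))`, with `q_alpha(k)` the
#' studentized-range quantile at infinite degrees of freedom divided by
#' sqrt(2). Two conditions differ significantly when their mean ranks
#' differ by more than CD.
#'
#' @param k number of conditions (2..10)
#' @param N number of subjects
#' @param alpha significance level (default 0.05)
#' @return the critical difference (scalar)
#' @export
nemenyi_cd <- function(k, N, alpha = 0.05) {
  if (k < 2 || k > 10)
    stop("range error: Nemenyi CD supported for 2 <= k <= 10")
  q <- qtukey(1 - alpha, nmeans = k, df = Inf) / sqrt(2)
  q * sqrt(k * (k + 1) / (6 * N))
}

#' Nemenyi post-hoc over a performance matrix
#'
#' @param M a `performance_matrix`
#' @param alpha significance level
#' @return list: `cd`, `mean_ranks`, `significant` (logical k x k matrix),
#'   `graph` (data.frame of NOT-significantly-different pairs, the edges of
#'   the significance graph)
#' @export
nemenyi_posthoc <- function(M, alpha = 0.05) {
  fr <- friedman_test(M)
  k <- length(fr$mean_ranks)
  cd <- nemenyi_cd(k, nrow(M), alpha)
  dif <- abs(outer(fr$mean_ranks, fr$mean_ranks, `-`))
  sig <- dif > cd
  diag(sig) <- FALSE
  list(cd = cd, mean_ranks = fr$mean_ranks, significant = sig,
       graph = significance_graph(!sig))
}

holm_adjust <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- pmin(1, (m - seq_len(m) + 1) * p[ord])
  adj <- cummax(adj)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# all set partitions of 1..n (Bell-number many; fine for n <= 6)
set_partitions <- function(n) {
  if (n == 1) return(list(list(1L)))
  smaller <- set_partitions(n - 1L)
  out <- list()
  for (p in smaller) {
    for (b in seq_along(p))
      out[[length(out) + 1]] <- {
        q <- p; q[[b]] <- c(q[[b]], n); q
      }
    out[[length(out) + 1]] <- c(p, list(n))
  }
  out
}

#' Pairwise post-hoc comparisons after a Friedman test
#'
#' Pairwise statistics `z_ij = (Rbar_i - Rbar_j) / sqrt(k (k+1) / (6 N))`
#' with two-sided normal p-values, adjusted either by Holm's step-down
#' procedure or by Bergmann and Hommel's exhaustive-set procedure. The
#' latter enumerates all exhaustive hypothesis sets (via set partitions of
#' the conditions) and is more powerful, at exponential cost — supported
#' for k <= 6, which covers the five-algorithm comparison.
#'
#' @param M a `performance_matrix`
#' @param correction `"holm"` or `"bergmann_hommel"`
#' @param alpha significance level for the graph
#' @return list: `friedman`, `pairs` data.frame (i, j, z, p, p_adj),
#'   `p_adj` (symmetric k x k matrix), `graph` (edges between conditions
#'   NOT significantly different at `alpha`)
#' @export
pairwise_posthoc <- function(M, correction = c("holm", "bergmann_hommel"),
                             alpha = 0.05) {
  correction <- match.arg(correction)
  fr <- friedman_test(M)
  k <- length(fr$mean_ranks); N <- nrow(M)
  if (correction == "bergmann_hommel" && k > 6)
    stop("feasibility error: bergmann_hommel supported for k <= 6; ",
         "use correction = \"holm\"")
  se <- sqrt(k * (k + 1) / (6 * N))
  pairs <- t(utils::combn(k, 2))
  z <- (fr$mean_ranks[pairs[, 1]] - fr$mean_ranks[pairs[, 2]]) / se
  p <- 2 * pnorm(-abs(z))
  p_adj <- if (correction == "holm") holm_adjust(p) else
    bergmann_hommel_adjust(p, pairs, k)
  labels <- names(fr$mean_ranks)
  Padj <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  for (h in seq_len(nrow(pairs))) {
    Padj[pairs[h, 1], pairs[h, 2]] <- p_adj[h]
    Padj[pairs[h, 2], pairs[h, 1]] <- p_adj[h]
  }
  not_sig <- Padj >= alpha
  not_sig[is.na(not_sig)] <- FALSE
  list(friedman = fr,
       pairs = data.frame(i = labels[pairs[, 1]], j = labels[pairs[, 2]],
                          z = as.numeric(z), p = as.numeric(p),
                          p_adj = p_adj, stringsAsFactors = FALSE),
       p_adj = Padj, graph = significance_graph(not_sig))
}

# Bergmann-Hommel adjusted p-values by enumeration of exhaustive sets.
# An exhaustive set is the set of within-group pairs of some partition of
# the conditions; adjusted p for a pair is the max over exhaustive sets
# containing it of |E| * min(p in E), capped at 1.
bergmann_hommel_adjust <- function(p, pairs, k) {
  pair_id <- matrix(0L, k, k)
  for (h in seq_len(nrow(pairs)))
    pair_id[pairs[h, 1], pairs[h, 2]] <- h
  exhaustive <- list()
  for (part in set_partitions(k)) {
    ids <- integer()
    for (grp in part) {
      if (length(grp) < 2) next
      gp <- t(utils::combn(sort(grp), 2))
      ids <- c(ids, pair_id[gp])
    }
    if (length(ids)) exhaustive[[length(exhaustive) + 1]] <- sort(ids)
  }
  exhaustive <- unique(exhaustive)
  adj <- p
  for (E in exhaustive) {
    v <- min(1, length(E) * min(p[E]))
    adj[E] <- pmax(adj[E], v)
  }
  pmin(adj, 1)
}

# edges = pairs flagged TRUE in a symmetric logical matrix (no self edges)
significance_graph <- function(not_sig) {
  labels <- rownames(not_sig)
  k <- nrow(not_sig)
  edges <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    if (isTRUE(not_sig[i, j]))
      edges[[length(edges) + 1]] <- data.frame(
        from = labels[i], to = labels[j], stringsAsFactors = FALSE)
  if (!length(edges))
    return(data.frame(from = character(), to = character()))
  do.call(rbind, edges)
}

#' Compare conditions across subjects and write a JSON report
#'
#' Runs the Friedman test on a subject x condition metric matrix and, when
#' it rejects at `alpha`, the requested post-hoc (Nemenyi critical
#' difference, or pairwise z-tests with Holm / Bergmann-Hommel correction).
#'
#' @param M a `performance_matrix`
#' @param posthoc `"nemenyi"`, `"holm"` or `"bergmann_hommel"`
#' @param alpha significance level
#' @param path optional path to write the JSON report
#' @return a `comparison_result` list (friedman, mean_ranks, posthoc
#'   details, significance-graph edge list)
#' @export
compare_conditions <- function(M, posthoc = c("nemenyi", "holm",
                                              "bergmann_hommel"),
                               alpha = 0.05, path = NULL) {
  posthoc <- match.arg(posthoc)
  fr <- friedman_test(M)
  res <- list(method = posthoc, alpha = alpha, friedman = fr,
              mean_ranks = fr$mean_ranks)
  if (posthoc == "nemenyi") {
    nm <- nemenyi_posthoc(M, alpha)
    res$cd <- nm$cd
    res$graph <- nm$graph
  } else {
    pw <- pairwise_posthoc(M, posthoc, alpha)
    res$pairs <- pw$pairs
    res$p_adj <- pw$p_adj
    res$graph <- pw$graph
  }
  class(res) <- "comparison_result"
  if (!is.null(path))
    jsonlite::write_json(
      list(method = res$method, alpha = alpha,
           friedman = list(chi2 = fr$chi2, df = fr$df, p = fr$p),
           mean_ranks = as.list(fr$mean_ranks),
           cd = res$cd, pairs = res$pairs, graph = res$graph),
      path, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  res
}

#' @export
print.comparison_result <- function(x, ...) {
  fr <- x$friedman
  cat(sprintf("Friedman chi-squared = %.3f, df = %d, p-value = %.3g\n",
              fr$chi2, fr$df, fr$p))
  cat("mean ranks:", paste(sprintf("%s=%.2f", names(x$mean_ranks),
                                   x$mean_ranks), collapse = ", "), "\n")
  if (!is.null(x$cd)) cat(sprintf("Nemenyi CD = %.3f\n", x$cd))
  if (nrow(x$graph))
    cat("not significantly different:",
        paste(x$graph$from, x$graph$to, sep = "~", collapse = ", "), "\n")
  invisible(x)
}
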