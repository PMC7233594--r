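# Simplified conditional inference tree.
#
# Recursive partitioning for a categorical response on numeric covariates:
# at each node, each covariate's association with the response is assessed
# by a Monte-Carlo permutation test on a one-way ANOVA F statistic (the
# class-wise linear statistic), with Bonferroni adjustment across
# covariates. Splitting stops when the smallest adjusted p-value is not
# below alpha or the node is too small. The selected covariate is split at
# the threshold maximizing the Pearson chi-square of the resulting
# two-sample class table, ties broken toward the smaller threshold. This is
# a deliberately simplified variant: it makes no attempt at
# bit-compatibility with any published recursive-partitioning package.

# F statistics of x-by-class association for each column of `xp`
# (n x B matrix of permuted copies of one covariate).
anova_f_stat <- function(xp, y_int, n_k) {
  n <- nrow(xp); k <- length(n_k)
  tot <- colSums(xp)
  sums <- rowsum(xp, y_int, reorder = TRUE)        # k x B class sums
  ssb <- colSums(sums^2 / n_k) - tot^2 / n
  sst <- colSums(xp^2) - tot^2 / n
  ssw <- pmax(sst - ssb, 0)
  (ssb / (k - 1)) / pmax(ssw / (n - k), .Machine$double.eps)
}

perm_assoc_p <- function(x, y_int, n_k, n_perm) {
  n <- length(x)
  obs <- anova_f_stat(matrix(x, ncol = 1L), y_int, n_k)
  perm <- matrix(x[vapply(seq_len(n_perm), function(b) sample.int(n),
                          integer(n))], nrow = n)
  f_perm <- anova_f_stat(perm, y_int, n_k)
  p <- (1 + sum(f_perm >= obs - 1e-12)) / (1 + n_perm)
  c(stat = unname(obs), p = p)
}

# best binary split of x by the Pearson chi-square of table(x <= c, y);
# ties toward the smaller threshold
best_split_threshold <- function(x, y, minbucket) {
  xs <- sort(unique(x))
  if (length(xs) < 2L) return(NULL)
  cand <- (xs[-length(xs)] + xs[-1L]) / 2
  best <- NULL; best_stat <- -Inf
  for (cc in cand) {
    left <- x <= cc
    if (sum(left) < minbucket || sum(!left) < minbucket) next
    tab <- table(factor(left, levels = c(TRUE, FALSE)), y)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    stat <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$statistic)
    if (is.finite(stat) && stat > best_stat + 1e-12) {
      best_stat <- stat; best <- cc
    }
  }
  if (is.null(best)) NULL else list(threshold = best, statistic = best_stat)
}

grow_node <- function(data, covariates, y, alpha, n_perm, min_node, minbucket,
                      max_depth, depth, id_env) {
  id_env$id <- id_env$id + 1L
  node <- list(id = id_env$id, n = length(y),
               class_dist = table(y), terminal = TRUE,
               split_var = NA_character_, split_threshold = NA_real_,
               p_adjusted = NA_real_, depth = depth)
  if (length(y) < min_node || depth >= max_depth ||
      length(unique(as.integer(y))) < 2L)
    return(node)
  y_int <- as.integer(y)
  n_k <- as.vector(table(y_int))
  tests <- vapply(covariates, function(v)
    perm_assoc_p(data[[v]], y_int, n_k, n_perm), numeric(2L))
  p_adj <- pmin(1, tests["p", ] * length(covariates))
  j <- which.min(p_adj)
  node$p_adjusted <- unname(p_adj[j])
  if (node$p_adjusted >= alpha) return(node)
  split <- best_split_threshold(data[[covariates[j]]], y, minbucket)
  if (is.null(split)) return(node)
  node$terminal <- FALSE
  node$split_var <- covariates[j]
  node$split_threshold <- split$threshold
  left <- data[[covariates[j]]] <= split$threshold
  node$left <- grow_node(data[left, , drop = FALSE], covariates,
                         droplevels(y[left]), alpha, n_perm, min_node,
                         minbucket, max_depth, depth + 1L, id_env)
  node$right <- grow_node(data[!left, , drop = FALSE], covariates,
                          droplevels(y[!left]), alpha, n_perm, min_node,
                          minbucket, max_depth, depth + 1L, id_env)
  node
}

#' Fit a simplified conditional inference tree
#'
#' @param data data.frame of numeric covariates (non-finite values are
#'   rejected).
#' @param response Categorical response (factor or coercible).
#' @param covariates Columns of `data` to use (default all).
#' @param alpha Significance level for the Bonferroni-adjusted permutation
#'   p-value required to split (default 0.05).
#' @param n_perm Monte-Carlo permutations per association test
#'   (default 9999).
#' @param min_node Minimum observations for a node to be tested/split
#'   (default 10).
#' @param minbucket Minimum observations in a child (default 5).
#' @param max_depth Maximum tree depth (default `Inf`; depth 1 allows a
#'   single split).
#' @param seed Seed for the permutation stream (default 1); the caller's
#'   RNG state is untouched.
#' @return Object of class `lcshift_ctree` with the recursive node
#'   structure in `$root`.
#' @export
ctree_fit <- function(data, response, covariates = names(data), alpha = 0.05,
                      n_perm = 9999L, min_node = 10L, minbucket = 5L,
                      max_depth = Inf, seed = 1L) {
  stopifnot(is.data.frame(data), all(covariates %in% names(data)))
  y <- droplevels(as.factor(response))
  keep <- stats::complete.cases(data[, covariates, drop = FALSE]) & !is.na(y)
  data <- data[keep, , drop = FALSE]; y <- droplevels(y[keep])
  for (v in covariates)
    if (!is.numeric(data[[v]]) || any(!is.finite(data[[v]])))
      stop_lcshift("covariate ", v, " must be finite numeric")
  id_env <- new.env(parent = emptyenv())
  id_env$id <- 0L
  root <- with_seed(seed, grow_node(data, covariates, y, alpha,
                                    as.integer(n_perm), min_node, minbucket,
                                    max_depth, 0L, id_env = id_env))
  structure(list(root = root, alpha = alpha, n_perm = n_perm,
                 covariates = covariates, n = length(y),
                 classes = levels(y)),
            class = "lcshift_ctree")
}

collect_terminal <- function(node) {
  if (node$terminal) return(list(node))
  c(collect_terminal(node$left), collect_terminal(node$right))
}

#' Terminal nodes of a fitted tree
#'
#' @param tree An `lcshift_ctree`.
#' @return List of terminal node records (id, n, class distribution).
#' @export
ctree_terminal_nodes <- function(tree) collect_terminal(tree$root)

format_node <- function(node, indent = "") {
  dist <- paste(names(node$class_dist), as.vector(node$class_dist),
                sep = ":", collapse = " ")
  if (node$terminal) {
    sprintf("%s* n=%d (%s)%s\n", indent, node$n, dist,
            if (!is.na(node$p_adjusted))
              sprintf(" [min adj p = %.3g]", node$p_adjusted) else "")
  } else {
    paste0(
      sprintf("%s%s (adj p = %.3g), n=%d (%s)\n", indent, node$split_var,
              node$p_adjusted, node$n, dist),
      sprintf("%s<= %.4g:\n", indent, node$split_threshold),
      format_node(node$left, paste0(indent, "  ")),
      sprintf("%s>  %.4g:\n", indent, node$split_threshold),
      format_node(node$right, paste0(indent, "  ")))
  }
}

#' @export
format.lcshift_ctree <- function(x, ...) {
  paste0("Conditional inference tree (permutation test, Bonferroni), n = ",
         x$n, ", alpha = ", x$alpha, "\n", format_node(x$root))
}

#' @export
print.lcshift_ctree <- function(x, ...) {
  cat(format(x))
  invisible(x)
}
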