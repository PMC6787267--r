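#' Anosim test of group differences in community structure
#'
#' Rank-based permutation test of whether between-group dissimilarities
#' exceed within-group ones (statistic R in \[-1, 1\]), computed by
#' [vegan::anosim()]. The p-value is one-tailed with the add-one
#' convention, (count(perm >= obs) + 1) / (permutations + 1).
#'
#' @param d sample dissimilarity `dist` or square matrix.
#' @param groups per-sample group labels (>= 2 groups, each >= 2 samples).
#' @param permutations number of label permutations (default 999).
#' @param seed integer seed.
#' @return a `"permutation_test"` list: `statistic`, `p_value`,
#'   `n_permutations`, `seed`, `method`.
#' @export
anosim_test <- function(d, groups, permutations = 999, seed = 1) {
  d <- stats::as.dist(d)
  groups <- as.factor(groups)
  if (length(groups) != attr(d, "Size")) stop("groups do not match samples")
  if (nlevels(droplevels(groups)) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2))
    stop("every group needs >= 2 samples")
  set.seed(mix_seed(seed))
  fit <- vegan::anosim(d, groups, permutations = permutations)
  permutation_test(fit$statistic, fit$signif, permutations, seed, "anosim")
}

#' Mantel test of correlation between two distance matrices
#'
#' Pearson correlation of the two lower-triangle vectors; the p-value is
#' obtained by jointly permuting rows and columns of `d1`
#' ([vegan::mantel()]; one-tailed greater, add-one convention).
#'
#' @param d1,d2 `dist` objects or square matrices over the same items.
#' @param permutations number of permutations (default 999).
#' @param seed integer seed.
#' @return a `"permutation_test"` list.
#' @export
mantel_test <- function(d1, d2, permutations = 999, seed = 1) {
  d1 <- stats::as.dist(d1); d2 <- stats::as.dist(d2)
  check_same_items(d1, d2)
  if (stats::sd(as.vector(d1)) == 0 || stats::sd(as.vector(d2)) == 0)
    stop("constant distance vector: correlation undefined")
  set.seed(mix_seed(seed))
  fit <- vegan::mantel(d1, d2, permutations = permutations, method = "pearson")
  permutation_test(fit$statistic, fit$signif, permutations, seed, "mantel")
}

#' Partial Mantel test
#'
#' First-order partial correlation r(d1, d2 | d3) =
#' (r12 - r13 r23) / sqrt((1 - r13^2)(1 - r23^2)) on the lower-triangle
#' vectors; the p-value permutes only `d1` ([vegan::mantel.partial()]).
#'
#' @param d1,d2,d3 `dist` objects or square matrices over the same items.
#' @inheritParams mantel_test
#' @return a `"permutation_test"` list.
#' @export
partial_mantel_test <- function(d1, d2, d3, permutations = 999, seed = 1) {
  d1 <- stats::as.dist(d1); d2 <- stats::as.dist(d2); d3 <- stats::as.dist(d3)
  check_same_items(d1, d2); check_same_items(d1, d3)
  v1 <- as.vector(d1); v2 <- as.vector(d2); v3 <- as.vector(d3)
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0 || stats::sd(v3) == 0)
    stop("constant distance vector: correlation undefined")
  r13 <- stats::cor(v1, v3); r23 <- stats::cor(v2, v3)
  if (abs(r13) >= 1 - 1e-12 || abs(r23) >= 1 - 1e-12)
    stop("covariate matrix perfectly correlated with an input: partial correlation undefined")
  set.seed(mix_seed(seed))
  fit <- vegan::mantel.partial(d1, d2, d3, permutations = permutations,
                               method = "pearson")
  permutation_test(fit$statistic, fit$signif, permutations, seed, "partial_mantel")
}

#' Pearson correlation with a t-based two-tailed p-value
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return list with `r` and `p_value` (two-tailed, t with n-2 df).
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input vector")
  fit <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(fit$estimate), p_value = fit$p.value)
}

check_same_items <- function(a, b) {
  if (attr(a, "Size") != attr(b, "Size")) stop("distance matrices differ in size")
  la <- attr(a, "Labels"); lb <- attr(b, "Labels")
  if (!is.null(la) && !is.null(lb) && !identical(la, lb))
    stop("distance matrices have different item labels")
  invisible(NULL)
}

permutation_test <- function(statistic, p_value, n_permutations, seed, method) {
  structure(list(statistic = unname(statistic), p_value = p_value,
                 n_permutations = n_permutations, seed = seed,
                 method = method),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, p = %.4g (%d permutations)\n",
              x$method, x$statistic, x$p_value, x$n_permutations))
  invisible(x)
}
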