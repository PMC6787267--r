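#' Rarefy a community table to even depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric, one draw per sample) down to `depth`, via
#' [vegan::rrarefy()]. Samples whose total is below `depth` are dropped
#' with a warning. Deterministic for a given `seed`.
#'
#' @param table a [community_table()] or taxa x samples count matrix.
#' @param depth target reads per sample (the study convention is 10,000).
#' @param seed integer seed.
#' @return a rarefied [community_table()]; every column sums to `depth`.
#' @export
rarefy_table <- function(table, depth = 10000, seed = 1) {
  m <- as_count_matrix(table)
  if (depth < 1) stop("depth must be >= 1")
  totals <- colSums(m)
  keep <- totals >= depth
  if (!any(keep)) stop("all samples have fewer than ", depth, " reads")
  if (any(!keep))
    warning(sprintf("dropping %d sample(s) with fewer than %d reads: %s",
                    sum(!keep), depth,
                    paste(colnames(m)[!keep], collapse = ", ")))
  m <- m[, keep, drop = FALSE]
  set.seed(mix_seed(seed))
  # rrarefy warns when the smallest positive count exceeds 1, suspecting
  # pre-scaled data; inputs are validated as raw counts above
  out <- withCallingHandlers(
    t(vegan::rrarefy(t(m), depth)),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  community_table(out)
}

#' Shannon diversity (natural log)
#'
#' H = -sum p_i log p_i over taxa with positive counts, in nats.
#'
#' @param counts non-negative count (or abundance) vector.
#' @return Shannon index in nats.
#' @export
shannon <- function(counts) {
  if (any(counts < 0)) stop("negative counts")
  if (sum(counts) <= 0) stop("all-zero count vector")
  as.numeric(vegan::diversity(counts, index = "shannon"))
}

#' Taxon richness
#'
#' Number of taxa with a positive count.
#'
#' @param counts non-negative count vector.
#' @return integer richness.
#' @export
richness <- function(counts) {
  if (any(counts < 0)) stop("negative counts")
  as.integer(sum(counts > 0))
}

#' Per-sample alpha diversity
#'
#' @param table a [community_table()] or taxa x samples matrix.
#' @return data.frame with columns `sample`, `shannon` (nats), `richness`.
#' @export
alpha_diversity <- function(table) {
  m <- as_count_matrix(table)
  data.frame(sample = colnames(m),
             shannon = apply(m, 2, shannon),
             richness = apply(m, 2, richness),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity between two samples
#'
#' BC = 1 - 2 sum min(x_i, y_i) / (sum x + sum y), in \[0, 1\].
#'
#' @param x,y equal-length non-negative count vectors with positive totals.
#' @return Bray-Curtis dissimilarity.
#' @export
bray_curtis <- function(x, y) {
  check_pair_vectors(x, y)
  as.numeric(vegan::vegdist(rbind(x, y), method = "bray"))
}

#' Jaccard dissimilarity (presence/absence) between two samples
#'
#' 1 - |shared taxa| / |union taxa|; depends only on which taxa are present.
#'
#' @inheritParams bray_curtis
#' @return Jaccard dissimilarity in \[0, 1\].
#' @export
jaccard <- function(x, y) {
  check_pair_vectors(x, y)
  as.numeric(vegan::vegdist(rbind(x, y), method = "jaccard", binary = TRUE))
}

check_pair_vectors <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (any(x < 0) || any(y < 0)) stop("negative counts")
  if (sum(x) <= 0 || sum(y) <= 0) stop("zero-total count vector")
  invisible(NULL)
}

#' Pairwise beta diversity of a community table
#'
#' @param table a [community_table()] or taxa x samples matrix.
#' @param metric `"bray"` (abundance-based Bray-Curtis) or `"jaccard"`
#'   (presence/absence).
#' @return a [stats::dist] over samples.
#' @export
beta_diversity <- function(table, metric = c("bray", "jaccard")) {
  metric <- match.arg(metric)
  m <- as_count_matrix(table)
  if (any(colSums(m) <= 0)) stop("zero-total sample(s) in table")
  vegan::vegdist(t(m), method = metric, binary = metric == "jaccard")
}

#' Distance decay of community dissimilarity with elevation
#'
#' Ordinary least squares of pairwise beta diversity on pairwise
#' elevational distance (absolute altitude difference) over all unordered
#' sample pairs. Because pairs are not independent, the p-value comes from
#' a Mantel-style permutation of sample labels (one-tailed, correlation
#' greater than observed).
#'
#' @param beta sample dissimilarity `dist` or square matrix.
#' @param elevations per-sample elevation (meters), named by sample or in
#'   `beta` order.
#' @param permutations number of label permutations.
#' @param seed integer seed.
#' @return list with `slope`, `intercept`, `r`, `p_value`, `n_samples`,
#'   `n_permutations`, class `"distance_decay"`.
#' @export
distance_decay <- function(beta, elevations, permutations = 999, seed = 1) {
  d <- stats::as.dist(beta)
  n <- attr(d, "Size")
  if (n < 3) stop("distance decay needs at least 3 samples")
  labs <- attr(d, "Labels")
  if (!is.null(names(elevations)) && !is.null(labs)) {
    if (!all(labs %in% names(elevations)))
      stop("elevations missing for some samples")
    elevations <- elevations[labs]
  }
  if (length(elevations) != n) stop("elevations do not match samples")
  bv <- as.vector(d)
  ev <- as.vector(stats::dist(elevations))
  if (stats::sd(ev) == 0) stop("constant elevational distances")
  fit <- stats::lm(bv ~ ev)
  r_obs <- stats::cor(ev, bv)
  set.seed(mix_seed(seed))
  r_perm <- replicate(permutations, {
    p <- sample.int(n)
    stats::cor(as.vector(stats::dist(elevations[p])), bv)
  })
  p <- (sum(r_perm >= r_obs) + 1) / (permutations + 1)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r = r_obs, p_value = p, n_samples = n,
                 n_permutations = permutations),
            class = "distance_decay")
}

#' @export
print.distance_decay <- function(x, ...) {
  cat("Distance decay of beta diversity\n")
  cat(sprintf("  slope: %.4g per m, intercept: %.4g\n", x$slope, x$intercept))
  cat(sprintf("  r = %.4f, p = %.4g (%d permutations, %d samples)\n",
              x$r, x$p_value, x$n_permutations, x$n_samples))
  invisible(x)
}
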