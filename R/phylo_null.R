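#' Cophenetic distances between the tips of a phylogeny
#'
#' d(i, j) = sum of branch lengths along the path between tips i and j.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @return symmetric tip-by-tip distance matrix with a zero diagonal.
#' @export
cophenetic_distances <- function(tree) {
  validate_phylogeny(tree)
  ape::cophenetic.phylo(tree)
}

#' Abundance-weighted beta mean-nearest-taxon distance (betaMNTD)
#'
#' For each taxon present in one community, the phylogenetic distance to
#' its closest relative in the other community is found; betaMNTD is the
#' relative-abundance-weighted mean of these nearest-taxon distances,
#' averaged over the two directions. A taxon present in both communities
#' contributes its self-distance of zero.
#'
#' @param x,y count (or abundance) vectors over the taxa of `d`, either
#'   named or in row order of `d`; each must have a positive total.
#' @param d taxon-by-taxon phylogenetic distance matrix (see
#'   [cophenetic_distances()]).
#' @return betaMNTD, in the branch-length units of `d`.
#' @export
beta_mntd <- function(x, y, d) {
  d <- as.matrix(d)
  x <- align_taxon_vector(x, d)
  y <- align_taxon_vector(y, d)
  if (sum(x) <= 0 || sum(y) <= 0) stop("empty community")
  bmntd_pair(which(x > 0), which(y > 0), x / sum(x), y / sum(y), d)
}

align_taxon_vector <- function(v, d) {
  if (!is.null(names(v))) {
    if (!all(names(v) %in% rownames(d)))
      stop("taxa absent from the distance matrix: ",
           paste(setdiff(names(v), rownames(d)), collapse = ", "))
    out <- stats::setNames(numeric(nrow(d)), rownames(d))
    out[names(v)] <- v
    return(out)
  }
  if (length(v) != nrow(d)) stop("vector length does not match distance matrix")
  v
}

# One betaMNTD given support indices, full relative-abundance vectors and
# the (possibly tip-shuffled) distance matrix. max.col on the negated
# sub-matrix is a fast row-wise min.
bmntd_pair <- function(sx, sy, fx, fy, d) {
  dxy <- d[sx, sy, drop = FALSE]
  min_x <- dxy[cbind(seq_along(sx), max.col(-dxy, ties.method = "first"))]
  dyx <- t(dxy)
  min_y <- dyx[cbind(seq_along(sy), max.col(-dyx, ties.method = "first"))]
  0.5 * (sum(fx[sx] * min_x) + sum(fy[sy] * min_y))
}

#' Beta nearest taxon index (betaNTI) from a tip-shuffling null model
#'
#' For every requested sample pair, the observed betaMNTD is compared to a
#' null distribution obtained by shuffling taxon labels across all tips of
#' the tree (topology, branch lengths and the community matrix are kept
#' fixed). betaNTI is the standardized effect size
#' (obs - mean(null)) / sd(null) with the n-1 standard deviation.
#' |betaNTI| > 2 indicates that selection dominates the pair's turnover.
#'
#' One shuffle is drawn per replicate and reused across all pairs, so
#' results do not depend on pair ordering; the whole computation is
#' reproducible for a given `seed`.
#'
#' @param table a [community_table()] or taxa x samples count matrix,
#'   aligned to the tree (see [align_table_and_tree()]).
#' @param tree rooted `phylo` with branch lengths covering all table taxa.
#' @param reps null replicates (default 999).
#' @param seed integer seed.
#' @param pairs optional 2-column matrix/data.frame of sample identifiers
#'   (or indices); default all unordered pairs.
#' @param method `"sample"` draws `reps` random shuffles; `"exhaustive"`
#'   enumerates every tip permutation (only feasible for very small trees)
#'   and ignores `reps`.
#' @return data.frame with one row per pair: `sample_1`, `sample_2`,
#'   `beta_mntd_obs`, `null_mean`, `null_sd`, `beta_nti`, `n_null`.
#'   Pairs with a degenerate null (sd = 0) get `beta_nti = NA` with a
#'   warning and are excluded from downstream classification.
#' @export
null_beta_nti <- function(table, tree, reps = 999, seed = 1, pairs = NULL,
                          method = c("sample", "exhaustive")) {
  method <- match.arg(method)
  m <- as_count_matrix(table)
  m <- drop_empty_taxa(m)
  if (!all(rownames(m) %in% tree$tip.label))
    stop("table taxa missing from tree; run align_table_and_tree() first")
  if (method == "sample" && reps < 2) stop("reps must be >= 2")
  if (any(colSums(m) <= 0)) stop("empty community in table")

  d_full <- cophenetic_distances(tree)
  tips <- rownames(d_full)
  idx <- match(rownames(m), tips)
  ntip <- length(tips)

  f <- sweep(m, 2, colSums(m), "/")
  supports <- lapply(seq_len(ncol(m)), function(j) which(m[, j] > 0))
  pr <- resolve_pairs(pairs, colnames(m))
  npair <- nrow(pr)

  perms <- if (method == "exhaustive") {
    if (ntip > 8) stop("exhaustive enumeration is limited to <= 8 tips")
    all_permutations(ntip)
  } else NULL
  nrep <- if (method == "exhaustive") nrow(perms) else reps

  bmntd_all <- function(dsub) {
    vapply(seq_len(npair), function(k) {
      i <- pr[k, 1]; j <- pr[k, 2]
      bmntd_pair(supports[[i]], supports[[j]], f[, i], f[, j], dsub)
    }, numeric(1))
  }

  obs <- bmntd_all(d_full[idx, idx, drop = FALSE])
  nulls <- matrix(0, nrep, npair)
  for (r in seq_len(nrep)) {
    if (method == "exhaustive") {
      p <- perms[r, ]
    } else {
      set.seed(mix_seed(seed, r))
      p <- sample.int(ntip)
    }
    nulls[r, ] <- bmntd_all(d_full[p[idx], p[idx], drop = FALSE])
  }

  mu <- colMeans(nulls)
  sdv <- apply(nulls, 2, stats::sd)
  bnti <- (obs - mu) / sdv
  degen <- sdv == 0
  if (any(degen)) {
    warning(sprintf("%d pair(s) have a degenerate null (sd = 0); betaNTI set to NA",
                    sum(degen)))
    bnti[degen] <- NA_real_
  }
  data.frame(sample_1 = colnames(m)[pr[, 1]],
             sample_2 = colnames(m)[pr[, 2]],
             beta_mntd_obs = obs, null_mean = mu, null_sd = sdv,
             beta_nti = bnti, n_null = nrep,
             row.names = NULL, stringsAsFactors = FALSE)
}

drop_empty_taxa <- function(m) {
  keep <- rowSums(m) > 0
  m[keep, , drop = FALSE]
}

# Normalize a pairs argument (identifiers or indices) to an index matrix.
resolve_pairs <- function(pairs, sample_ids) {
  if (is.null(pairs)) return(pair_index(length(sample_ids)))
  p <- as.matrix(pairs)
  if (ncol(p) != 2) stop("pairs must have two columns")
  if (is.character(p)) {
    i <- match(p[, 1], sample_ids)
    j <- match(p[, 2], sample_ids)
    if (anyNA(i) || anyNA(j)) stop("unknown sample identifiers in pairs")
    p <- cbind(i, j)
  }
  storage.mode(p) <- "integer"
  if (any(p < 1) || any(p > length(sample_ids))) stop("pair index out of range")
  if (any(p[, 1] == p[, 2])) stop("a pair must name two distinct samples")
  p
}

#' Bray-Curtis-based Raup-Crick index (RCbray)
#'
#' For each sample pair, the observed Bray-Curtis dissimilarity is
#' compared with a null distribution of dissimilarities between
#' probabilistically assembled communities. Each null community keeps the
#' sample's observed richness and total reads: taxa are first drawn from
#' the regional species pool (all samples of the table) without
#' replacement with probability proportional to occupancy (number of
#' samples occupied), each drawn taxon receives one individual, and the
#' remaining individuals are allocated with replacement in proportion to
#' the taxon's total relative abundance in the pool.
#'
#' RCbray = 2 ((count(null < obs) + 0.5 count(null = obs)) / reps - 0.5),
#' in \[-1, 1\]. RCbray > +0.95 indicates dispersal limitation,
#' RCbray < -0.95 homogenizing dispersal, |RCbray| <= 0.95 drift, for
#' pairs whose |betaNTI| <= 2.
#'
#' Each pair draws its null replicates from its own RNG substream derived
#' from `seed` and the pair's sample indices, so results are independent
#' of the order in which pairs are requested.
#'
#' @param table a [community_table()] or taxa x samples count matrix,
#'   ideally rarefied to even depth.
#' @param reps null replicates (default 999).
#' @param seed integer seed.
#' @param pairs optional 2-column matrix of sample identifiers or indices;
#'   default all unordered pairs.
#' @return data.frame with one row per pair: `sample_1`, `sample_2`,
#'   `bray_obs`, `rc_bray`, `n_null`.
#' @export
raup_crick_bray <- function(table, reps = 999, seed = 1, pairs = NULL) {
  m <- as_count_matrix(table)
  m <- drop_empty_taxa(m)
  if (reps < 2) stop("reps must be >= 2")
  if (any(colSums(m) <= 0)) stop("empty community in table")
  ntax <- nrow(m)
  occ <- rowSums(m > 0)
  ab <- rowSums(m) / sum(m)
  rich <- colSums(m > 0)
  tot <- colSums(m)
  if (any(rich > ntax)) stop("sample richness exceeds pool richness")

  pr <- resolve_pairs(pairs, colnames(m))
  bray_num <- function(a, b) 1 - 2 * sum(pmin(a, b)) / (sum(a) + sum(b))
  null_comm <- function(k, n_reads) {
    sel <- sample.int(ntax, k, prob = occ)
    cnt <- numeric(ntax)
    cnt[sel] <- 1
    if (n_reads > k)
      cnt[sel] <- cnt[sel] + stats::rmultinom(1, n_reads - k, ab[sel])[, 1]
    cnt
  }

  out <- data.frame(sample_1 = colnames(m)[pr[, 1]],
                    sample_2 = colnames(m)[pr[, 2]],
                    bray_obs = NA_real_, rc_bray = NA_real_, n_null = reps,
                    row.names = NULL, stringsAsFactors = FALSE)
  for (k in seq_len(nrow(pr))) {
    i <- pr[k, 1]; j <- pr[k, 2]
    obs <- bray_num(m[, i], m[, j])
    set.seed(mix_seed(seed, min(i, j), max(i, j)))
    nulls <- vapply(seq_len(reps), function(r) {
      bray_num(null_comm(rich[i], tot[i]), null_comm(rich[j], tot[j]))
    }, numeric(1))
    eps <- 1e-12
    below <- sum(nulls < obs - eps)
    ties <- sum(abs(nulls - obs) <= eps)
    out$bray_obs[k] <- obs
    out$rc_bray[k] <- 2 * ((below + 0.5 * ties) / reps - 0.5)
  }
  out
}
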