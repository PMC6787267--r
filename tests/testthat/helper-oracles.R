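# Independent oracle implementations, deliberately naive and kept separate
# from the package's code paths.

# betaMNTD by exhaustive double loop over present taxa.
bmntd_loop <- function(x, y, d) {
  sx <- which(x > 0); sy <- which(y > 0)
  fx <- x[sx] / sum(x[sx]); fy <- y[sy] / sum(y[sy])
  acc_x <- 0
  for (a in seq_along(sx)) {
    best <- Inf
    for (b in seq_along(sy)) best <- min(best, d[sx[a], sy[b]])
    acc_x <- acc_x + fx[a] * best
  }
  acc_y <- 0
  for (b in seq_along(sy)) {
    best <- Inf
    for (a in seq_along(sx)) best <- min(best, d[sx[a], sy[b]])
    acc_y <- acc_y + fy[b] * best
  }
  0.5 * (acc_x + acc_y)
}

# All permutations of 1..n by insertion (different algorithm from the
# package's recursion-by-first-element).
perms_by_insertion <- function(n) {
  rows <- list(1L)
  for (k in 2:n) {
    nxt <- list()
    for (p in rows) {
      for (pos in 0:(k - 1)) {
        nxt[[length(nxt) + 1L]] <- append(p, k, after = pos)
      }
    }
    rows <- nxt
  }
  do.call(rbind, rows)
}

# Anosim R by direct hand-ranking of the dissimilarities.
anosim_R_oracle <- function(d, groups) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  iv <- jv <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) { iv <- c(iv, i); jv <- c(jv, j) }
  vals <- dm[cbind(iv, jv)]
  rk <- rank(vals)   # ties averaged
  within <- groups[iv] == groups[jv]
  M <- n * (n - 1) / 2
  (mean(rk[!within]) - mean(rk[within])) / (M / 2)
}

# Small fixture builders ----------------------------------------------------

toy_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

random_table <- function(n_taxa, n_samples, seed, depth = 200) {
  set.seed(seed)
  m <- sapply(seq_len(n_samples), function(i) {
    as.vector(rmultinom(1, depth, rlnorm(n_taxa)))
  })
  dimnames(m) <- list(paste0("OTU_", seq_len(n_taxa)),
                      paste0("S", seq_len(n_samples)))
  m
}
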