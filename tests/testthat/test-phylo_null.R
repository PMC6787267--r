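test_that("cophenetic distances are path sums of branch lengths", {
  d <- cophenetic_distances(toy_tree())
  expect_equal(d["A", "B"], 2)
  expect_equal(d["A", "C"], 4)
  expect_equal(d["B", "C"], 4)
  expect_equal(unname(diag(d)), c(0, 0, 0))
  star <- ape::read.tree(text = "(A:1.5,B:1.5,C:1.5,D:1.5)R;")
  star <- ape::root(star, outgroup = "A", resolve.root = TRUE)
  ds <- cophenetic_distances(star)
  expect_true(all(ds[upper.tri(ds)] == 3))
})

test_that("betaMNTD matches hand values and the double-loop oracle", {
  d <- cophenetic_distances(toy_tree())
  # identical supports: every nearest-taxon distance is a self-match
  expect_equal(beta_mntd(c(A = 2, B = 1, C = 0), c(A = 9, B = 4, C = 0), d), 0)
  # two singletons: forced to the single cross distance
  expect_equal(beta_mntd(c(A = 3, B = 0, C = 0), c(A = 0, B = 0, C = 5), d), 4)
  # random 5-taxon instances against the exhaustive double loop
  set.seed(21)
  tr <- ape::rtree(5)
  dm <- cophenetic_distances(tr)
  for (i in 1:20) {
    x <- rpois(5, 2); y <- rpois(5, 2)
    if (sum(x) == 0) x[1] <- 1
    if (sum(y) == 0) y[2] <- 1
    expect_equal(beta_mntd(x, y, dm), bmntd_loop(x, y, dm))
    expect_equal(beta_mntd(x, y, dm), beta_mntd(y, x, dm))
  }
  expect_error(beta_mntd(c(A = 0, B = 0, C = 0), c(A = 1, B = 0, C = 0), d),
               "empty community")
})

test_that("betaMNTD agrees with picante's comdistnt", {
  skip_if_not_installed("picante")
  set.seed(31)
  tr <- ape::rtree(12)
  m <- random_table(12, 5, seed = 32)
  rownames(m) <- tr$tip.label
  dm <- cophenetic_distances(tr)
  ref <- as.matrix(picante::comdistnt(t(m), dm, abundance.weighted = TRUE))
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(beta_mntd(m[, i], m[, j], dm), ref[i, j], tolerance = 1e-10)
  }
})

test_that("betaNTI equals the exhaustive tip-permutation oracle on tiny trees", {
  set.seed(41)
  tr <- ape::rtree(4)
  tr$tip.label <- c("t1", "t2", "t3", "t4")
  m <- matrix(c(4, 1, 0, 0,
                0, 0, 3, 2), 4, 2,
              dimnames = list(tr$tip.label, c("S1", "S2")))
  res <- null_beta_nti(m, tr, seed = 1, method = "exhaustive")
  expect_equal(res$n_null, 24)

  # independent oracle: insertion-built permutations + double-loop betaMNTD
  dm <- cophenetic_distances(tr)[tr$tip.label, tr$tip.label]
  perms <- perms_by_insertion(4)
  nulls <- apply(perms, 1, function(p) {
    bmntd_loop(m[, 1], m[, 2], dm[p, p])
  })
  obs <- unname(bmntd_loop(m[, 1], m[, 2], dm))
  expect_equal(res$beta_mntd_obs, obs)
  expect_equal(res$null_mean, mean(nulls))
  expect_equal(res$null_sd, sd(nulls))
  expect_equal(res$beta_nti, (obs - mean(nulls)) / sd(nulls))
})

test_that("betaNTI is reproducible, pair-order invariant and scale invariant", {
  set.seed(51)
  tr <- ape::rtree(10)
  m <- random_table(10, 6, seed = 52)
  rownames(m) <- tr$tip.label
  a <- suppressWarnings(null_beta_nti(m, tr, reps = 49, seed = 9))
  b <- suppressWarnings(null_beta_nti(m, tr, reps = 49, seed = 9))
  expect_identical(a, b)

  # same pairs requested in reverse order give the same per-pair values
  pr <- cbind(c(1, 2), c(4, 3))
  fwd <- suppressWarnings(null_beta_nti(m, tr, reps = 49, seed = 9, pairs = pr))
  rev <- suppressWarnings(null_beta_nti(m, tr, reps = 49, seed = 9,
                                        pairs = pr[2:1, ]))
  expect_equal(fwd$beta_nti, rev$beta_nti[2:1])

  # multiplying all branch lengths by a constant leaves betaNTI unchanged
  tr3 <- tr; tr3$edge.length <- tr3$edge.length * 3
  c3 <- suppressWarnings(null_beta_nti(m, tr3, reps = 49, seed = 9))
  expect_equal(a$beta_nti, c3$beta_nti, tolerance = 1e-12)
  expect_equal(a$beta_mntd_obs * 3, c3$beta_mntd_obs, tolerance = 1e-12)
})

test_that("a degenerate null (identical supports) is flagged, not guessed", {
  tr <- toy_tree()
  m <- matrix(c(3, 1, 0,
                5, 2, 0), 3, 2,
              dimnames = list(c("A", "B", "C"), c("S1", "S2")))
  expect_warning(res <- null_beta_nti(m, tr, reps = 19, seed = 2),
                 "degenerate null")
  expect_true(is.na(res$beta_nti))
  expect_equal(res$beta_mntd_obs, 0)
})

test_that("RCbray hits its boundaries and stays reproducible", {
  # identical pair inside a pool of many distinct communities: obs = 0 is
  # below nearly every null draw, so RCbray ~ -1
  m <- random_table(30, 8, seed = 61, depth = 300)
  m[, 2] <- m[, 1]
  res <- raup_crick_bray(m, reps = 199, seed = 3, pairs = cbind(1, 2))
  expect_equal(res$bray_obs, 0)
  expect_lte(res$rc_bray, -0.95)
  expect_gte(res$rc_bray, -1)

  # an independently coded null sampler agrees on the verdict
  set.seed(99)
  occ <- rowSums(m > 0); ab <- rowSums(m) / sum(m)
  k <- sum(m[, 1] > 0); N <- sum(m[, 1])
  nulls <- replicate(199, {
    mk <- function() {
      sel <- sample(nrow(m), k, prob = occ)
      cnt <- numeric(nrow(m)); cnt[sel] <- 1
      cnt[sel] <- cnt[sel] + rmultinom(1, N - k, ab[sel])[, 1]
      cnt
    }
    a <- mk(); b <- mk()
    1 - 2 * sum(pmin(a, b)) / (sum(a) + sum(b))
  })
  rc_oracle <- 2 * ((sum(nulls < 0) + 0.5 * sum(nulls == 0)) / 199 - 0.5)
  expect_lte(rc_oracle, -0.95)

  # bounds, determinism, pair-order invariance
  full <- raup_crick_bray(m, reps = 99, seed = 4)
  expect_true(all(full$rc_bray >= -1 & full$rc_bray <= 1))
  expect_identical(full, raup_crick_bray(m, reps = 99, seed = 4))
  pr <- cbind(c(1, 3), c(5, 6))
  fwd <- raup_crick_bray(m, reps = 99, seed = 4, pairs = pr)
  bwd <- raup_crick_bray(m, reps = 99, seed = 4, pairs = pr[2:1, ])
  expect_equal(fwd$rc_bray, bwd$rc_bray[2:1])
  expect_error(raup_crick_bray(m, reps = 1, seed = 1), "reps")
})
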