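test_that("pairwise classification follows the two-step decision rule", {
  expect_equal(as.character(classify_pair(2.5)), "variable_selection")
  expect_equal(as.character(classify_pair(-2.5)), "homogenizing_selection")
  expect_equal(as.character(classify_pair(1.0, 0.96)), "dispersal_limitation")
  expect_equal(as.character(classify_pair(0, -0.99)), "homogenizing_dispersal")
  expect_equal(as.character(classify_pair(0, 0)), "drift")
  # boundary conventions: betaNTI exactly +/-2 falls through to RCbray,
  # RCbray exactly +/-0.95 classifies as drift
  expect_equal(as.character(classify_pair(c(2, -2), c(0.96, -0.96))),
               c("dispersal_limitation", "homogenizing_dispersal"))
  expect_equal(as.character(classify_pair(c(0, 0), c(0.95, -0.95))),
               c("drift", "drift"))
  expect_error(classify_pair(1.5), "rc_bray required")
  expect_error(classify_pair(NA_real_, 0), "NA beta_nti")
})

test_that("classification is total and mutually exclusive over the plane", {
  grid <- expand.grid(bnti = seq(-4, 4, by = 0.25),
                      rc = seq(-1, 1, by = 0.05))
  lab <- classify_pair(grid$bnti, grid$rc)
  expect_false(anyNA(lab))
  expect_setequal(levels(lab), process_levels())
  # each point maps to exactly the region its coordinates define
  det <- abs(grid$bnti) > 2
  expect_true(all(lab[det] %in% c("variable_selection", "homogenizing_selection")))
  expect_true(all(lab[!det & abs(grid$rc) <= 0.95] == "drift"))
})

test_that("module enumeration yields C(n,2) within and n1*n2 between pairs", {
  md <- data.frame(sample = paste0("S", 1:18),
                   group = rep(c("A", "B"), c(8, 10)))
  mods <- enumerate_modules(md)
  expect_equal(sum(mods$module == "A"), choose(8, 2))
  expect_equal(sum(mods$module == "B"), choose(10, 2))
  expect_equal(sum(mods$module == "A-B"), 80)

  md5 <- data.frame(sample = paste0("S", 1:48),
                    group = rep(paste0("G", 1:5), c(8, 10, 10, 10, 10)))
  mods5 <- enumerate_modules(md5)
  expect_equal(length(unique(mods5$module[mods5$type == "within"])), 5)
  expect_equal(length(unique(mods5$module[mods5$type == "between"])), choose(5, 2))
  expect_error(enumerate_modules(data.frame(sample = c("a", "b"),
                                            group = c("A", "B"))), "2 samples")
})

test_that("process fractions reproduce worked percentage examples", {
  lab45 <- rep(c("dispersal_limitation", "drift", "variable_selection"),
               c(1, 24, 20))
  fr <- process_fractions(data.frame(module = "W", label = lab45))
  expect_equal(fr$dispersal_limitation, 2.22)
  expect_equal(fr$drift, 53.33)
  expect_equal(fr$variable_selection, 44.44)
  expect_equal(fr$stochastic_total, 55.56)
  expect_equal(fr$deterministic_total, 44.44)

  lab80 <- rep(c("dispersal_limitation", "drift", "variable_selection"),
               c(47, 1, 32))
  fr80 <- process_fractions(data.frame(module = "B", label = lab80))
  expect_equal(fr80$dispersal_limitation, 58.75)
  expect_equal(fr80$drift, 1.25)
  expect_equal(fr80$variable_selection, 40.00)

  frd <- process_fractions(data.frame(module = "D", label = rep("drift", 10)))
  expect_equal(frd$drift, 100)
  expect_equal(frd$deterministic_total, 0)
})

test_that("fractions always sum to 100 within rounding slack", {
  set.seed(77)
  for (i in 1:25) {
    n <- sample(5:120, 1)
    lab <- sample(process_levels(), n, replace = TRUE)
    fr <- process_fractions(data.frame(module = "M", label = lab))
    expect_lt(abs(sum(unlist(fr[process_levels()])) - 100), 0.025)
    expect_lt(abs(fr$stochastic_total + fr$deterministic_total - 100), 0.021)
  }
})

test_that("undefined pairs shrink the denominator instead of being guessed", {
  df <- data.frame(module = "M",
                   label = c("drift", "drift", NA, "variable_selection"))
  expect_message(fr <- process_fractions(df), "excluding 1")
  expect_equal(fr$n_pairs, 3)
  expect_equal(fr$drift, round(100 * 2 / 3, 2))
})

test_that("published contribution rates decompose into integer pair counts", {
  ref <- reference_process_fractions()
  cnt <- implied_pair_counts(ref)
  expect_equal(nrow(cnt), 15)
  within <- !grepl("-", cnt$module)
  expect_equal(sort(unique(cnt$n_pairs[within])), c(28, 45))
  expect_true(all(cnt$n_pairs[!within] %in% c(80, 100)))
  # counts sum back to the module pair count, except one published row
  # (CF2550-DBF1780) whose printed percentages total 107% — an
  # inconsistency in the source table that the decomposition exposes
  sums <- rowSums(cnt[, intersect(process_levels(), names(cnt))])
  bad <- cnt$module == "CF2550-DBF1780"
  expect_equal(sums[!bad], cnt$n_pairs[!bad])
  expect_equal(unname(sums[bad] - cnt$n_pairs[bad]), 7)
})

test_that("the full driver classifies and aggregates coherently", {
  set.seed(88)
  sc <- assembly_scenario("selection", n_taxa = 40, n_groups = 2,
                          samples_per_group = 4, depth = 500, seed = 5)
  sim <- simulate_table(sc)
  q <- suppressWarnings(quantify_assembly(sim$table, sim$tree, sim$metadata,
                                          reps = 49, seed = 6))
  expect_s3_class(q, "assembly_quantification")
  expect_equal(nrow(q$pairs), choose(8, 2))
  expect_setequal(unique(q$pairs$module), c("G1", "G2", "G1-G2"))
  # RCbray computed exactly where the betaNTI gate requires it
  need <- !is.na(q$pairs$beta_nti) & abs(q$pairs$beta_nti) <= 2
  expect_true(all(!is.na(q$pairs$rc_bray[need])))
  expect_true(all(is.na(q$pairs$rc_bray[!need])))
  expect_equal(sum(q$fractions$n_pairs), sum(!is.na(q$pairs$label)))
})
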