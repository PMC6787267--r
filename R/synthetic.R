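#' Define a synthetic community-assembly scenario
#'
#' Parameters of the generator that emulates the study design the null
#' models are meant to resolve: several groups of samples along a
#' gradient, a shared regional species pool with log-normal base
#' abundances, a phylogeny whose tips carry a Brownian (phylogenetically
#' conserved) trait, and one generative regime controlling how group
#' composition departs from the pool.
#'
#' Regimes:
#' \describe{
#'   \item{selection}{each group applies a Gaussian environmental filter
#'     in trait space, centred on its `env` value with width `sigma`;
#'     groups with distant `env` favour different clades.}
#'   \item{drift}{all samples share the pool composition but each sample's
#'     relative abundances are jittered by independent log-normal noise of
#'     scale `drift_noise` before multinomial sampling, emulating
#'     demographic stochasticity around a shared metacommunity.}
#'   \item{dispersal_limitation}{each group only receives a random subset
#'     (fraction `dispersal_keep`) of the pool before sampling, plus the
#'     drift jitter; subsets are independent between groups.}
#'   \item{homogenizing_dispersal}{every sample is a multinomial draw from
#'     one tight shared composition (no jitter), emulating mass effects.}
#' }
#'
#' @param regime one of `"selection"`, `"drift"`, `"dispersal_limitation"`,
#'   `"homogenizing_dispersal"`.
#' @param n_taxa taxa in the regional pool.
#' @param n_groups number of sample groups along the gradient.
#' @param samples_per_group samples per group.
#' @param depth reads per sample (every generated column sums to this).
#' @param trait_rate Brownian-motion variance per unit branch length.
#' @param env per-group environmental optimum in standardized trait units;
#'   default evenly spaced on \[-1.5, 1.5\].
#' @param sigma width of the Gaussian trait filter (selection regime).
#' @param dispersal_keep fraction of pool taxa each group receives under
#'   dispersal limitation.
#' @param drift_noise sd of the log-normal per-sample abundance jitter
#'   (applied under the drift and dispersal-limitation regimes).
#' @param pool_sdlog sd of the log-normal base-abundance distribution of
#'   the regional pool; microbial OTU abundances are strongly uneven, and
#'   this unevenness is what lets occupancy-weighted Raup-Crick nulls
#'   discriminate convergent from divergent assembly.
#' @param seed integer seed; recorded in the output.
#' @return list of class `"assembly_scenario"`.
#' @export
assembly_scenario <- function(regime = c("selection", "drift",
                                         "dispersal_limitation",
                                         "homogenizing_dispersal"),
                              n_taxa = 150, n_groups = 2,
                              samples_per_group = 8, depth = 10000,
                              trait_rate = 1, env = NULL, sigma = 0.5,
                              dispersal_keep = 0.45, drift_noise = 0.2,
                              pool_sdlog = 1.4, seed = 1) {
  regime <- match.arg(regime)
  if (n_taxa < 2 || n_groups < 1 || samples_per_group < 1 || depth < 1)
    stop("all sizes must be >= 1 (n_taxa >= 2)")
  if (regime == "selection" && sigma <= 0)
    stop("sigma must be > 0 under the selection regime")
  if (is.null(env))
    env <- if (n_groups == 1) 0 else seq(-1.5, 1.5, length.out = n_groups)
  if (length(env) != n_groups) stop("env must have one value per group")
  structure(list(regime = regime, n_taxa = n_taxa, n_groups = n_groups,
                 samples_per_group = samples_per_group, depth = depth,
                 trait_rate = trait_rate, env = env, sigma = sigma,
                 dispersal_keep = dispersal_keep, drift_noise = drift_noise,
                 pool_sdlog = pool_sdlog, seed = seed),
            class = "assembly_scenario")
}

#' Simulate a pure-birth (Yule) phylogeny
#'
#' Yule tree with `n_taxa` tips via [ape::rphylo()] (birth 1, death 0),
#' branch lengths rescaled to unit mean, tips labelled `OTU_1..OTU_n`.
#' Deterministic for a given seed.
#'
#' @param n_taxa number of tips (>= 2).
#' @param seed integer seed.
#' @return a `phylo` object.
#' @export
simulate_tree <- function(n_taxa, seed = 1) {
  if (n_taxa < 2) stop("n_taxa must be >= 2")
  set.seed(mix_seed(seed))
  tree <- ape::rphylo(n_taxa, birth = 1, death = 0)
  tree$edge.length <- tree$edge.length / mean(tree$edge.length)
  tree$tip.label <- paste0("OTU_", seq_len(n_taxa))
  tree
}

#' Simulate a Brownian-motion trait on a phylogeny
#'
#' Trait evolves from a root value of 0 with variance `rate` per unit
#' branch length ([ape::rTraitCont()]), so two tips covary in proportion
#' to their shared path length — the phylogenetic signal the betaNTI null
#' model needs to detect selection.
#'
#' @param tree a `phylo` with branch lengths.
#' @param rate Brownian variance per unit branch length (> 0).
#' @param seed integer seed.
#' @return named numeric vector of tip trait values.
#' @export
simulate_traits <- function(tree, rate = 1, seed = 1) {
  if (rate <= 0) stop("rate must be > 0")
  set.seed(mix_seed(seed))
  ape::rTraitCont(tree, model = "BM", sigma = sqrt(rate), root.value = 0)
}

#' Simulate a community table under a known assembly regime
#'
#' Generates the full synthetic data set for a scenario: phylogeny,
#' Brownian trait, log-normal base abundances, and multinomial sampling of
#' `depth` reads per sample under the scenario's regime (see
#' [assembly_scenario()] for the generative laws). Deterministic for the
#' scenario seed.
#'
#' @param scenario an [assembly_scenario()].
#' @param tree optional pre-built `phylo` (default: simulated from the
#'   scenario seed).
#' @param traits optional named per-tip trait vector (default: simulated).
#' @return list of class `"synthetic_community"`: `table` (a
#'   [community_table()], taxa x samples, columns summing to `depth`),
#'   `metadata` (sample, group, elevation, env), `tree`, `traits`,
#'   `scenario`, and `truth` (the generative regime label).
#' @export
simulate_table <- function(scenario, tree = NULL, traits = NULL) {
  stopifnot(inherits(scenario, "assembly_scenario"))
  s <- scenario
  if (is.null(tree)) tree <- simulate_tree(s$n_taxa, mix_seed(s$seed, 101))
  if (length(tree$tip.label) != s$n_taxa)
    stop("tree tip count does not match scenario n_taxa")
  if (is.null(traits)) traits <- simulate_traits(tree, s$trait_rate,
                                                 mix_seed(s$seed, 102))
  traits <- traits[tree$tip.label]
  z <- as.numeric(scale(traits))   # standardized trait, env is on this scale

  set.seed(mix_seed(s$seed, 103))
  base <- stats::rlnorm(s$n_taxa, meanlog = 0, sdlog = s$pool_sdlog)
  base <- base / sum(base)

  groups <- paste0("G", seq_len(s$n_groups))
  elev <- if (s$n_groups == 1) 1000 else seq(1000, 2800, length.out = s$n_groups)

  set.seed(mix_seed(s$seed, 104))
  group_keep <- lapply(seq_len(s$n_groups), function(g) {
    if (s$regime != "dispersal_limitation") return(seq_len(s$n_taxa))
    sort(sample.int(s$n_taxa, max(2L, round(s$dispersal_keep * s$n_taxa))))
  })

  counts <- matrix(0, s$n_taxa, s$n_groups * s$samples_per_group,
                   dimnames = list(tree$tip.label, NULL))
  ids <- character(ncol(counts))
  meta_group <- character(ncol(counts))
  col <- 0L
  for (g in seq_len(s$n_groups)) {
    w_group <- base
    if (s$regime == "selection")
      w_group <- base * exp(-(z - s$env[g])^2 / (2 * s$sigma^2))
    if (s$regime == "dispersal_limitation") {
      mask <- numeric(s$n_taxa); mask[group_keep[[g]]] <- 1
      w_group <- base * mask
    }
    for (i in seq_len(s$samples_per_group)) {
      col <- col + 1L
      w <- w_group
      if (s$regime %in% c("drift", "dispersal_limitation"))
        w <- w * exp(stats::rnorm(s$n_taxa, 0, s$drift_noise))
      counts[, col] <- stats::rmultinom(1, s$depth, w / sum(w))[, 1]
      ids[col] <- sprintf("%s_S%02d", groups[g], i)
      meta_group[col] <- groups[g]
    }
  }
  colnames(counts) <- ids
  metadata <- data.frame(sample = ids, group = meta_group,
                         elevation = elev[match(meta_group, groups)],
                         env = s$env[match(meta_group, groups)],
                         stringsAsFactors = FALSE)
  list(table = community_table(counts), metadata = metadata, tree = tree,
       traits = traits, scenario = s, truth = s$regime) |>
    structure(class = "synthetic_community")
}

#' @export
print.synthetic_community <- function(x, ...) {
  s <- x$scenario
  cat(sprintf("Synthetic community (regime: %s): %d taxa, %d groups x %d samples, depth %d, seed %d\n",
              s$regime, s$n_taxa, s$n_groups, s$samples_per_group, s$depth, s$seed))
  invisible(x)
}
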