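#' Process labels
#'
#' The five ecological processes a pairwise comparison can be assigned to.
#' "drift" aggregates what part of the literature calls "undominated":
#' drift acting alone together with weak, non-dominant selection and
#' dispersal.
#'
#' @return character vector of the five labels, in canonical order.
#' @export
process_levels <- function() {
  c("variable_selection", "homogenizing_selection",
    "dispersal_limitation", "homogenizing_dispersal", "drift")
}

#' Classify pairwise turnover into an ecological process
#'
#' Two-step decision rule. betaNTI > +2: variable selection;
#' betaNTI < -2: homogenizing selection. Otherwise the pair is passed to
#' RCbray: > +0.95 dispersal limitation, < -0.95 homogenizing dispersal,
#' and |RCbray| <= 0.95 drift. Boundary values (betaNTI exactly +/-2 and
#' RCbray exactly +/-0.95) fall to the stochastic side of each inequality;
#' both events have measure zero in practice.
#'
#' @param beta_nti numeric vector of betaNTI values.
#' @param rc_bray numeric vector of RCbray values, required (non-NA)
#'   wherever |beta_nti| <= 2; may be NA/omitted elsewhere.
#' @return factor of process labels, levels [process_levels()].
#' @examples
#' classify_pair(c(2.5, -2.5, 1, 0), c(NA, NA, 0.96, 0))
#' @export
classify_pair <- function(beta_nti, rc_bray = NULL) {
  n <- length(beta_nti)
  if (is.null(rc_bray)) rc_bray <- rep(NA_real_, n)
  if (length(rc_bray) != n) stop("beta_nti and rc_bray lengths differ")
  if (anyNA(beta_nti)) stop("NA beta_nti; exclude undefined pairs before classification")
  need_rc <- abs(beta_nti) <= 2
  if (any(need_rc & is.na(rc_bray)))
    stop("rc_bray required when |beta_nti| <= 2")
  lab <- ifelse(beta_nti > 2, "variable_selection",
         ifelse(beta_nti < -2, "homogenizing_selection",
         ifelse(rc_bray > 0.95, "dispersal_limitation",
         ifelse(rc_bray < -0.95, "homogenizing_dispersal", "drift"))))
  factor(lab, levels = process_levels())
}

#' Enumerate within-group and between-group comparison modules
#'
#' A module is either one group (all unordered sample pairs inside it,
#' C(n, 2) pairs) or an ordered pair of groups (all cross pairs, n1 x n2).
#' Groups are taken in their order of first appearance in `metadata`.
#'
#' @param metadata data.frame with `sample` and `group` columns.
#' @return data.frame with one row per pair: `module`, `type`
#'   (`"within"`/`"between"`), `sample_1`, `sample_2`.
#' @export
enumerate_modules <- function(metadata) {
  if (!all(c("sample", "group") %in% names(metadata)))
    stop("metadata must contain 'sample' and 'group' columns")
  groups <- unique(metadata$group)
  sizes <- table(metadata$group)[groups]
  if (any(sizes < 2))
    stop("within-group modules need >= 2 samples per group; offending group(s): ",
         paste(groups[sizes < 2], collapse = ", "))
  rows <- list()
  for (g in groups) {
    s <- metadata$sample[metadata$group == g]
    p <- pair_index(length(s))
    rows[[length(rows) + 1L]] <- data.frame(
      module = g, type = "within",
      sample_1 = s[p[, 1]], sample_2 = s[p[, 2]],
      stringsAsFactors = FALSE)
  }
  if (length(groups) > 1) {
    gp <- pair_index(length(groups))
    for (k in seq_len(nrow(gp))) {
      g1 <- groups[gp[k, 1]]; g2 <- groups[gp[k, 2]]
      s1 <- metadata$sample[metadata$group == g1]
      s2 <- metadata$sample[metadata$group == g2]
      grid <- expand.grid(a = s1, b = s2, stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        module = paste(g1, g2, sep = "-"), type = "between",
        sample_1 = grid$a, sample_2 = grid$b,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Per-module process contribution rates
#'
#' Converts per-pair process labels into the familiar contribution-rate
#' table: for each module, the percentage of pairs assigned to each of the
#' five processes, plus stochastic (dispersal limitation + homogenizing
#' dispersal + drift) and deterministic (variable + homogenizing
#' selection) totals. Percentages are rounded half-up to 2 decimals; the
#' totals are computed from the raw counts and then rounded, so they are
#' not a sum of already-rounded parts.
#'
#' @param pairs data.frame with columns `module` and `label` (a factor or
#'   character of process labels); rows with `NA` labels (undefined
#'   betaNTI) are excluded from the denominator with a message.
#' @return data.frame with one row per module: `module`, `n_pairs`, one
#'   percentage column per process, `stochastic_total`,
#'   `deterministic_total`.
#' @export
process_fractions <- function(pairs) {
  if (!all(c("module", "label") %in% names(pairs)))
    stop("pairs must contain 'module' and 'label' columns")
  if (nrow(pairs) == 0L) stop("empty module set")
  drop <- is.na(pairs$label)
  if (any(drop)) {
    message(sprintf("excluding %d pair(s) with undefined betaNTI", sum(drop)))
    pairs <- pairs[!drop, , drop = FALSE]
  }
  lab <- factor(as.character(pairs$label), levels = process_levels())
  if (anyNA(lab)) stop("unknown process label(s)")
  modules <- unique(pairs$module)
  out <- lapply(modules, function(mod) {
    l <- lab[pairs$module == mod]
    n <- length(l)
    if (n == 0L) stop("empty module: ", mod)
    cnt <- table(l)
    pct <- round_half_up(100 * as.numeric(cnt) / n, 2)
    names(pct) <- names(cnt)
    sto <- sum(cnt[c("dispersal_limitation", "homogenizing_dispersal", "drift")])
    det <- sum(cnt[c("variable_selection", "homogenizing_selection")])
    df <- data.frame(module = mod, n_pairs = n, stringsAsFactors = FALSE)
    for (p in process_levels()) df[[p]] <- pct[[p]]
    df$stochastic_total <- round_half_up(100 * sto / n, 2)
    df$deterministic_total <- round_half_up(100 * det / n, 2)
    df
  })
  do.call(rbind, out)
}

#' Quantify community assembly processes along a gradient
#'
#' End-to-end driver: enumerates within- and between-group modules from
#' the metadata, computes betaNTI for every pair against the tip-shuffling
#' null, computes RCbray for the pairs with |betaNTI| <= 2, classifies
#' each pair into one of the five ecological processes, and aggregates
#' per-module contribution rates.
#'
#' @param table a [community_table()] (ideally rarefied) aligned to `tree`.
#' @param tree rooted `phylo` with branch lengths covering the table taxa.
#' @param metadata data.frame with `sample` and `group` columns covering
#'   all table samples.
#' @param reps null replicates for both null models (default 999).
#' @param seed integer seed.
#' @return an object of class `"assembly_quantification"`: a list with
#'   `pairs` (per-pair betaNTI, RCbray and process label) and `fractions`
#'   (per-module contribution rates), plus `reps` and `seed`.
#' @export
quantify_assembly <- function(table, tree, metadata, reps = 999, seed = 1) {
  m <- as_count_matrix(table)
  if (!all(colnames(m) %in% metadata$sample))
    stop("metadata missing for sample(s): ",
         paste(setdiff(colnames(m), metadata$sample), collapse = ", "))
  metadata <- metadata[match(colnames(m), metadata$sample), , drop = FALSE]
  mods <- enumerate_modules(metadata)
  pr <- cbind(match(mods$sample_1, colnames(m)),
              match(mods$sample_2, colnames(m)))
  bnti <- null_beta_nti(m, tree, reps = reps, seed = seed, pairs = pr)
  res <- cbind(mods, bnti[, c("beta_mntd_obs", "null_mean", "null_sd",
                              "beta_nti", "n_null")])
  res$rc_bray <- NA_real_
  need_rc <- !is.na(res$beta_nti) & abs(res$beta_nti) <= 2
  if (any(need_rc)) {
    rc <- raup_crick_bray(m, reps = reps, seed = seed,
                          pairs = pr[need_rc, , drop = FALSE])
    res$rc_bray[need_rc] <- rc$rc_bray
  }
  res$label <- factor(NA_character_, levels = process_levels())
  ok <- !is.na(res$beta_nti)
  res$label[ok] <- classify_pair(res$beta_nti[ok], res$rc_bray[ok])
  structure(list(pairs = res,
                 fractions = process_fractions(res),
                 reps = reps, seed = seed),
            class = "assembly_quantification")
}

#' @export
print.assembly_quantification <- function(x, ...) {
  cat(sprintf("Assembly process quantification: %d pairs, %d modules (%d null reps)\n",
              nrow(x$pairs), nrow(x$fractions), x$reps))
  print(x$fractions, row.names = FALSE)
  invisible(x)
}

#' @export
summary.assembly_quantification <- function(object, ...) {
  lab <- object$pairs$label
  cat("Per-pair process counts:\n")
  print(table(lab, useNA = "ifany"))
  cat(sprintf("betaNTI range: [%.2f, %.2f]\n",
              min(object$pairs$beta_nti, na.rm = TRUE),
              max(object$pairs$beta_nti, na.rm = TRUE)))
  invisible(object$fractions)
}

#' @export
plot.assembly_quantification <- function(x, ...) {
  fr <- x$fractions
  m <- t(as.matrix(fr[, process_levels()]))
  colnames(m) <- fr$module
  op <- graphics::par(mar = c(7, 4, 2, 8), xpd = TRUE)
  on.exit(graphics::par(op))
  graphics::barplot(m, las = 2, col = grDevices::hcl.colors(5, "Zissou 1"),
                    ylab = "% of pairs", ...)
  graphics::legend("topright", inset = c(-0.35, 0), legend = rownames(m),
                   fill = grDevices::hcl.colors(5, "Zissou 1"), cex = 0.7, bty = "n")
  invisible(x)
}
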