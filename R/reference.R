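#' Published process-contribution rates for a soil-fungal elevational gradient
#'
#' Contribution rates of the five assembly processes reported for soil
#' fungal communities across five forest types on an elevational gradient
#' (Shennongjia, China; within-site and between-site modules, group sizes
#' 8/10/10/10/10 plots). Used as a worked arithmetic example: every
#' printed percentage should be an integer count of pairs divided by the
#' module's pair count, which [process_fractions()] reproduces.
#'
#' The published table carries no homogenizing-dispersal column (no pair
#' was assigned that process); it is implicitly 0 throughout.
#'
#' @return data.frame with one row per module: `module`, `n_pairs`, the
#'   published percentage for each process, and the published stochastic
#'   and deterministic totals.
#' @export
reference_process_fractions <- function() {
  path <- system.file("extdata", "shennongjia_process_fractions.tsv",
                      package = "ecoassembly", mustWork = TRUE)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  df$homogenizing_dispersal <- 0
  df
}

#' Integer pair counts implied by published contribution rates
#'
#' Reverses the percentage arithmetic: for each module, the per-process
#' percentage times the module's pair count must be (within printing
#' precision) an integer number of pairs.
#'
#' @param fractions a data.frame as returned by
#'   [reference_process_fractions()].
#' @return data.frame of integer counts per module and process, plus
#'   `n_pairs`.
#' @export
implied_pair_counts <- function(fractions = reference_process_fractions()) {
  procs <- intersect(process_levels(), names(fractions))
  out <- fractions[, c("module", "n_pairs")]
  for (p in procs) {
    raw <- fractions[[p]] * fractions$n_pairs / 100
    cnt <- round(raw)
    if (any(abs(raw - cnt) > 0.01 * fractions$n_pairs / 100 + 1e-9))
      stop("percentage not consistent with an integer pair count in process ", p)
    out[[p]] <- as.integer(cnt)
  }
  out
}
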