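#' Construct and validate a community table
#'
#' A community table is an integer matrix of sequence counts with taxa
#' (OTUs) as rows and samples as columns — the canonical orientation used
#' throughout the package. Row and column names are the taxon and sample
#' identifiers and must be unique.
#'
#' @param counts numeric matrix of non-negative integer counts, taxa x
#'   samples, with unique dimnames.
#' @return the validated matrix with class `"community_table"` prepended.
#' @examples
#' m <- matrix(c(1, 2, 3, 4), 2, 2,
#'             dimnames = list(c("OTU_1", "OTU_2"), c("S1", "S2")))
#' community_table(m)
#' @export
community_table <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) == 0L) stop("no taxa in community table")
  if (ncol(counts) == 0L) stop("no samples in community table")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("community table requires taxon row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate taxon identifiers: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (any(!is.finite(counts))) stop("non-finite counts in community table")
  if (any(counts < 0)) stop("negative counts in community table")
  bad <- which(counts != floor(counts), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-integer count %s at taxon '%s', sample '%s'",
                 format(counts[bad[1, 1], bad[1, 2]]),
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  }
  storage.mode(counts) <- "double"
  class(counts) <- c("community_table", class(counts))
  counts
}

# Accept a community_table or a plain taxa x samples matrix; validate lightly.
as_count_matrix <- function(table) {
  m <- unclass(as.matrix(table))
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("community table requires taxon row names and sample column names")
  m
}

#' @export
print.community_table <- function(x, ...) {
  cat(sprintf("Community table: %d taxa x %d samples, %s reads total\n",
              nrow(x), ncol(x), format(sum(x), big.mark = ",")))
  invisible(x)
}

#' Read a community (OTU) table from tab-separated text
#'
#' Reads the classic QIIME-style tab-separated table: one header row, one
#' identifier column (conventionally `#OTU_ID`), integer counts. Either
#' orientation on disk is accepted; the result is always returned in the
#' canonical taxa-rows orientation.
#'
#' @param path file path to a TSV table.
#' @param orientation `"taxa_rows"` (default) if rows on disk are taxa,
#'   `"samples_rows"` if rows are samples.
#' @return a [community_table()].
#' @export
read_community_table <- function(path, orientation = c("taxa_rows", "samples_rows")) {
  orientation <- match.arg(orientation)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          comment.char = "", stringsAsFactors = FALSE,
                          fill = FALSE, colClasses = "character")
  if (nrow(df) == 0L)
    stop(if (orientation == "taxa_rows") "no taxa in community table"
         else "no samples in community table")
  if (ncol(df) < 2L) stop("community table needs an identifier column and at least one data column")
  ids <- df[[1]]
  vals <- df[, -1, drop = FALSE]
  num <- suppressWarnings(vapply(vals, as.numeric, numeric(nrow(vals))))
  num <- matrix(num, nrow = nrow(vals),
                dimnames = list(ids, colnames(vals)))
  bad <- which(is.na(num) | num != floor(num), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-integer count '%s' at row '%s', column '%s'",
                 vals[bad[1, 1], bad[1, 2]], ids[bad[1, 1]],
                 colnames(vals)[bad[1, 2]]))
  }
  if (orientation == "samples_rows") num <- t(num)
  community_table(num)
}

#' Write a community table as tab-separated text
#'
#' Canonical on-disk form: taxa as rows, samples as columns, identifier
#' column headed `#OTU_ID`. `read_community_table()` of the written file
#' reproduces the table exactly.
#'
#' @param table a [community_table()] or taxa x samples count matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_community_table <- function(table, path) {
  m <- as_count_matrix(table)
  df <- data.frame("#OTU_ID" = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogeny with branch lengths
#'
#' Thin wrapper around [ape::read.tree()] that enforces what the
#' phylogenetic null models require: a rooted tree, unique tip labels, and
#' non-negative branch lengths on every edge.
#'
#' @param path newick file path.
#' @return an [ape::read.tree()] `phylo` object.
#' @export
read_phylogeny <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick tree from ", path)
  validate_phylogeny(tree)
}

# Shared tree checks for file input and in-memory trees.
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' tree")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (is.null(tree$edge.length) || length(tree$edge.length) != nrow(tree$edge) ||
      anyNA(tree$edge.length))
    stop("tree is missing branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  if (!ape::is.rooted(tree)) stop("tree is not rooted")
  tree
}

#' Align a community table with a phylogeny
#'
#' Taxa present in the tree but absent from the table are ignored (the tree
#' may be a supertree). Taxa present in the table but absent from the tree
#' would silently bias betaMNTD, so they are an error unless
#' `allow_prune = TRUE`, in which case they are dropped with a warning.
#'
#' @param table a [community_table()] or taxa x samples matrix.
#' @param tree a `phylo` object.
#' @param allow_prune drop table taxa missing from the tree instead of
#'   raising an error.
#' @return the (possibly subset) community table, taxa ordered as before.
#' @export
align_table_and_tree <- function(table, tree, allow_prune = FALSE) {
  m <- as_count_matrix(table)
  missing <- setdiff(rownames(m), tree$tip.label)
  keep <- intersect(rownames(m), tree$tip.label)
  if (length(keep) == 0L) stop("no taxa shared between table and tree")
  if (length(missing) > 0L) {
    if (!allow_prune)
      stop("taxa absent from the tree: ", paste(missing, collapse = ", "),
           " (set allow_prune = TRUE to drop them)")
    warning(sprintf("dropping %d table taxa absent from the tree", length(missing)))
    m <- m[keep, , drop = FALSE]
  }
  community_table(m)
}

#' Read a sample metadata table
#'
#' Tab-separated metadata with one row per sample. Must contain columns
#' `sample` and `group`; `elevation` (meters) and any environmental
#' covariates are carried through unchanged.
#'
#' @param path TSV file path.
#' @return a `data.frame` with one row per sample.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(df)))
    stop("metadata must contain 'sample' and 'group' columns")
  if (anyDuplicated(df$sample))
    stop("duplicate sample identifiers in metadata")
  if (any(is.na(df$group) | !nzchar(df$group)))
    stop("empty group labels in metadata")
  df
}

#' Write a sample metadata or result table
#'
#' Tab-separated, single header row, no quoting; numeric columns are
#' written with up to 6 significant digits.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(df, path) {
  out <- df
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) signif(x, 6))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BIOM 1.0 (JSON) community table
#'
#' Requires the `biomformat` package. The table is returned in the
#' canonical taxa-rows orientation.
#'
#' @param path BIOM JSON file path.
#' @return a [community_table()].
#' @export
read_biom_table <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("reading BIOM files requires the 'biomformat' package")
  b <- biomformat::read_biom(path)
  m <- as(biomformat::biom_data(b), "matrix")
  community_table(m)
}
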