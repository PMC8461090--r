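# Count-table, tree and metadata input/output plus rarefaction and
# relative-abundance transforms.

MEMBRANE_LEVELS <- c("POX", "PTA", "SPTA", "SPSU", "COM", "MLSS")
SURFACE_LEVELS  <- c("hydrophobic", "hydrophilic", "n/a")
FLUX_LEVELS     <- c("flux", "no-flux", "n/a")
DAY_LEVELS      <- c(1L, 10L, 20L, 30L)
COMPARTMENT_LEVELS <- c("biofilm", "MLSS")
NUCLEIC_LEVELS  <- c("DNA", "cDNA")

#' Validate a community count table
#'
#' A community table is a numeric matrix of nonnegative integer counts with
#' samples as rows and taxa as columns, both carrying unique identifiers as
#' dimnames.
#'
#' @param counts numeric matrix, samples x taxa, with dimnames.
#' @return the validated matrix (in storage mode integer-compatible double
#'   or integer), invisibly unchanged.
#' @export
validate_community_table <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("community table must be a numeric matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("community table must have sample (row) and taxon (column) names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate taxon ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf(
      "non-integer or negative count at sample '%s', taxon '%s'",
      rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  counts
}

#' Read a count table from tab-separated text
#'
#' By disk convention taxa are rows and samples are columns (the common
#' amplicon layout); the returned matrix is always oriented samples x taxa.
#'
#' @param path path to a tab-separated file with a header row; the first
#'   column holds row identifiers.
#' @param taxa_as_rows logical; `TRUE` (default) if rows on disk are taxa.
#' @return validated count matrix, samples x taxa.
#' @export
read_count_table <- function(path, taxa_as_rows = TRUE) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("count table contains non-numeric cells")
  rownames(m) <- ids
  if (taxa_as_rows) m <- t(m)
  storage.mode(m) <- "double"
  validate_community_table(m)
}

#' Write a count table as tab-separated text
#'
#' @param table samples x taxa count matrix.
#' @param path output path.
#' @param taxa_as_rows write taxa as rows (default, the disk convention).
#' @export
write_count_table <- function(table, path, taxa_as_rows = TRUE) {
  validate_community_table(table)
  m <- if (taxa_as_rows) t(table) else table
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- if (taxa_as_rows) "taxon_id" else "sample_id"
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogenetic tree from a newick file
#'
#' @param path newick file.
#' @param taxa optional character vector of taxon ids that must all be tip
#'   labels; missing ones raise an error listing them.
#' @return an `ape::phylo` tree.
#' @export
read_tree <- function(path, taxa = NULL) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse a tree from ", path)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("tree has negative branch lengths")
  check_tree_covers(tree, taxa)
  tree
}

check_tree_covers <- function(tree, taxa) {
  if (is.null(taxa)) return(invisible(TRUE))
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing) > 0)
    stop("taxa missing from tree: ", paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Write a tree to a newick file
#' @param tree an `ape::phylo` object.
#' @param path output path.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Expects tab-separated columns `sample_id`, `membrane_type`,
#' `surface_character`, `flux`, `day`, `compartment`, `nucleic`, with factor
#' levels restricted to the study design enumerations.
#'
#' @param path tab-separated file with header.
#' @return a data.frame with validated columns.
#' @export
read_sample_metadata <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_sample_metadata(df)
}

#' Validate sample metadata levels
#' @param df metadata data.frame.
#' @return the data.frame with `day` as integer.
#' @export
validate_sample_metadata <- function(df) {
  required <- c("sample_id", "membrane_type", "surface_character", "flux",
                "day", "compartment", "nucleic")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("metadata missing columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in metadata")
  chk <- function(col, levels) {
    bad <- setdiff(unique(as.character(df[[col]])), as.character(levels))
    if (length(bad) > 0)
      stop(sprintf("invalid %s level(s): %s", col, paste(bad, collapse = ", ")))
  }
  chk("membrane_type", MEMBRANE_LEVELS)
  chk("surface_character", SURFACE_LEVELS)
  chk("flux", FLUX_LEVELS)
  chk("day", DAY_LEVELS)
  chk("compartment", COMPARTMENT_LEVELS)
  chk("nucleic", NUCLEIC_LEVELS)
  df$day <- as.integer(df$day)
  df
}

#' Rarefy a count table to an even depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric draw) to a common depth. Samples whose total falls below
#' the target depth are dropped with a warning, mirroring standard practice
#' of excluding under-sequenced samples rather than failing.
#'
#' @param table samples x taxa count matrix.
#' @param depth target reads per sample (>= 1).
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return rarefied count matrix whose rows each sum exactly to `depth`;
#'   attribute `"dropped"` lists excluded sample ids.
#' @export
rarefy_counts <- function(table, depth, seed = 1L) {
  validate_community_table(table)
  if (length(depth) != 1 || depth < 1 || depth != round(depth))
    stop("depth must be a positive integer")
  totals <- rowSums(table)
  keep <- totals >= depth
  if (!any(keep)) stop("all samples have fewer than ", depth, " reads")
  if (any(!keep))
    warning("dropping ", sum(!keep), " sample(s) below depth ", depth, ": ",
            paste(rownames(table)[!keep], collapse = ", "))
  kept <- table[keep, , drop = FALSE]
  out <- with_seed_(seed, suppressWarnings(vegan::rrarefy(kept, depth)))
  storage.mode(out) <- "double"
  dimnames(out) <- dimnames(kept)
  attr(out, "dropped") <- rownames(table)[!keep]
  out
}

#' Convert counts to relative abundances
#'
#' @param table samples x taxa count matrix with strictly positive row sums.
#' @return matrix of proportions; every row sums to 1.
#' @export
relative_abundance <- function(table) {
  totals <- rowSums(table)
  zero <- totals <= 0
  if (any(zero))
    stop("zero-sum sample(s): ",
         paste(rownames(table)[zero], collapse = ", "))
  sweep(table, 1, totals, "/")
}
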