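#' Read a rooted binary phylogeny from a newick file
#'
#' Wraps [ape::read.tree()]. Polytomies are an error unless
#' `resolve_polytomies = TRUE`, in which case they are resolved into
#' zero-length splits via [ape::multi2di()]. Zero-length (or missing) branch
#' lengths are replaced by `epsilon` with a warning, so that contrasts are
#' always well defined.
#'
#' @param path newick file
#' @param resolve_polytomies resolve multifurcations instead of failing
#' @param epsilon replacement for zero-length branches
#' @return an [ape::phylo] tree
#' @export
read_newick <- function(path, resolve_polytomies = FALSE, epsilon = 1e-8) {
  if (!file.exists(path)) stop("file not found: ", path)
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick: ", path)
  if (!ape::is.binary(tree) || !ape::is.rooted(tree)) {
    if (!resolve_polytomies)
      stop("polytomy in tree; independent contrasts require a rooted binary ",
           "tree (set resolve_polytomies = TRUE to split with zero-length ",
           "branches)")
    tree <- ape::multi2di(tree)
  }
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  if (any(tree$edge.length <= 0)) {
    warning("zero-length branch(es) replaced by epsilon = ", epsilon)
    tree$edge.length[tree$edge.length <= 0] <- epsilon
  }
  tree
}

#' Read an orthogroup membership table
#'
#' @param path TSV with columns orthogroup_id, gene_id, species_id
#' @return data.frame
#' @export
read_orthogroups <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("orthogroup_id", "gene_id", "species_id")
  if (!all(need %in% names(df)))
    stop("orthogroup table requires columns: ", paste(need, collapse = ", "))
  df
}

#' Read a species-to-clade ladder mapping
#'
#' @param path TSV with columns species_id, most_specific_clade
#' @return data.frame
#' @export
read_ladder <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("species_id", "most_specific_clade")
  if (!all(need %in% names(df)))
    stop("ladder table requires columns: ", paste(need, collapse = ", "))
  df
}

#' Read a miRNA copy-number matrix
#'
#' @param path TSV, first column `accession`, remaining columns one per species
#' @return integer matrix with accession rownames
#' @export
read_copy_number <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  if (any(m < 0, na.rm = TRUE)) stop("copy numbers must be non-negative")
  m
}

# small TSV writer used throughout
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
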