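#' Read a FASTA file into a named character vector
#'
#' Thin wrapper around [Biostrings::readBStringSet()] with strict checks:
#' duplicate identifiers and empty records are hard errors. Sequences are
#' uppercased and normalized to the requested alphabet (`"dna"` stores T,
#' `"rna"` stores U).
#'
#' @param path FASTA file
#' @param alphabet `"dna"` or `"rna"`
#' @return named character vector of sequences, input order preserved
#' @export
read_fasta <- function(path, alphabet = c("dna", "rna")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate identifier in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(Biostrings::width(set) == 0))
    stop("empty record in ", path, ": ",
         paste(ids[Biostrings::width(set) == 0], collapse = ", "))
  seqs <- as.character(set)
  seqs <- if (alphabet == "dna") as_dna(seqs) else as_rna(seqs)
  names(seqs) <- ids
  seqs
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs named character vector
#' @param path output file
#' @param width line width for wrapping
#' @return `path`, invisibly
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("all sequences must be named")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
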