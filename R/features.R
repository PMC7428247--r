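# Genomic features are plain data.frames with 0-based half-open intervals
# (BED convention) and columns chrom, start, end, strand, kind, gene_id.
# GFF3's 1-based closed coordinates are converted at the boundary.

FEATURE_KINDS <- c("gene", "exon", "intron", "transposable_element",
                   "uncharacterized_repeat")

#' Construct a genomic feature table
#'
#' @param chrom,start,end,strand,kind,gene_id feature columns; `start`/`end`
#'   are 0-based half-open, strand is `"+"` or `"-"`.
#' @return a `data.frame` of features
#' @export
genomic_features <- function(chrom = character(), start = integer(),
                             end = integer(), strand = character(),
                             kind = character(), gene_id = character()) {
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), strand = as.character(strand),
                   kind = as.character(kind), gene_id = as.character(gene_id),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (any(df$start < 0L) || any(df$start >= df$end))
      stop("features require 0 <= start < end")
    if (!all(df$strand %in% c("+", "-")))
      stop("strand must be '+' or '-'")
    if (!all(df$kind %in% FEATURE_KINDS))
      stop("unknown feature kind: ",
           paste(setdiff(df$kind, FEATURE_KINDS), collapse = ", "))
    bad <- df$kind %in% c("exon", "intron") & (is.na(df$gene_id) | df$gene_id == "")
    if (any(bad)) stop("exon/intron features require a gene_id")
  }
  df
}

# derive introns as gaps between consecutive exons of the same gene
derive_introns <- function(exons) {
  if (!nrow(exons)) return(genomic_features())
  out <- lapply(split(exons, exons$gene_id), function(ex) {
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) < 2) return(NULL)
    istart <- ex$end[-nrow(ex)]
    iend <- ex$start[-1]
    keep <- istart < iend
    if (!any(keep)) return(NULL)
    genomic_features(chrom = ex$chrom[1], start = istart[keep],
                     end = iend[keep], strand = ex$strand[1],
                     kind = "intron", gene_id = ex$gene_id[1])
  })
  out <- do.call(rbind, out)
  if (is.null(out)) genomic_features() else `rownames<-`(out, NULL)
}

#' Read gene models from a GFF3 file
#'
#' Reads `gene` and `exon` rows via [rtracklayer::import()], converts the
#' 1-based closed GFF coordinates to the package's 0-based half-open
#' convention, and derives introns as gaps between consecutive exons of the
#' same gene. Exons extending outside their gene span are clipped with a
#' warning; an exon whose `Parent` is not a gene in the file is an error;
#' an unstranded row is treated as `"+"` with a warning.
#'
#' @param path GFF3 file
#' @return feature `data.frame` with genes, exons and derived introns
#' @export
read_gff3_genes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  keep <- type %in% c("gene", "exon")
  gr <- gr[keep]
  type <- type[keep]
  if (!length(gr)) stop("no gene/exon rows in ", path)
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(strand == "*")) {
    warning("unstranded feature(s) treated as '+'")
    strand[strand == "*"] <- "+"
  }
  chrom <- as.character(GenomeInfoDb::seqnames(gr))
  start0 <- BiocGenerics::start(gr) - 1L
  end0 <- BiocGenerics::end(gr)
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else rep(NA_character_, length(gr))
  parent <- if (!is.null(gr$Parent)) {
    vapply(gr$Parent, function(p) if (length(p)) as.character(p[[1]]) else NA_character_,
           character(1))
  } else rep(NA_character_, length(gr))

  is_gene <- type == "gene"
  genes <- if (any(is_gene))
    genomic_features(chrom = chrom[is_gene], start = start0[is_gene],
                     end = end0[is_gene], strand = strand[is_gene],
                     kind = "gene", gene_id = ids[is_gene])
  else genomic_features()
  ex_parent <- parent[!is_gene]
  if (any(is.na(ex_parent)) || !all(ex_parent %in% genes$gene_id))
    stop("orphan exon: parent gene not found for ",
         paste(unique(ex_parent[is.na(ex_parent) | !(ex_parent %in% genes$gene_id)]),
               collapse = ", "))
  ex_start <- start0[!is_gene]
  ex_end <- end0[!is_gene]
  gidx <- match(ex_parent, genes$gene_id)
  clip_lo <- pmax(ex_start, genes$start[gidx])
  clip_hi <- pmin(ex_end, genes$end[gidx])
  if (any(clip_lo != ex_start | clip_hi != ex_end)) {
    warning("exon(s) extending outside their gene span were clipped")
    ex_start <- clip_lo
    ex_end <- clip_hi
  }
  exons <- genomic_features(chrom = chrom[!is_gene], start = ex_start,
                            end = ex_end, strand = strand[!is_gene],
                            kind = "exon", gene_id = ex_parent)
  out <- rbind(genes, exons, derive_introns(exons))
  `rownames<-`(out[order(out$chrom, out$start, out$end, out$kind), ], NULL)
}

#' Write gene and exon features as GFF3
#'
#' Introns are not written; they are re-derived on read.
#' @param features feature `data.frame`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_gff3_genes <- function(features, path) {
  f <- features[features$kind %in% c("gene", "exon"), , drop = FALSE]
  f <- f[order(f$chrom, f$start, match(f$kind, c("gene", "exon"))), , drop = FALSE]
  attr9 <- ifelse(f$kind == "gene", paste0("ID=", f$gene_id),
                  paste0("ID=", f$gene_id, ":exon", seq_len(nrow(f)),
                         ";Parent=", f$gene_id))
  lines <- paste(f$chrom, "beemir", f$kind, f$start + 1L, f$end, ".",
                 f$strand, ".", attr9, sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read repeat (or precursor) annotations from a BED6 file
#'
#' The `kind` of each interval is `"transposable_element"` when its name
#' matches any pattern in `te_classes` (case-insensitive), else
#' `"uncharacterized_repeat"`. BED is natively 0-based half-open so
#' coordinates pass through unchanged.
#'
#' @param path BED6 file
#' @param te_classes character vector of regular expressions identifying
#'   transposable-element families in the name field
#' @return feature `data.frame` (with a `name` attribute column)
#' @export
read_bed6 <- function(path, te_classes = c("LINE", "SINE", "LTR", "DNA",
                                           "Helitron", "RC", "Penelope")) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 6) stop("BED6 requires 6 columns: ", path)
  names(df)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
  is_te <- rep(FALSE, nrow(df))
  for (p in te_classes) is_te <- is_te | grepl(p, df$name, ignore.case = TRUE)
  out <- genomic_features(chrom = df$chrom, start = df$start, end = df$end,
                          strand = df$strand,
                          kind = ifelse(is_te, "transposable_element",
                                        "uncharacterized_repeat"),
                          gene_id = "")
  out$name <- df$name
  out
}

#' Write intervals as BED6
#' @param features data.frame with chrom, start, end, strand and optional name
#' @param path output file
#' @return `path`, invisibly
#' @export
write_bed6 <- function(features, path) {
  nm <- if (!is.null(features$name)) features$name else
    if (!is.null(features$id)) features$id else
      paste0("feat", seq_len(nrow(features)))
  lines <- paste(features$chrom, features$start, features$end, nm, 0L,
                 features$strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
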