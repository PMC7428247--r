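# Gene-age assignment from orthogroup taxonomic breadth over a nested clade
# ladder, with Vertebrata handled as the outermost (oldest) class.

LADDER_LABELS <- c("Vertebrata", "Metazoa", "Arthropoda", "Insecta",
                   "Holometabola", "Hymenoptera", "Aculeata", "Apoidea")

#' Construct a clade ladder from a species-to-clade mapping
#'
#' The ladder orders clades oldest-first; every label after Vertebrata is
#' strictly nested in the previous one. Each species maps to its most
#' specific clade (e.g. a fly maps to Holometabola, a bee to Apoidea).
#'
#' @param species_clade named character vector or data.frame
#'   (species_id, most_specific_clade)
#' @return object of class `clade_ladder`
#' @export
clade_ladder <- function(species_clade) {
  if (is.data.frame(species_clade)) {
    map <- setNames(species_clade$most_specific_clade,
                    species_clade$species_id)
  } else {
    map <- species_clade
  }
  bad <- setdiff(unique(map), LADDER_LABELS)
  if (length(bad))
    stop("unknown clade label(s): ", paste(bad, collapse = ", "))
  structure(list(labels = LADDER_LABELS, map = map), class = "clade_ladder")
}

#' Assign a gene age from the species breadth of its orthogroup
#'
#' Walks the ladder oldest-first and returns the first label with at least
#' one member species belonging to that clade but not to the next (more
#' specific) one; any vertebrate member immediately gives Vertebrata. An
#' orthogroup containing only most-specific-clade species gives the youngest
#' ladder label (Apoidea by default, controlled by
#' `single_clade_label`). Genes without an orthogroup are aged "Unique" by
#' the caller ([assign_gene_ages()]).
#'
#' @param orthogroup_species character vector of species ids in the
#'   orthogroup (duplicates and order are irrelevant)
#' @param ladder a [clade_ladder()]
#' @param single_clade_label label used when no ladder step qualifies
#' @return a single age label
#' @export
assign_age <- function(orthogroup_species, ladder,
                       single_clade_label = "Apoidea") {
  sp <- unique(as.character(orthogroup_species))
  unmapped <- setdiff(sp, names(ladder$map))
  if (length(unmapped))
    stop("species not in clade ladder: ", paste(unmapped, collapse = ", "))
  clades <- unname(ladder$map[sp])
  # most-specific-clade rank of each member; Vertebrata sits outside the chain
  if (any(clades == "Vertebrata")) return("Vertebrata")
  ranks <- match(clades, ladder$labels) # 2..8 for the nested chain
  for (k in 2:(length(ladder$labels) - 1)) {
    # a species whose most specific clade is exactly label k belongs to k
    # but not to the next lower (more specific) label
    if (any(ranks == k)) return(ladder$labels[k])
  }
  single_clade_label
}

#' Assign ages to all genes of a species
#'
#' @param gene_ids character vector of the species' gene ids (the universe)
#' @param orthogroups data.frame (orthogroup_id, gene_id, species_id); genes
#'   absent from it are labelled "Unique"
#' @param ladder a [clade_ladder()]
#' @param single_clade_label see [assign_age()]
#' @return data.frame (gene_id, age_label, orthogroup_id)
#' @export
assign_gene_ages <- function(gene_ids, orthogroups, ladder,
                             single_clade_label = "Apoidea") {
  og_species <- split(orthogroups$species_id, orthogroups$orthogroup_id)
  og_age <- vapply(og_species, assign_age, character(1), ladder = ladder,
                   single_clade_label = single_clade_label)
  idx <- match(gene_ids, orthogroups$gene_id)
  og_id <- ifelse(is.na(idx), "", orthogroups$orthogroup_id[idx])
  age <- ifelse(og_id == "", "Unique", unname(og_age[og_id]))
  data.frame(gene_id = gene_ids, age_label = age, orthogroup_id = og_id,
             stringsAsFactors = FALSE)
}

#' Tabulate an age distribution
#'
#' @param ages data.frame from [assign_gene_ages()] (or any with
#'   `age_label`)
#' @return named integer vector of counts over all ladder labels plus
#'   "Unique"; sums to the number of genes
#' @export
age_distribution <- function(ages) {
  lv <- c(LADDER_LABELS, "Unique")
  tab <- table(factor(ages$age_label, levels = lv))
  setNames(as.integer(tab), lv)
}
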