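# Gene-level summary: %intact, loss classification, ancestral presence,
# shared-mutation support.

#' Maximum percentage of the intact reading frame (%intact)
#'
#' Given the relative coding positions (fractions in \[0,1\]) of the surviving
#' inactivating mutations of one isoform, returns 100 times the largest gap
#' between consecutive elements of \{0\} U positions U \{1\}: the longest
#' stretch of the coding sequence free of inactivating mutations.  A gene with
#' mutations at relative positions 0.20 and 0.55 has %intact 45.  With no
#' mutations the value is 100.  At the gene level the value is the maximum
#' over isoforms (see [call_losses()]).
#'
#' @param positions numeric vector of relative CDS positions in \[0,1\].
#' @return a single number in \[0, 100\].
#' @export
#' @examples
#' percent_intact(c(0.20, 0.55))  # 45
#' percent_intact(numeric(0))     # 100
percent_intact <- function(positions) {
  stopifnot(is.numeric(positions) || length(positions) == 0L)
  positions <- as.numeric(positions)
  if (any(positions < 0 | positions > 1, na.rm = TRUE))
    stop("relative positions must lie in [0, 1]")
  positions <- positions[!is.na(positions)]
  # rounding absorbs binary floating-point noise (1 - 0.55 != 0.45 exactly)
  round(100 * max(diff(sort(c(0, positions, 1)))), 9)
}

#' Classify a gene in one query species
#'
#' A gene is a `loss_candidate` when %intact is below `intact_max` (default
#' 60) and at least a fraction `exon_fraction` (default 0.2) of its exons
#' carry surviving inactivating mutations; a single-exon gene is a loss
#' candidate when it carries at least `single_exon_min_muts` (default 2)
#' surviving mutations.  Genes whose status cannot be assessed (synteny
#' failure, assembly-gap coverage, no data) are `missing_data`; everything
#' else is `intact`.
#'
#' @param percent_intact %intact value in \[0,100\].
#' @param n_exons number of coding exons of the chosen isoform.
#' @param n_exons_mutated number of exons with at least one surviving mutation.
#' @param n_mutations number of surviving mutations.
#' @param missing logical; `TRUE` when the gene is unassessable in this species.
#' @param intact_max,exon_fraction,single_exon_min_muts thresholds (defaults
#'   60, 0.2 and 2).
#' @return one of `"intact"`, `"loss_candidate"`, `"missing_data"`.
#' @export
classify_gene <- function(percent_intact, n_exons, n_exons_mutated,
                          n_mutations, missing = FALSE,
                          intact_max = 60, exon_fraction = 0.2,
                          single_exon_min_muts = 2L) {
  if (isTRUE(missing)) return("missing_data")
  stopifnot(n_exons >= 1L)
  lost <- if (n_exons == 1L) {
    n_mutations >= single_exon_min_muts
  } else {
    percent_intact < intact_max && (n_exons_mutated / n_exons) >= exon_fraction
  }
  if (lost) "loss_candidate" else "intact"
}

#' Most ancient ancestor in which a gene was present
#'
#' The ancestor is the most recent common ancestor of the reference species
#' and all query species in which the gene has no surviving inactivating
#' mutations.  Only losses in species descending from that ancestor are
#' countable as losses of an ancestrally present gene; loss candidates
#' outside the clade are reported in `dropped`.
#'
#' @param tree an [ape::read.tree()] phylo object whose tips are species names.
#' @param intact_species character vector of species classified intact
#'   (zero surviving mutations after all filters).
#' @param reference name of the reference species (counts as intact).
#' @param loss_species character vector of loss-candidate species.
#' @return list with `node` (internal node id, or tip id when the gene is
#'   intact in the reference only), `eligible` (tips descending from it) and
#'   `dropped` (loss candidates outside the clade, reclassified
#'   `not_ancestrally_present`).
#' @export
infer_ancestral_presence <- function(tree, intact_species, reference,
                                     loss_species = character(0)) {
  stopifnot(inherits(tree, "phylo"))
  present <- unique(c(reference, intact_species))
  unknown <- setdiff(present, tree$tip.label)
  if (length(unknown) > 0)
    stop("species not in tree: ", paste(unknown, collapse = ", "))
  if (length(present) == 1L) {
    node <- match(present, tree$tip.label)
    eligible <- present
  } else {
    node <- ape::getMRCA(tree, present)
    eligible <- clade_tips(tree, node)
  }
  keep <- intersect(loss_species, eligible)
  list(node = node, eligible = eligible,
       dropped = setdiff(loss_species, keep))
}

clade_tips <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(tree$tip.label[node])
  ape::extract.clade(tree, node)$tip.label
}

#' Inventory of inactivating mutations shared between loss species
#'
#' Mutations identical in class, exon index, CDS position and indel length
#' across two or more species are grouped; a shared mutation is evidence that
#' the loss happened once, on the common ancestral branch of the sharing
#' species.
#'
#' @param muts mutation table ([mutation_table()] schema) of surviving
#'   mutations of one gene across the loss species.
#' @return data.frame with one row per shared mutation: `class`, `exon`,
#'   `cds_pos`, `length`, `n_species`, `species` (comma-separated).
#' @export
shared_mutation_support <- function(muts) {
  muts <- surviving(muts)
  out <- data.frame(class = character(0), exon = integer(0),
                    cds_pos = numeric(0), length = numeric(0),
                    n_species = integer(0), species = character(0),
                    stringsAsFactors = FALSE)
  if (nrow(muts) == 0) return(out)
  key <- paste(muts$class, muts$exon, muts$cds_pos, muts$length, sep = "|")
  for (k in unique(key)) {
    rows <- muts[key == k, , drop = FALSE]
    sp <- unique(rows$species)
    if (length(sp) >= 2L) {
      out <- rbind(out, data.frame(
        class = rows$class[1], exon = rows$exon[1],
        cds_pos = rows$cds_pos[1], length = rows$length[1],
        n_species = length(sp), species = paste(sort(sp), collapse = ","),
        stringsAsFactors = FALSE))
    }
  }
  out
}

#' Assemble gene-status records into %intact and classification tables
#'
#' @param statuses data.frame with one row per gene x species carrying at
#'   least `gene`, `species`, `percent_intact`, `classification`.
#' @return list with `matrix` (genes x species %intact, `NA` for missing
#'   data) and `classification` (genes x species character matrix).
#' @export
call_losses <- function(statuses) {
  genes <- sort(unique(statuses$gene))
  species <- sort(unique(statuses$species))
  m <- matrix(NA_real_, length(genes), length(species),
              dimnames = list(genes, species))
  cl <- matrix(NA_character_, length(genes), length(species),
               dimnames = list(genes, species))
  idx <- cbind(match(statuses$gene, genes), match(statuses$species, species))
  m[idx] <- ifelse(statuses$classification == "missing_data", NA_real_,
                   statuses$percent_intact)
  cl[idx] <- statuses$classification
  list(matrix = m, classification = cl)
}
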