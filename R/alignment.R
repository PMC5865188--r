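# Container for one gene x query-species alignment: per coding exon the
# aligned reference/query rows, query locus, and splice dinucleotides, plus
# the nearest up/downstream aligning anchors used to judge deleted and
# unaligned exons.  Query coordinates are 0-based half-open on the positive
# strand of the query contig; sequences are stored in transcript orientation.

#' Construct a pairwise gene alignment
#'
#' @param gene_id,tx_id,species identifiers.
#' @param qry_contig query contig name.
#' @param exons list, one element per coding exon in transcript order, each a
#'   list with `present` (logical), `ref`/`qry` (equal-length aligned strings
#'   with `-` gaps; `NULL` when absent), `ref_len` (reference exon length,
#'   bp), `qry_start`/`qry_end` (query locus), `donor`/`acceptor` (query
#'   intron dinucleotides in transcript orientation; `NA` where not
#'   applicable).
#' @param anchors numeric `c(up =, dn =)` query coordinates of the nearest
#'   aligning blocks outside the gene (`NA` when absent, e.g. contig edge).
#' @param cds_len total reference CDS length (bp).
#' @param qry_strand `"+"` or `"-"`: strand of the query locus relative to
#'   the stored positive-strand coordinates.
#' @param validate check the per-exon invariants (equal row lengths, no
#'   gap-to-gap columns); skipped by the simulator, which emits by
#'   construction.
#' @return object of class `gene_alignment`.
#' @export
gene_alignment <- function(gene_id, tx_id, species, qry_contig, exons,
                           anchors = c(up = NA_real_, dn = NA_real_),
                           cds_len = NULL, qry_strand = "+",
                           validate = TRUE) {
  if (validate) for (e in exons) {
    if (isTRUE(e$present)) {
      if (nchar(e$ref) != nchar(e$qry)) stop("aligned rows differ in length")
      both <- gregexpr("-", e$ref, fixed = TRUE)[[1]]
      qg <- gregexpr("-", e$qry, fixed = TRUE)[[1]]
      if (both[1] != -1 && qg[1] != -1 && length(intersect(both, qg)) > 0)
        stop("gap aligned to gap in exon alignment")
    }
  }
  if (is.null(cds_len))
    cds_len <- sum(vapply(exons, function(e) e$ref_len, numeric(1)))
  structure(list(gene_id = gene_id, tx_id = tx_id, species = species,
                 qry_contig = qry_contig, qry_strand = qry_strand,
                 exons = exons, anchors = anchors, cds_len = cds_len),
            class = "gene_alignment")
}

#' @export
print.gene_alignment <- function(x, ...) {
  cat(sprintf("<gene_alignment> %s/%s in %s: %d exons (%d aligned), CDS %d bp\n",
              x$gene_id, x$tx_id, x$species, length(x$exons),
              sum(vapply(x$exons, function(e) isTRUE(e$present), logical(1))),
              as.integer(x$cds_len)))
  invisible(x)
}

# cumulative CDS offset (bp) of each exon start, from reference exon lengths
exon_cds_offsets <- function(galn) {
  lens <- vapply(galn$exons, function(e) e$ref_len, numeric(1))
  cumsum(c(0, lens))[seq_along(lens)]
}
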