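# Confirm candidate mutations against unassembled reads by exact matching of
# the mutation's assembly context (mutated allele with >= 50 bp flanks).

#' Extract the genomic context of a mutation from the query assembly
#'
#' Returns the assembly substring spanning `flank` bases either side of the
#' mutation locus (for indels, either side of the junction), truncated with a
#' warning at contig ends.  A context overlapping an N run cannot confirm
#' anything and is an error.
#'
#' @param assembly a [genome_assembly()].
#' @param contig contig name.
#' @param pos 0-based position of the mutated base (point mutations) or of
#'   the indel junction.
#' @param flank flank length each side (default 50).
#' @param point logical: `TRUE` for a point mutation (context includes the
#'   mutated base, length `2*flank+1`), `FALSE` for an indel junction
#'   (length `2*flank`).
#' @return list of class `mutation_context`: `context`, `revcomp`, `contig`,
#'   `start`, `end`.
#' @export
extract_context <- function(assembly, contig, pos, flank = 50L, point = TRUE) {
  len <- nchar(assembly$sequences[[contig]])
  start <- max(0, pos - flank)
  end <- min(len, pos + flank + as.integer(point))
  if (start > pos - flank || end < pos + flank + as.integer(point))
    warning("context truncated at contig end (", end - start, " bp)")
  ctx <- asm_slice(assembly, contig, start, end)
  if (grepl("N", ctx, fixed = TRUE))
    stop("mutation context overlaps an assembly gap; not confirmable")
  structure(list(context = ctx, revcomp = revcomp(ctx), contig = contig,
                 start = start, end = end), class = "mutation_context")
}

#' Count reads exactly containing a mutation context
#'
#' A read supports the mutation when it contains the full context as an
#' exact substring in either orientation (reads are unstranded).  The
#' mutation is validated when at least `min_support` (default 10) reads do.
#'
#' @param context a [extract_context()] result or a plain string.
#' @param reads character vector of read sequences.
#' @param min_support validation threshold (default 10).
#' @return list: `n_matches`, `validated`.
#' @export
count_support <- function(context, reads, min_support = 10L) {
  ctx <- if (inherits(context, "mutation_context")) context$context
         else toupper(context)
  rc <- if (inherits(context, "mutation_context")) context$revcomp
        else revcomp(ctx)
  if (length(reads) == 0) return(list(n_matches = 0L, validated = FALSE))
  reads <- toupper(reads)
  n <- sum(grepl(ctx, reads, fixed = TRUE) | grepl(rc, reads, fixed = TRUE))
  list(n_matches = n, validated = n >= min_support)
}

#' Validate a table of mutations against unassembled reads
#'
#' @param muts mutation table with `qry_pos` filled; rows without a query
#'   position are reported unvalidated with `n_matches` `NA`.
#' @param assembly query [genome_assembly()].
#' @param reads character vector of read sequences.
#' @param contig_of function mapping a mutation row to its contig name, or a
#'   single contig name used for all rows.
#' @param flank,min_support see [extract_context()], [count_support()].
#' @return `muts` with `n_matches` and `validated` columns appended.
#' @export
validate_mutations <- function(muts, assembly, reads, contig_of,
                               flank = 50L, min_support = 10L) {
  n <- integer(nrow(muts)); v <- logical(nrow(muts))
  for (i in seq_len(nrow(muts))) {
    if (is.na(muts$qry_pos[i])) { n[i] <- NA_integer_; v[i] <- FALSE; next }
    ctg <- if (is.function(contig_of)) contig_of(muts[i, ]) else contig_of
    res <- tryCatch({
      ctx <- extract_context(assembly, ctg, muts$qry_pos[i], flank = flank,
                             point = is.na(muts$length[i]))
      count_support(ctx, reads, min_support = min_support)
    }, error = function(e) list(n_matches = NA_integer_, validated = FALSE))
    n[i] <- res$n_matches; v[i] <- res$validated
  }
  muts$n_matches <- n
  muts$validated <- v
  muts
}
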