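# The mutation report is a plain data.frame; every scanner and filter speaks
# this schema.  `filtered_reason == ""` marks a surviving (inactivating) event.

MUTATION_CLASSES <- c("FS_INS", "FS_DEL", "STOP_SUBST", "STOP_IN_INS",
                      "SPLICE_DONOR", "SPLICE_ACCEPTOR", "BIG_INDEL",
                      "EXON_DELETED", "EXON_UNALIGNED")

#' Construct an (empty or filled) inactivating-mutation table
#'
#' Columns: `gene`, `tx`, `species`, `exon` (0-based index), `class`
#' (one of `r paste(MUTATION_CLASSES, collapse = ", ")`), `cds_pos`
#' (0-based position on the coding sequence, bp), `rel_pos`
#' (`cds_pos / cds_len`, in \[0,1\]), `length` (indel length, `NA` otherwise),
#' `detail` (free-text: codon, dinucleotide, ...), `qry_pos` (0-based query
#' genomic coordinate, `NA` if unknown) and `filtered_reason` (`""` while the
#' event counts as inactivating).
#'
#' @param gene,tx,species,exon,class,cds_pos,rel_pos,length,detail,qry_pos,filtered_reason
#'   vectors, recycled to a common length (zero rows if all empty).
#' @return a `data.frame` with the mutation-report schema.
#' @export
mutation_table <- function(gene = character(0), tx = character(0),
                           species = character(0), exon = integer(0),
                           class = character(0), cds_pos = numeric(0),
                           rel_pos = numeric(0), length = NA_real_,
                           detail = "", qry_pos = NA_real_,
                           filtered_reason = "") {
  if (length(class) == 0L) return(EMPTY_MUTATIONS)
  n <- max(lengths(list(gene, tx, species, exon, class, cds_pos, rel_pos)))
  df <- data.frame(
    gene = rep_len(as.character(gene %|0|% NA_character_), n),
    tx = rep_len(as.character(tx %|0|% NA_character_), n),
    species = rep_len(as.character(species %|0|% NA_character_), n),
    exon = rep_len(as.integer(exon %|0|% NA_integer_), n),
    class = rep_len(as.character(class %|0|% NA_character_), n),
    cds_pos = rep_len(as.numeric(cds_pos %|0|% NA_real_), n),
    rel_pos = rep_len(as.numeric(rel_pos %|0|% NA_real_), n),
    length = rep_len(as.numeric(length %|0|% NA_real_), n),
    detail = rep_len(as.character(detail %|0|% ""), n),
    qry_pos = rep_len(as.numeric(qry_pos %|0|% NA_real_), n),
    filtered_reason = rep_len(as.character(filtered_reason %|0|% ""), n),
    stringsAsFactors = FALSE
  )
  if (!all(is.na(df$class) | df$class %in% MUTATION_CLASSES))
    stop("unknown mutation class")
  df
}

`%|0|%` <- function(a, b) if (length(a) == 0L) b else a

# shared empty table (schema identical to mutation_table() output)
EMPTY_MUTATIONS <- data.frame(
  gene = character(0), tx = character(0), species = character(0),
  exon = integer(0), class = character(0), cds_pos = numeric(0),
  rel_pos = numeric(0), length = numeric(0), detail = character(0),
  qry_pos = numeric(0), filtered_reason = character(0),
  stringsAsFactors = FALSE)

bind_mutations <- function(...) {
  xs <- Filter(function(d) !is.null(d) && nrow(d) > 0, list(...))
  if (length(xs) == 0L) return(mutation_table())
  do.call(rbind, xs)
}

surviving <- function(muts) muts[muts$filtered_reason == "", , drop = FALSE]
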