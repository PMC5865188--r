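# External formats: GFF3/GTF annotation, FASTA genomes, MAF alignments,
# Newick trees, TSV tables, BED mutation reports.  Internal coordinates are
# 0-based half-open everywhere; GFF (1-based closed) and MAF conventions are
# converted exactly once, here.

#' A genome assembly with its N-run (assembly gap) index
#'
#' @param name species identifier.
#' @param sequences named character vector of contig sequences.
#' @return object of class `genome_assembly` with `gaps`: per contig a
#'   matrix of maximal N-run intervals (0-based half-open).
#' @export
genome_assembly <- function(name, sequences) {
  stopifnot(!is.null(names(sequences)))
  sequences <- toupper(unlist(sequences))
  gaps <- lapply(sequences, function(s) {
    m <- gregexpr("N+", s)[[1]]
    if (m[1] == -1) return(matrix(numeric(0), 0, 2,
                                  dimnames = list(NULL, c("start", "end"))))
    cbind(start = as.numeric(m) - 1,
          end = as.numeric(m) - 1 + attr(m, "match.length"))
  })
  structure(list(name = name, sequences = sequences, gaps = gaps),
            class = "genome_assembly")
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat(sprintf("<genome_assembly> %s: %d contig(s), %.0f bp, %d gap run(s)\n",
              x$name, length(x$sequences), sum(nchar(x$sequences)),
              sum(vapply(x$gaps, nrow, integer(1)))))
  invisible(x)
}

# 0-based half-open substring of a contig
asm_slice <- function(assembly, contig, start, end) {
  substr(assembly$sequences[[contig]], start + 1, end)
}

#' Read a genome FASTA into a [genome_assembly()]
#'
#' @param path FASTA file.
#' @param name species identifier (default: file name without extension).
#' @return a `genome_assembly`; any run of N (length >= 1) is indexed as an
#'   assembly gap.
#' @export
read_genome_fasta <- function(path, name = sub("\\.[^.]*$", "", basename(path))) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  genome_assembly(name, seqs)
}

#' Write a [genome_assembly()] to FASTA
#' @param assembly a `genome_assembly`.
#' @param path output file.
#' @export
write_genome_fasta <- function(assembly, path) {
  ss <- Biostrings::DNAStringSet(assembly$sequences)
  Biostrings::writeXStringSet(ss, path, width = 80)
  invisible(path)
}

#' A reference transcript model
#'
#' @param gene_id,tx_id identifiers.
#' @param contig reference contig.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame/matrix with columns `start`, `end` (0-based
#'   half-open genomic CDS-exon intervals), ordered 5'->3' in transcript
#'   orientation (descending genomic start on the minus strand).
#' @param priority `"principal"` or `"alternative"` isoform tag.
#' @return object of class `transcript_model`.
#' @export
transcript_model <- function(gene_id, tx_id, contig, strand, exons,
                             priority = "principal") {
  exons <- as.data.frame(exons)[, c("start", "end")]
  exons$start <- as.numeric(exons$start); exons$end <- as.numeric(exons$end)
  stopifnot(strand %in% c("+", "-"), all(exons$end > exons$start))
  g_start <- exons$start
  if (strand == "+") stopifnot(!is.unsorted(g_start, strictly = TRUE))
  else stopifnot(!is.unsorted(rev(g_start), strictly = TRUE))
  structure(list(gene_id = gene_id, tx_id = tx_id, contig = contig,
                 strand = strand, exons = exons, priority = priority),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s/%s (%s) %s:%s, %d exon(s), CDS %d bp\n",
              x$gene_id, x$tx_id, x$priority, x$contig, x$strand,
              nrow(x$exons), sum(x$exons$end - x$exons$start)))
  invisible(x)
}

tx_cds_length <- function(tx) sum(tx$exons$end - tx$exons$start)

#' Read CDS annotation (GFF3/GTF) into transcript models
#'
#' Only `CDS` features are used; coordinates are converted from the 1-based
#' closed GFF convention to internal 0-based half-open intervals, and exons
#' are ordered in transcript orientation.  CDS features without a transcript
#' id are skipped with a warning.
#'
#' @param path GFF3 or GTF file (format detected by [rtracklayer::import()]).
#' @return named list of [transcript_model()]s (names = transcript ids).
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type == "CDS"]
  mc <- as.data.frame(S4Vectors::mcols(gr))
  pick <- function(...) {
    for (col in c(...)) if (col %in% names(mc)) {
      v <- mc[[col]]
      if (methods::is(v, "List") || is.list(v))
        v <- vapply(v, function(x) if (length(x)) as.character(x[1]) else
          NA_character_, character(1))
      return(as.character(v))
    }
    rep(NA_character_, nrow(mc))
  }
  tx_id <- pick("transcript_id", "Parent")
  gene_id <- pick("gene_id", "gene")
  priority <- pick("priority")
  no_tx <- is.na(tx_id) | tx_id == ""
  if (any(no_tx)) {
    warning(sum(no_tx), " CDS feature(s) without transcript id skipped")
    gr <- gr[!no_tx]; tx_id <- tx_id[!no_tx]; gene_id <- gene_id[!no_tx]
    priority <- priority[!no_tx]
  }
  out <- list()
  for (tx in unique(tx_id)) {
    idx <- which(tx_id == tx)
    sub <- gr[idx]
    strand <- as.character(BiocGenerics::strand(sub))[1]
    ex <- data.frame(start = BiocGenerics::start(sub) - 1L,
                     end = BiocGenerics::end(sub))
    ex <- ex[order(ex$start, decreasing = (strand == "-")), , drop = FALSE]
    rownames(ex) <- NULL
    out[[tx]] <- transcript_model(
      gene_id = gene_id[idx][1] %|NA|% tx, tx_id = tx,
      contig = as.character(GenomicRanges::seqnames(sub))[1],
      strand = strand, exons = ex,
      priority = priority[idx][1] %|NA|% "principal")
  }
  out
}

`%|NA|%` <- function(a, b) if (is.na(a) || a == "") b else a

#' Write transcript models as GFF3
#' @param models list of [transcript_model()]s.
#' @param path output file.
#' @export
write_annotation <- function(models, path) {
  rows <- do.call(rbind, lapply(models, function(tx) {
    lens <- tx$exons$end - tx$exons$start         # transcript order
    offs <- cumsum(c(0, lens))[seq_along(lens)]
    phase <- (3 - offs %% 3) %% 3                 # GFF3 phase semantics
    ord <- order(tx$exons$start)
    data.frame(contig = tx$contig, start = tx$exons$start[ord] + 1L,
               end = tx$exons$end[ord], strand = tx$strand,
               phase = phase[ord], gene_id = tx$gene_id, tx_id = tx$tx_id,
               priority = tx$priority, stringsAsFactors = FALSE)
  }))
  gr <- GenomicRanges::GRanges(
    seqnames = rows$contig,
    ranges = IRanges::IRanges(start = rows$start, end = rows$end),
    strand = rows$strand)
  gr$source <- "genelossr"; gr$type <- "CDS"
  gr$phase <- as.integer(rows$phase)
  gr$gene_id <- rows$gene_id; gr$transcript_id <- rows$tx_id
  gr$priority <- rows$priority
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a MAF alignment file
#'
#' Every block must contain a row of the reference species (species taken as
#' the `src` prefix before the first dot); blocks without one are dropped
#' with a warning.  Query strand and coordinates keep MAF semantics
#' (`start` is on the given strand; minus-strand starts count from the end
#' of the source sequence).
#'
#' @param path MAF file.
#' @param reference reference species name.
#' @return list of blocks; each block is a list with `score` and `rows`
#'   (data.frame `src`, `species`, `contig`, `start`, `size`, `strand`,
#'   `src_size`, `text`), plus `ref_contig`, `ref_start`, `ref_end` for
#'   overlap queries (0-based half-open).
#' @export
read_maf <- function(path, reference) {
  lines <- readLines(path)
  blocks <- list(); cur <- NULL; score <- NA_real_
  flush <- function() {
    if (is.null(cur) || nrow(cur) == 0) return()
    ref <- cur[cur$species == reference, , drop = FALSE]
    if (nrow(ref) == 0) {
      warning("MAF block without reference row dropped")
    } else {
      blocks[[length(blocks) + 1L]] <<- list(
        score = score, rows = cur, ref_contig = ref$contig[1],
        ref_start = ref$start[1], ref_end = ref$start[1] + ref$size[1])
    }
    cur <<- NULL; score <<- NA_real_
  }
  for (ln in lines) {
    if (startsWith(ln, "a")) {
      flush()
      m <- regmatches(ln, regexec("score=([-0-9.eE+]+)", ln))[[1]]
      score <- if (length(m) == 2) as.numeric(m[2]) else NA_real_
      cur <- data.frame(src = character(0), species = character(0),
                        contig = character(0), start = numeric(0),
                        size = numeric(0), strand = character(0),
                        src_size = numeric(0), text = character(0),
                        stringsAsFactors = FALSE)
    } else if (startsWith(ln, "s ")) {
      f <- strsplit(trimws(ln), "[ \t]+")[[1]]
      if (length(f) != 7) stop("malformed MAF s line: ", ln)
      src <- f[2]
      sp <- sub("\\..*$", "", src)
      ctg <- sub("^[^.]*\\.", "", src)
      cur <- rbind(cur, data.frame(
        src = src, species = sp, contig = ctg, start = as.numeric(f[3]),
        size = as.numeric(f[4]), strand = f[5], src_size = as.numeric(f[6]),
        text = f[7], stringsAsFactors = FALSE))
    }
  }
  flush()
  widths <- vapply(blocks, function(b) length(unique(nchar(b$rows$text))),
                   integer(1))
  if (any(widths != 1)) stop("MAF block rows differ in width")
  blocks
}

#' Write MAF blocks (as produced by [read_maf()] or the simulator)
#' @param blocks list of blocks.
#' @param path output file.
#' @export
write_maf <- function(blocks, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("##maf version=1", con)
  for (b in blocks) {
    writeLines(if (is.na(b$score)) "a" else sprintf("a score=%g", b$score), con)
    r <- b$rows
    writeLines(sprintf("s %s %d %d %s %d %s", r$src, as.integer(r$start),
                       as.integer(r$size), r$strand, as.integer(r$src_size),
                       r$text), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read a Newick species tree
#' @param path Newick file.
#' @return an [ape::read.tree()] phylo object; leaf names must be unique and
#'   branch lengths non-negative.
#' @export
read_species_tree <- function(path) {
  tree <- ape::read.tree(path)
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf names in tree")
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("negative branch lengths")
  tree
}

#' Read a binary trait table
#'
#' TSV with columns `species` and `group` (`trait1` = derived phenotype,
#' `trait2` = background).  With a tree given, species absent from the tree
#' are a hard error listing the offenders.
#'
#' @param path TSV file.
#' @param tree optional phylo object for validation.
#' @return named character vector species -> group.
#' @export
read_trait_table <- function(path, tree = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("species", "group") %in% names(df)))
  if (!all(df$group %in% c("trait1", "trait2")))
    stop("trait groups must be trait1/trait2")
  if (!is.null(tree)) {
    bad <- setdiff(df$species, tree$tip.label)
    if (length(bad) > 0)
      stop("trait species not in tree: ", paste(bad, collapse = ", "))
  }
  setNames(df$group, df$species)
}

#' Read a divergence-time bounds table
#' @param path TSV with columns `branch`, `T_lower`, `T_upper` (My).
#' @return data.frame.
#' @export
read_time_bounds <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("branch", "T_lower", "T_upper") %in% names(df)))
  df
}

#' Write the gene x species %intact matrix (TSV, genes as rows)
#' @param m matrix from [call_losses()].
#' @param path output TSV.
#' @export
write_status_table <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a %intact matrix written by [write_status_table()]
#' @param path TSV file.
#' @return numeric matrix, genes as rows.
#' @export
read_status_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write the mutation report (TSV or BED)
#'
#' TSV keeps the full [mutation_table()] schema; BED (0-based half-open)
#' reports query positions with name `gene|species|class`.
#'
#' @param muts mutation table.
#' @param path output file.
#' @param format `"tsv"` or `"bed"`.
#' @export
write_mutation_report <- function(muts, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(muts, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    ok <- !is.na(muts$qry_pos)
    b <- muts[ok, , drop = FALSE]
    span <- ifelse(is.na(b$length), 1, pmax(b$length, 1))
    bed <- data.frame(chrom = b$species, start = as.integer(b$qry_pos),
                      end = as.integer(b$qry_pos + span),
                      name = paste(b$gene, b$species, b$class, sep = "|"))
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read sequencing reads (FASTA or FASTQ)
#' @param path file; `.fq`/`.fastq` parsed as FASTQ, else FASTA.
#' @return character vector of read sequences.
#' @export
read_reads <- function(path) {
  fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path)) "fastq" else "fasta"
  as.character(Biostrings::readDNAStringSet(path, format = fmt))
}

#' Write reads as FASTQ (constant quality)
#' @param reads named or unnamed character vector of read sequences.
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  ids <- names(reads) %||% paste0("read", seq_along(reads))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0("@", ids, "\n", reads, "\n+\n",
                    vapply(nchar(reads), function(n)
                      collapse0(rep("I", n)), character(1))), con)
  invisible(path)
}
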