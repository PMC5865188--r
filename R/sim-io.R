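# File round trip for the simulator: write a complete input directory
# (genomes, annotation, alignments, tree, truth) and re-assemble gene
# alignments from MAF blocks.

# MAF blocks of one species' alignments (one block per exon + two anchor
# blocks per gene)
sim_maf_blocks <- function(sim, sp) {
  blocks <- list()
  ref_asm <- sim$assemblies[[sim$reference]]
  qry_asm <- sim$assemblies[[sp]]
  for (g in sim$genes) {
    tx <- sim$annotation[[paste0(g$id, ".t1")]]
    galn <- sim$alignments[[g$id]][[sp]][[1]]
    qlen <- nchar(qry_asm$sequences[[galn$qry_contig]])
    rlen <- nchar(ref_asm$sequences[[tx$contig]])
    mk_row <- function(src, start, size, srcSize, text)
      data.frame(src = src, species = sub("\\..*", "", src),
                 contig = sub("^[^.]*\\.", "", src), start = start,
                 size = size, strand = "+", src_size = srcSize, text = text,
                 stringsAsFactors = FALSE)
    # anchor blocks: aligned flank halves either side of the gene
    a_len <- 20L
    up_r <- tx$exons$start[1] - sim$config$flank_len / 2
    dn_r <- tx$exons$end[nrow(tx$exons)] + sim$config$flank_len / 2 - a_len
    up_q <- galn$anchors["up"] - a_len; dn_q <- galn$anchors["dn"]
    for (anch in list(c(up_r - a_len, up_q), c(dn_r, dn_q))) {
      rtxt <- asm_slice(ref_asm, tx$contig, anch[1], anch[1] + a_len)
      qtxt <- asm_slice(qry_asm, galn$qry_contig, anch[2], anch[2] + a_len)
      blocks[[length(blocks) + 1L]] <- list(score = 0, rows = rbind(
        mk_row(paste(sim$reference, tx$contig, sep = "."), anch[1], a_len,
               rlen, rtxt),
        mk_row(paste(sp, galn$qry_contig, sep = "."), anch[2], a_len, qlen,
               qtxt)),
        ref_contig = tx$contig, ref_start = anch[1],
        ref_end = anch[1] + a_len)
    }
    for (e in seq_along(galn$exons)) {
      ex <- galn$exons[[e]]
      if (!isTRUE(ex$present)) next
      rstart <- tx$exons$start[e]
      qsize <- nchar(gsub("-", "", ex$qry, fixed = TRUE))
      blocks[[length(blocks) + 1L]] <- list(score = 0, rows = rbind(
        mk_row(paste(sim$reference, tx$contig, sep = "."), rstart,
               ex$ref_len, rlen, ex$ref),
        mk_row(paste(sp, galn$qry_contig, sep = "."), ex$qry_start, qsize,
               qlen, ex$qry)),
        ref_contig = tx$contig, ref_start = rstart,
        ref_end = rstart + ex$ref_len)
    }
  }
  blocks
}

#' Write a simulated study to an input directory
#'
#' Produces `genomes/*.fa`, `annotation.gff3`, `alignments/<species>.maf`,
#' `tree.nwk`, `truth.tsv`, `config.yaml` and, optionally, `traits.tsv` and
#' `reads/<species>.fq`.
#'
#' @param sim a [simulate_geneloss()] result.
#' @param dir output directory (created).
#' @param groups optional trait assignment written as `traits.tsv`.
#' @param reads logical: also sample and write reads per query species.
#' @return `dir`, invisibly.
#' @export
sim_write <- function(sim, dir, groups = NULL, reads = FALSE) {
  dir.create(file.path(dir, "genomes"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "alignments"), showWarnings = FALSE)
  for (sp in names(sim$assemblies))
    write_genome_fasta(sim$assemblies[[sp]],
                       file.path(dir, "genomes", paste0(sp, ".fa")))
  write_annotation(sim$annotation, file.path(dir, "annotation.gff3"))
  for (sp in sim$species)
    write_maf(sim_maf_blocks(sim, sp),
              file.path(dir, "alignments", paste0(sp, ".maf")))
  ape::write.tree(sim$tree, file.path(dir, "tree.nwk"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- sim$config
  cfg$tree <- ape::write.tree(cfg$tree)
  if (requireNamespace("yaml", quietly = TRUE)) {
    writeLines(yaml::as.yaml(unclass(cfg)), file.path(dir, "config.yaml"))
  }
  if (!is.null(groups)) {
    utils::write.table(
      data.frame(species = names(groups), group = unname(groups)),
      file.path(dir, "traits.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  if (reads) {
    dir.create(file.path(dir, "reads"), showWarnings = FALSE)
    for (sp in sim$species)
      write_fastq(sample_reads(sim$assemblies[[sp]], sim$config),
                  file.path(dir, "reads", paste0(sp, ".fq")))
  }
  invisible(dir)
}

#' Assemble per-gene alignments from MAF blocks
#'
#' For each coding exon of `tx`, finds the MAF block covering its reference
#' interval, slices the aligned rows to the exon, and reads splice
#' dinucleotides from the query assembly; the nearest blocks outside the
#' gene span provide the flanking anchors.  Query rows must be on the
#' positive strand (as emitted by [sim_write()]).
#'
#' @param blocks [read_maf()] result for one query species.
#' @param tx a [transcript_model()] (positive-strand reference).
#' @param qry_assembly query [genome_assembly()].
#' @param species query species name.
#' @return a [gene_alignment()].
#' @export
collect_gene_alignments <- function(blocks, tx, qry_assembly, species) {
  stopifnot(tx$strand == "+")
  bstart <- vapply(blocks, `[[`, numeric(1), "ref_start")
  bend <- vapply(blocks, `[[`, numeric(1), "ref_end")
  bctg <- vapply(blocks, `[[`, character(1), "ref_contig")
  qry_contig <- NA_character_
  exons <- vector("list", nrow(tx$exons))
  for (e in seq_len(nrow(tx$exons))) {
    lo <- tx$exons$start[e]; hi <- tx$exons$end[e]
    hit <- which(bctg == tx$contig & bstart <= lo & bend >= hi)
    if (length(hit) == 0) {
      exons[[e]] <- list(present = FALSE, ref = NULL, qry = NULL,
                         ref_len = hi - lo, qry_start = NA_real_,
                         qry_end = NA_real_, donor = NA_character_,
                         acceptor = NA_character_)
      next
    }
    b <- blocks[[hit[1]]]
    ref_row <- b$rows[b$rows$contig == tx$contig &
                        b$rows$species != species, ][1, ]
    qry_row <- b$rows[b$rows$species == species, ][1, ]
    stopifnot(qry_row$strand == "+")
    rtext <- chars(ref_row$text); qtext <- chars(qry_row$text)
    refpos <- ref_row$start + cumsum(rtext != "-") - 1
    cols <- which(refpos >= lo & refpos < hi & rtext != "-")
    cols <- seq(min(cols), max(cols))
    qbefore <- sum(qtext[seq_len(min(cols) - 1)] != "-")
    qin <- sum(qtext[cols] != "-")
    qs <- qry_row$start + qbefore
    qry_contig <- qry_row$contig
    exons[[e]] <- list(
      present = TRUE, ref = collapse0(rtext[cols]),
      qry = collapse0(qtext[cols]), ref_len = hi - lo,
      qry_start = qs, qry_end = qs + qin,
      donor = NA_character_, acceptor = NA_character_)
  }
  n_ex <- length(exons)
  for (e in seq_len(n_ex)) {
    ex <- exons[[e]]
    if (!isTRUE(ex$present)) next
    if (e < n_ex)
      exons[[e]]$donor <- asm_slice(qry_assembly, qry_contig, ex$qry_end,
                                    ex$qry_end + 2)
    if (e > 1)
      exons[[e]]$acceptor <- asm_slice(qry_assembly, qry_contig,
                                       ex$qry_start - 2, ex$qry_start)
  }
  gene_lo <- tx$exons$start[1]; gene_hi <- tx$exons$end[nrow(tx$exons)]
  up_blocks <- which(bctg == tx$contig & bend <= gene_lo)
  dn_blocks <- which(bctg == tx$contig & bstart >= gene_hi)
  anchor_q <- function(i, side) {
    if (length(i) == 0) return(NA_real_)
    b <- blocks[[i]]
    qr <- b$rows[b$rows$species == species, ][1, ]
    if (side == "up") qr$start + qr$size else qr$start
  }
  up <- up_blocks[which.max(bend[up_blocks])]
  dn <- dn_blocks[which.min(bstart[dn_blocks])]
  gene_alignment(tx$gene_id, tx$tx_id, species, qry_contig, exons,
                 anchors = c(up = anchor_q(up, "up"),
                             dn = anchor_q(dn, "dn")))
}

#' Load a study directory written by [sim_write()] into pipeline inputs
#'
#' Reads genomes, annotation, per-species MAF alignments and the tree, and
#' re-assembles the per-gene [gene_alignment()]s, giving an object that
#' [run_pipeline()] accepts exactly like a [simulate_geneloss()] result.
#'
#' @param dir study directory (`genomes/`, `annotation.gff3`, `alignments/`,
#'   `tree.nwk`).
#' @param reference reference species name (default `"ref"`).
#' @return list of class `geneloss_sim` (without truth labels).
#' @export
read_study_dir <- function(dir, reference = "ref") {
  tree <- read_species_tree(file.path(dir, "tree.nwk"))
  ann <- read_annotation(file.path(dir, "annotation.gff3"))
  genomes <- list.files(file.path(dir, "genomes"), full.names = TRUE)
  assemblies <- lapply(genomes, function(f) read_genome_fasta(f))
  names(assemblies) <- vapply(assemblies, `[[`, character(1), "name")
  queries <- setdiff(names(assemblies), reference)
  gene_ids <- unique(vapply(ann, `[[`, character(1), "gene_id"))
  genes <- lapply(gene_ids, function(g) list(id = g))
  by_gene <- split(ann, vapply(ann, `[[`, character(1), "gene_id"))
  alignments <- setNames(vector("list", length(gene_ids)), gene_ids)
  loci <- list()
  for (sp in queries) {
    maf <- file.path(dir, "alignments", paste0(sp, ".maf"))
    blocks <- read_maf(maf, reference)
    pos <- numeric(length(gene_ids)); ctg <- character(length(gene_ids))
    for (gi in seq_along(gene_ids)) {
      g <- gene_ids[gi]
      isoforms <- lapply(by_gene[[g]], function(tx)
        collect_gene_alignments(blocks, tx, assemblies[[sp]], sp))
      # principal isoform first
      prio <- vapply(by_gene[[g]], `[[`, character(1), "priority")
      isoforms <- isoforms[order(prio != "principal")]
      alignments[[g]][[sp]] <- unname(isoforms)
      qs <- unlist(lapply(isoforms[[1]]$exons, function(e)
        c(e$qry_start, e$qry_end)))
      pos[gi] <- if (all(is.na(qs))) NA_real_ else mean(qs, na.rm = TRUE)
      ctg[gi] <- isoforms[[1]]$qry_contig %||% NA_character_
    }
    loci[[sp]] <- data.frame(gene = gene_ids, contig = ctg, pos = pos,
                             stringsAsFactors = FALSE)
  }
  truth_f <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truth_f))
    utils::read.delim(truth_f, stringsAsFactors = FALSE) else NULL
  structure(list(config = NULL, tree = tree, reference = reference,
                 species = queries, genes = genes, assemblies = assemblies,
                 annotation = ann, alignments = alignments, cds = NULL,
                 loci = loci, truth = truth,
                 loss_table = data.frame()),
            class = "geneloss_sim")
}
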