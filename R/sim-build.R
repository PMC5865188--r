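# Assembly of the synthetic study: per-leaf artifacts, genome layout,
# emitted alignments, truth table.

# apply per-species artifacts to one gene's exon alignments; returns
# modified exon list + intron list + truth rows
apply_artifacts <- function(exons, gstruct, introns, species, cfg) {
  truth <- list()
  note <- function(kind, class, exon, pos = NA_real_) {
    truth[[length(truth) + 1L]] <<- data.frame(
      gene = gstruct$id, species = species, kind = kind, class = class,
      exon = exon, cds_pos = pos, stringsAsFactors = FALSE)
  }
  # sequencing-error substitutions and 1-bp indels inside exons: one draw
  # for the whole gene, distributed over exons
  exon_qlen <- vapply(exons, function(e) sum(e$q != "-"), numeric(1))
  total_q <- sum(exon_qlen)
  n_sub <- rpois(1, cfg$err_sub * total_q)
  n_ind <- rpois(1, cfg$err_indel * total_q)
  if (n_sub + n_ind > 0 && total_q > 20) {
    for (j in seq_len(n_sub)) {
      e <- sample.int(length(exons), 1, prob = exon_qlen)
      q <- exons[[e]]$q
      qbase <- which(q != "-")
      at <- qbase[sample.int(length(qbase), 1)]
      q[at] <- sample(setdiff(BASES, q[at]), 1)
      exons[[e]]$q <- q
      note("artifact", "err_sub", e - 1L)
    }
    for (j in seq_len(n_ind)) {
      e <- sample.int(length(exons), 1, prob = exon_qlen)
      q <- exons[[e]]$q; r <- exons[[e]]$r
      qbase <- which(q != "-")
      qbase <- qbase[qbase > 3 & qbase < length(q) - 3]
      if (length(qbase) < 5) next
      at <- qbase[sample.int(length(qbase), 1)]
      if (runif(1) < 0.5) {
        q[at] <- "-"
        note("artifact", "err_del", e - 1L)
      } else {
        r <- append(r, "-", after = at)
        q <- append(q, sample(BASES, 1), after = at)
        note("artifact", "err_ins", e - 1L)
      }
      exons[[e]]$q <- q; exons[[e]]$r <- r
    }
  }
  # aligner misplacement of evolved frame-preserving indels
  for (e in seq_along(exons)) {
    q <- exons[[e]]$q; r <- exons[[e]]$r
    if (!any(q == "-") && !any(r == "-")) next
    for (row in 1:2) {
      gapv <- if (row == 1) r == "-" else q == "-"
      runs <- runs_of(gapv)
      runs <- runs[(runs$end - runs$start + 1) %% 3 == 0 &
                     runs$start > 2 & runs$end < length(gapv) - 1, ,
                   drop = FALSE]
      for (k in seq_len(nrow(runs))) {
        if (runif(1) >= cfg$misplace_prob) next
        a <- runs$start[k]; b <- runs$end[k]
        other <- if (row == 1) q else r   # the row WITHOUT the gap
        ## slide gap right by one: re-pair the base after the run
        if (gapv[b + 1L] || !gapv[a]) next
        own <- if (row == 1) r else q
        if (own[b + 1L] == "-") next
        own[a] <- own[b + 1L]; own[b + 1L] <- "-"
        if (row == 1) r <- own else q <- own
        note("artifact", "misplaced_indel", e - 1L)
        break
      }
    }
    exons[[e]]$q <- q; exons[[e]]$r <- r
  }
  # splice-site shift: donor moved +3 bp into intron `i`
  shifted_introns <- integer(0)
  if (length(introns) > 0 && runif(1) < cfg$splice_shift_prob) {
    i <- sample.int(length(introns), 1)
    gained <- sample(c("AAC", "CAA", "ACA", "AAA"), 1)  # non-stop, non-GT/GC
    introns[[i]] <- paste0(gained, "GT",
                           substr(introns[[i]], 6, nchar(introns[[i]])))
    shifted_introns <- i
    note("artifact", "splice_shift", i - 1L)
  }
  # precise intron deletion
  deleted_introns <- integer(0)
  if (length(introns) > 0 && runif(1) < cfg$intron_del_prob) {
    cand <- setdiff(seq_along(introns), shifted_introns)
    if (length(cand) > 0) {
      i <- if (length(cand) == 1) cand else sample(cand, 1)
      deleted_introns <- i
      note("artifact", "intron_deletion", i - 1L)
    }
  }
  list(exons = exons, introns = introns, deleted_introns = deleted_introns,
       truth = if (length(truth)) do.call(rbind, truth) else NULL)
}

# build one gene's query region string + exon offsets + splice dinucleotides
build_region <- function(exons, introns, deleted_introns, gstruct, cfg) {
  qseq <- vapply(exons, function(e) collapse0(e$q[e$q != "-"]), character(1))
  n_ex <- length(exons)
  flankL <- random_dna(cfg$flank_len); flankR <- random_dna(cfg$flank_len)
  parts <- character(0); offs <- numeric(n_ex); pos <- nchar(flankL)
  parts <- flankL
  for (e in seq_len(n_ex)) {
    offs[e] <- pos
    parts <- c(parts, qseq[e]); pos <- pos + nchar(qseq[e])
    if (e < n_ex && !(e %in% deleted_introns)) {
      parts <- c(parts, introns[[e]]); pos <- pos + nchar(introns[[e]])
    }
  }
  parts <- c(parts, flankR)
  region <- collapse0(parts)
  ends <- offs + nchar(qseq)
  donors <- acceptors <- rep(NA_character_, n_ex)
  for (e in seq_len(n_ex)) {
    if (e < n_ex) donors[e] <- substr(region, ends[e] + 1, ends[e] + 2)
    if (e > 1) acceptors[e] <- substr(region, offs[e] - 1, offs[e])
  }
  list(region = region, exon_start = offs, exon_end = ends,
       donor = donors, acceptor = acceptors)
}

# N-gap corruption of one region; propagates Ns into exon alignment columns
corrupt_region <- function(reg, exons, cfg) {
  len <- nchar(reg$region)
  n_gaps <- rpois(1, cfg$gap_rate * len)
  if (n_gaps == 0) return(list(reg = reg, exons = exons, n = 0L))
  s <- chars(reg$region)
  for (j in seq_len(n_gaps)) {
    glen <- rint(1, cfg$gap_len[1], cfg$gap_len[2])
    at <- sample.int(len - glen, 1)
    s[at:(at + glen - 1L)] <- "N"
  }
  reg$region <- collapse0(s)
  for (e in seq_along(exons)) {
    q <- exons[[e]]$q
    qidx <- which(q != "-")
    if (length(qidx) == 0) next
    regpos <- reg$exon_start[e] + seq_along(qidx) - 1L
    hit <- s[regpos + 1L] == "N"
    q[qidx[hit]] <- "N"
    exons[[e]]$q <- q
  }
  for (e in seq_along(exons)) {
    if (!is.na(reg$donor[e]))
      reg$donor[e] <- substr(reg$region, reg$exon_end[e] + 1,
                             reg$exon_end[e] + 2)
    if (!is.na(reg$acceptor[e]))
      reg$acceptor[e] <- substr(reg$region, reg$exon_start[e] - 1,
                                reg$exon_start[e])
  }
  list(reg = reg, exons = exons, n = n_gaps)
}

#' Run the synthetic-evolution generator
#'
#' Evolves `n_genes + n_loss_genes` genes along the configured tree, injects
#' inactivating mutations on the loss branches, corrupts the query
#' assemblies with sequencing errors and N gaps, and emits truth-derived
#' pairwise gene alignments, genome assemblies, a reference annotation and a
#' truth table.
#'
#' @param cfg a [sim_config()].
#' @return object of class `geneloss_sim`: `config`, `tree`, `reference`,
#'   `species` (query leaves), `genes` (structures), `assemblies` (named
#'   list of [genome_assembly()], including the reference), `annotation`
#'   (list of [transcript_model()] on the reference), `alignments`
#'   (`alignments[[gene]][[species]]` = list of [gene_alignment()]s, one per
#'   isoform), `cds` (per gene: named vector of leaf CDS strings),
#'   `loci` (per species: data.frame gene/contig/pos for synteny),
#'   `truth` (injected mutations and artifacts), `loss_table`
#'   (gene/branch/descendant species).
#' @export
simulate_geneloss <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  tree <- ape::reorder.phylo(cfg$tree, "cladewise")
  tips <- tree$tip.label
  queries <- setdiff(tips, cfg$reference)
  n_total <- cfg$n_genes + cfg$n_loss_genes
  ref_node <- match(cfg$reference, tips)
  ref_path <- integer(0)
  node <- ref_node
  repeat {
    k <- which(tree$edge[, 2] == node)
    if (length(k) == 0) break
    ref_path <- c(ref_path, k)
    node <- tree$edge[k, 1]
  }
  loss_nodes <- if (cfg$n_loss_genes > 0)
    vapply(cfg$loss_branches, branch_node, numeric(1), tree = tree) else
    numeric(0)
  for (ln in loss_nodes)
    if (cfg$reference %in% clade_tips(tree, ln))
      stop("loss branch contains the reference lineage")

  genes <- lapply(seq_len(n_total), function(i)
    sample_gene_struct(sprintf("g%04d", i), cfg))
  loss_assign <- rep(NA_real_, n_total)
  if (cfg$n_loss_genes > 0)
    loss_assign[cfg$n_genes + seq_len(cfg$n_loss_genes)] <-
      rep_len(loss_nodes, cfg$n_loss_genes)

  root_depth <- max(ape::node.depth.edgelength(tree))
  truth_rows <- list(); loss_rows <- list()
  per_gene <- vector("list", n_total)
  cds_store <- vector("list", n_total)

  for (gi in seq_len(n_total)) {
    g <- genes[[gi]]
    states <- evolve_gene(g, tree, cfg, loss_node = loss_assign[gi],
                          ref_path_edges = ref_path)
    ref_st <- states[[cfg$reference]]
    cds_store[[gi]] <- vapply(states, function(s)
      collapse0(s$cod), character(1))
    if (!is.na(loss_assign[gi])) {
      desc <- intersect(clade_tips(tree, loss_assign[gi]), queries)
      lstate <- states[[desc[1]]]
      for (ev in lstate$injected)
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          gene = g$id, species = paste(desc, collapse = ","),
          kind = "loss", class = ev$class,
          exon = findInterval(ev$anc_pos, g$offs, rightmost.closed = TRUE) - 1L,
          cds_pos = ev$anc_pos, stringsAsFactors = FALSE)
      loss_rows[[length(loss_rows) + 1L]] <- data.frame(
        gene = g$id, branch = names(loss_nodes)[match(loss_assign[gi],
                                                      loss_nodes)] %||%
          NA_character_,
        node = loss_assign[gi], species = paste(desc, collapse = ","),
        stringsAsFactors = FALSE)
    }
    # reference exon strings + introns evolved along the reference lineage
    ref_cds_aln <- list(r = chars(collapse0(ref_st$cod)),
                        q = chars(collapse0(ref_st$cod)),
                        anc = seq_len(g$cds_len) - 1)
    per_sp <- list()
    for (sp in queries) {
      aln <- materialize_cds_alignment(ref_st, states[[sp]], g)
      exons <- split_alignment_exons(aln, g)
      t_leaf <- root_depth   # iid intron divergence, one draw per leaf
      introns <- lapply(g$introns, function(s) mutate_noncoding(s, t_leaf))
      art <- apply_artifacts(exons, g, introns, sp, cfg)
      if (!is.null(art$truth))
        truth_rows[[length(truth_rows) + 1L]] <- art$truth
      reg <- build_region(art$exons, art$introns, art$deleted_introns, g, cfg)
      cor <- corrupt_region(reg, art$exons, cfg)
      per_sp[[sp]] <- list(exons = cor$exons, reg = cor$reg,
                           pseudo = runif(1) < cfg$pseudogene_prob)
      if (per_sp[[sp]]$pseudo)
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          gene = g$id, species = sp, kind = "artifact",
          class = "processed_pseudogene", exon = NA_integer_,
          cds_pos = NA_real_, stringsAsFactors = FALSE)
    }
    # reference region (clean: no artifacts, no gaps)
    ref_exons <- split_alignment_exons(ref_cds_aln, g)
    ref_reg <- build_region(ref_exons, lapply(g$introns, function(s)
      mutate_noncoding(s, root_depth)), integer(0), g, cfg)
    per_gene[[gi]] <- list(g = g, per_sp = per_sp, ref_reg = ref_reg,
                           ref_exons = ref_exons)
  }

  # ------------------------------------------------------------------ layout
  layout_species <- function(get_region, pseudo_flags = NULL) {
    contigs <- list(); starts <- numeric(n_total); ctg <- character(n_total)
    cur_name <- NULL; cur_parts <- character(0); cur_len <- 0
    spacer <- 200L
    pg_parts <- character(0); pg_len <- 0; pg_info <- list()
    for (gi in seq_len(n_total)) {
      cname <- sprintf("c%d", (gi - 1) %/% cfg$genes_per_contig + 1)
      if (!identical(cname, cur_name)) {
        if (!is.null(cur_name)) contigs[[cur_name]] <- collapse0(cur_parts)
        cur_name <- cname; cur_parts <- character(0); cur_len <- 0
      }
      reg <- get_region(gi)
      if (!is.null(pseudo_flags) && pseudo_flags[gi]) {
        starts[gi] <- pg_len
        ctg[gi] <- "pg"
        pg_parts <- c(pg_parts, reg, random_dna(spacer))
        pg_len <- pg_len + nchar(reg) + spacer
      } else {
        starts[gi] <- cur_len
        ctg[gi] <- cname
        cur_parts <- c(cur_parts, reg, random_dna(spacer))
        cur_len <- cur_len + nchar(reg) + spacer
      }
    }
    contigs[[cur_name]] <- collapse0(cur_parts)
    if (pg_len > 0) contigs[["pg"]] <- collapse0(pg_parts)
    list(contigs = contigs, starts = starts, contig_of = ctg)
  }

  ref_layout <- layout_species(function(gi) per_gene[[gi]]$ref_reg$region)
  assemblies <- list()
  assemblies[[cfg$reference]] <- genome_assembly(
    cfg$reference, unlist(ref_layout$contigs))
  annotation <- list()
  for (gi in seq_len(n_total)) {
    g <- genes[[gi]]; rr <- per_gene[[gi]]$ref_reg
    base <- ref_layout$starts[gi]
    ex <- data.frame(start = base + rr$exon_start, end = base + rr$exon_end)
    annotation[[paste0(g$id, ".t1")]] <- transcript_model(
      g$id, paste0(g$id, ".t1"), ref_layout$contig_of[gi], "+", ex,
      priority = "principal")
    if (!is.na(g$alt_drop))
      annotation[[paste0(g$id, ".t2")]] <- transcript_model(
        g$id, paste0(g$id, ".t2"), ref_layout$contig_of[gi], "+",
        ex[-g$alt_drop, , drop = FALSE], priority = "alternative")
  }

  alignments <- setNames(vector("list", n_total),
                         vapply(genes, `[[`, character(1), "id"))
  loci <- list()
  for (sp in queries) {
    pg_flags <- vapply(per_gene, function(pg) pg$per_sp[[sp]]$pseudo,
                       logical(1))
    lay <- layout_species(function(gi) per_gene[[gi]]$per_sp[[sp]]$reg$region,
                          pg_flags)
    assemblies[[sp]] <- genome_assembly(sp, unlist(lay$contigs))
    loci[[sp]] <- data.frame(
      gene = vapply(genes, `[[`, character(1), "id"),
      contig = lay$contig_of,
      pos = lay$starts + vapply(per_gene, function(pg)
        nchar(pg$per_sp[[sp]]$reg$region) / 2, numeric(1)),
      stringsAsFactors = FALSE)
    for (gi in seq_len(n_total)) {
      g <- genes[[gi]]
      dat <- per_gene[[gi]]$per_sp[[sp]]
      base <- lay$starts[gi]
      exon_list <- lapply(seq_len(g$n_exons), function(e) {
        ex <- dat$exons[[e]]
        list(present = TRUE, ref = collapse0(ex$r), qry = collapse0(ex$q),
             ref_len = g$exon_lens[e],
             qry_start = base + dat$reg$exon_start[e],
             qry_end = base + dat$reg$exon_end[e],
             donor = dat$reg$donor[e], acceptor = dat$reg$acceptor[e])
      })
      anchors <- c(up = base + cfg$flank_len / 2,
                   dn = base + nchar(dat$reg$region) - cfg$flank_len / 2)
      isoforms <- list(gene_alignment(
        g$id, paste0(g$id, ".t1"), sp, lay$contig_of[gi], exon_list,
        anchors = anchors, cds_len = g$cds_len, validate = FALSE))
      if (!is.na(g$alt_drop)) {
        isoforms[[2]] <- gene_alignment(
          g$id, paste0(g$id, ".t2"), sp, lay$contig_of[gi],
          exon_list[-g$alt_drop], anchors = anchors,
          cds_len = g$cds_len - g$exon_lens[g$alt_drop], validate = FALSE)
      }
      alignments[[g$id]][[sp]] <- isoforms
    }
  }

  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(gene = character(0), species = character(0),
               kind = character(0), class = character(0),
               exon = integer(0), cds_pos = numeric(0))
  loss_table <- if (length(loss_rows)) do.call(rbind, loss_rows) else
    data.frame(gene = character(0), branch = character(0),
               node = numeric(0), species = character(0))
  structure(list(config = cfg, tree = tree, reference = cfg$reference,
                 species = queries, genes = genes, assemblies = assemblies,
                 annotation = annotation, alignments = alignments,
                 cds = setNames(cds_store,
                                vapply(genes, `[[`, character(1), "id")),
                 loci = loci, truth = truth, loss_table = loss_table),
            class = "geneloss_sim")
}

#' @export
print.geneloss_sim <- function(x, ...) {
  cat(sprintf("<geneloss_sim> %d genes (%d with injected loss) x %d query species\n",
              length(x$genes), nrow(x$loss_table), length(x$species)))
  invisible(x)
}

# iid substitutions on non-coding sequence, splice dinucleotides preserved
mutate_noncoding <- function(s, t) {
  ch <- chars(s)
  n <- length(ch)
  protect <- c(1, 2, n - 1, n)   # GT...AG kept under selection
  idx <- setdiff(which(runif(n) < t), protect)
  if (length(idx) > 0)
    ch[idx] <- vapply(ch[idx], function(b) sample(setdiff(BASES, b), 1),
                      character(1))
  collapse0(ch)
}

#' Corrupt a genome assembly with sequencing errors and N gaps
#'
#' Substitutes bases at rate `err_sub` and inserts Poisson-distributed N
#' runs at `gap_rate` per bp (lengths uniform in `gap_len`).  With both
#' rates 0 the assembly is returned unchanged.
#'
#' @param assembly a [genome_assembly()].
#' @param cfg a [sim_config()] (only the error/gap fields are used).
#' @return a corrupted `genome_assembly`.
#' @export
corrupt <- function(assembly, cfg) {
  if (cfg$err_sub == 0 && cfg$gap_rate == 0) return(assembly)
  seqs <- vapply(assembly$sequences, function(s) {
    ch <- chars(s)
    n <- length(ch)
    idx <- which(runif(n) < cfg$err_sub & ch %in% BASES)
    if (length(idx) > 0)
      ch[idx] <- vapply(ch[idx], function(b) sample(setdiff(BASES, b), 1),
                        character(1))
    n_gaps <- rpois(1, cfg$gap_rate * n)
    for (j in seq_len(n_gaps)) {
      glen <- rint(1, cfg$gap_len[1], cfg$gap_len[2])
      if (n <= glen + 1) next
      at <- sample.int(n - glen, 1)
      ch[at:(at + glen - 1L)] <- "N"
    }
    collapse0(ch)
  }, character(1))
  genome_assembly(assembly$name, seqs)
}

#' Sample unassembled reads from an assembly
#'
#' Uniform read starts at `coverage`x mean depth, per-base error rate
#' `read_err`, random orientation.
#'
#' @param assembly a [genome_assembly()].
#' @param cfg a [sim_config()] (read fields used).
#' @param seed optional seed (defaults to `cfg$seed + 1`).
#' @return named character vector of read sequences.
#' @export
sample_reads <- function(assembly, cfg, seed = cfg$seed + 1L) {
  set.seed(seed)
  out <- character(0)
  for (ctg in names(assembly$sequences)) {
    s <- assembly$sequences[[ctg]]
    len <- nchar(s)
    if (len < cfg$read_len) next
    n <- ceiling(cfg$coverage * len / cfg$read_len)
    starts <- sample.int(len - cfg$read_len + 1L, n, replace = TRUE)
    reads <- substring(s, starts, starts + cfg$read_len - 1L)
    reads <- vapply(reads, function(r) {
      ch <- chars(r)
      idx <- which(runif(length(ch)) < cfg$read_err & ch %in% BASES)
      if (length(idx) > 0)
        ch[idx] <- vapply(ch[idx], function(b) sample(setdiff(BASES, b), 1),
                          character(1))
      collapse0(ch)
    }, character(1), USE.NAMES = FALSE)
    flip <- runif(n) < 0.5
    reads[flip] <- revcomp(reads[flip])
    names(reads) <- sprintf("%s_%s_%d", ctg, seq_len(n), starts - 1L)
    out <- c(out, reads)
  }
  out
}

#' Simulate a %intact matrix directly (for the trait screen)
#'
#' Null genes get phylogeny-correlated noise (Brownian motion on the tree,
#' reflected below 100); convergent-loss genes get %intact drawn low in
#' every derived-phenotype (trait-1) species and high in the background.
#'
#' @param tree phylo object.
#' @param groups named species -> `"trait1"`/`"trait2"` assignment.
#' @param n_null,n_convergent gene counts.
#' @param bm_sd Brownian-motion noise scale (per unit branch length).
#' @param loss_range %intact range for trait-1 species of convergent genes.
#' @param seed random seed.
#' @return list: `matrix` (genes x species), `truth` (character vector,
#'   `"null"`/`"convergent"` per gene).
#' @export
simulate_intact_matrix <- function(tree, groups, n_null = 1000,
                                   n_convergent = 20, bm_sd = 8,
                                   loss_range = c(10, 50), seed = 1L) {
  set.seed(seed)
  species <- tree$tip.label
  C <- brownian_covariance(tree, species)
  Lc <- t(chol(C))
  x1 <- names(groups)[groups == "trait1"]
  n <- n_null + n_convergent
  m <- matrix(NA_real_, n, length(species),
              dimnames = list(sprintf("sim%04d", seq_len(n)), species))
  truth <- rep(c("null", "convergent"), c(n_null, n_convergent))
  for (i in seq_len(n)) {
    z <- as.numeric(Lc %*% rnorm(length(species))) * bm_sd
    y <- pmin(pmax(100 - abs(z), 0), 100)
    if (truth[i] == "convergent")
      y[match(x1, species)] <- runif(length(x1), loss_range[1], loss_range[2])
    m[i, ] <- y
  }
  list(matrix = m, truth = truth)
}

# leaf CDS string of one gene (gap-free, reference frame not guaranteed
# after frameshifts; used for dating fixtures)
cds_of <- function(sim, gene, species) sim$cds[[gene]][[species]]
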