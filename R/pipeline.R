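# End-to-end orchestration: scan -> filter cascade -> loss calling ->
# (optional) trait screen -> (optional) dating -> (optional) read validation.

#' Pipeline thresholds (defaults as printed in the study design)
#'
#' * `intact_max` 60: %intact below which a gene can be a loss candidate.
#' * `exon_fraction` 0.2: minimum fraction of exons with mutations.
#' * `single_exon_min_muts` 2: minimum mutations for single-exon genes.
#' * `big_indel_min` 51: frame-preserving indels longer than 50 bp inactivate.
#' * `terminal_trim` 0.2: mutations in the first/last 20% are trimmed.
#' * `splice_shift_window` 18: half-width (bp) of the splice-shift rescue scan.
#' * `pgls_p` 1e-6: selection threshold of the trait screen.
#' * `t2_intact_fraction` 0.9 / `t2_intact_cut` 90, `t2_broken_fraction`
#'   0.05 / `t2_broken_cut` 60, `missing_fraction` 0.5: trait-screen
#'   prefilters.
#' * `read_flank` 50 / `read_min_support` 10: read validation.
#'
#' @param ... overrides for any of the above.
#' @return list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(intact_max = 60, exon_fraction = 0.2, single_exon_min_muts = 2L,
              big_indel_min = 51L, terminal_trim = 0.2,
              splice_shift_window = 18L, pgls_p = 1e-6,
              t2_intact_fraction = 0.9, t2_intact_cut = 90,
              t2_broken_fraction = 0.05, t2_broken_cut = 60,
              missing_fraction = 0.5, read_flank = 50L,
              read_min_support = 10L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0)
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Run the gene-loss pipeline on a simulated (or assembled) data set
#'
#' Stages run in order: mutation scan + filter cascade per gene x species,
#' loss classification and ancestral-presence inference, then optionally the
#' phylogenetic trait screen (when `groups` is given) and loss dating (when
#' `time_bounds` is given).
#'
#' @param sim a [simulate_geneloss()] result (or an object with the same
#'   shape assembled from files, see [read_maf()] and
#'   [collect_gene_alignments()]).
#' @param config a [run_config()].
#' @param groups optional named species -> `"trait1"`/`"trait2"` assignment;
#'   enables the forward-genomics stage.
#' @param time_bounds optional data.frame (`branch`, `T_lower`, `T_upper`);
#'   enables the dating stage (branches labelled by species name, or by the
#'   sorted loss species joined with `+` for shared losses).
#' @param progress print progress every 200 genes.
#' @return list of class `geneloss_run`: `statuses` (gene x species rows),
#'   `matrix` + `classification` (from [call_losses()]), `muts`, `trace`,
#'   `ancestral` (per gene: eligible clade + dropped candidates),
#'   `pgls` (or `NULL`), `dating` (or `NULL`), `manifest`.
#' @export
run_pipeline <- function(sim, config = run_config(), groups = NULL,
                         time_bounds = NULL, progress = FALSE) {
  ref_contig_of <- vapply(sim$genes, function(g)
    sim$annotation[[paste0(g$id, ".t1")]]$contig, character(1))
  status_rows <- vector("list", length(sim$genes) * length(sim$species))
  mut_rows <- list(); trace_rows <- list()
  k <- 0L
  for (gi in seq_along(sim$genes)) {
    g <- sim$genes[[gi]]
    if (progress && gi %% 200 == 0) message("  gene ", gi)
    for (sp in sim$species) {
      galns <- sim$alignments[[g$id]][[sp]]
      asm <- sim$assemblies[[sp]]
      ctg <- galns[[1]]$qry_contig
      loci <- sim$loci[[sp]]
      syn <- NULL
      up_ok <- gi > 1 && ref_contig_of[gi - 1] == ref_contig_of[gi]
      dn_ok <- gi < length(sim$genes) &&
        ref_contig_of[gi + 1] == ref_contig_of[gi]
      if (up_ok && dn_ok) {
        syn <- list(
          gene = list(contig = loci$contig[gi], pos = loci$pos[gi]),
          up = list(contig = loci$contig[gi - 1], pos = loci$pos[gi - 1]),
          dn = list(contig = loci$contig[gi + 1], pos = loci$pos[gi + 1]))
      }
      res <- filter_cascade(galns, gaps = asm$gaps[[ctg]],
                            qry_seq = asm$sequences[[ctg]],
                            synteny = syn, config = config)
      k <- k + 1L
      status_rows[[k]] <- res$status
      if (nrow(res$muts) > 0) mut_rows[[length(mut_rows) + 1L]] <- res$muts
      trace_rows[[length(trace_rows) + 1L]] <- res$trace
    }
  }
  statuses <- do.call(rbind, status_rows[seq_len(k)])
  muts <- if (length(mut_rows)) do.call(rbind, mut_rows) else mutation_table()
  trace <- do.call(rbind, trace_rows)
  called <- call_losses(statuses)

  # ancestral presence per gene with at least one loss candidate
  ancestral <- list()
  for (g in rownames(called$classification)) {
    cl <- called$classification[g, ]
    loss_sp <- names(cl)[!is.na(cl) & cl == "loss_candidate"]
    if (length(loss_sp) == 0) next
    intact_sp <- names(cl)[!is.na(cl) & cl == "intact"]
    anc <- infer_ancestral_presence(sim$tree, intact_sp, sim$reference,
                                    loss_sp)
    ancestral[[g]] <- anc
    if (length(anc$dropped) > 0) {
      drop_idx <- statuses$gene == g & statuses$species %in% anc$dropped
      statuses$classification[drop_idx] <- "not_ancestrally_present"
      called$classification[g, anc$dropped] <- "not_ancestrally_present"
    }
  }

  pgls <- NULL
  if (!is.null(groups)) {
    pgls <- rank_and_select(
      forward_genomics(called$matrix, sim$tree, groups,
                       missing_fraction = config$missing_fraction,
                       t2_intact_fraction = config$t2_intact_fraction,
                       t2_intact_cut = config$t2_intact_cut,
                       t2_broken_fraction = config$t2_broken_fraction,
                       t2_broken_cut = config$t2_broken_cut),
      p_threshold = config$pgls_p)
  }

  dating <- NULL
  if (!is.null(time_bounds)) dating <- date_losses(sim, called, time_bounds)

  step_counts <- stats::aggregate(cbind(n_before, n_after) ~ step, data = trace,
                                  FUN = sum)
  step_counts <- step_counts[match(unique(trace$step), step_counts$step), ]
  manifest <- list(
    config = unclass(config),
    config_hash = content_hash(unclass(config)),
    n_genes = length(sim$genes), n_species = length(sim$species),
    steps = step_counts,
    n_loss_calls = sum(called$classification == "loss_candidate",
                       na.rm = TRUE),
    n_missing = sum(called$classification == "missing_data", na.rm = TRUE))
  manifest$hash <- content_hash(list(statuses, muts, manifest$steps))
  structure(list(statuses = statuses, matrix = called$matrix,
                 classification = called$classification, muts = muts,
                 trace = trace, ancestral = ancestral, pgls = pgls,
                 dating = dating, manifest = manifest),
            class = "geneloss_run")
}

#' @export
print.geneloss_run <- function(x, ...) {
  cat(sprintf("<geneloss_run> %d genes x %d species: %d loss calls, %d missing\n",
              x$manifest$n_genes, x$manifest$n_species,
              x$manifest$n_loss_calls, x$manifest$n_missing))
  print(x$manifest$steps)
  invisible(x)
}

# query sequence of one gene in reference CDS coordinates: deletions as "-",
# insertions dropped; for dating comparisons across species
ref_frame_seq <- function(galn) {
  out <- character(length(galn$exons))
  for (i in seq_along(galn$exons)) {
    e <- galn$exons[[i]]
    if (!isTRUE(e$present)) {
      out[i] <- collapse0(rep("-", e$ref_len))
      next
    }
    r <- chars(e$ref); q <- chars(e$qry)
    out[i] <- collapse0(q[r != "-"])
  }
  collapse0(out)
}

# dating stage over the loss calls of a pipeline run
date_losses <- function(sim, called, time_bounds) {
  rows <- list()
  for (g in rownames(called$classification)) {
    cl <- called$classification[g, ]
    loss_sp <- names(cl)[!is.na(cl) & cl == "loss_candidate"]
    intact_sp <- names(cl)[!is.na(cl) & cl == "intact"]
    if (length(loss_sp) == 0 || length(intact_sp) < 2) next
    seqs <- vapply(c(loss_sp, intact_sp), function(sp)
      ref_frame_seq(sim$alignments[[g]][[sp]][[1]]), character(1))
    branch <- if (length(loss_sp) > 1)
      paste(sort(loss_sp), collapse = "+") else loss_sp
    tb <- time_bounds[time_bounds$branch == branch, , drop = FALSE]
    if (nrow(tb) == 0) next
    fit <- tryCatch(
      date_loss(seqs[[loss_sp[1]]], seqs[intact_sp], tb$T_lower[1],
                tb$T_upper[1], gene = g, branch = branch),
      error = function(e) NULL)
    if (!is.null(fit)) rows[[length(rows) + 1L]] <- fit
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}
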