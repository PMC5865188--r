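# Truth-labelled synthetic evolution: coding genes evolve along a species
# tree under purifying selection (target Ka/Ks = omega_sel) or neutrally
# after an inactivation switch point on configured loss branches; assemblies
# are corrupted with sequencing errors and N gaps; alignments are emitted
# from the known homology (no heuristic aligner), so every detected mutation
# is attributable to a recorded cause.

#' Configuration for the synthetic-evolution generator
#'
#' Branch lengths of `tree` are expected neutral substitutions per site.
#' Defaults emulate a small mammal-like study: ~0.1-0.25 substitutions per
#' neutral site from root to tip, purifying selection at Ka/Ks 0.2, short
#' in-frame indels in conserved genes, draft-assembly artifact rates, and
#' trace-archive-style reads (800 bp, 1% per-base error, 20x coverage).
#'
#' @param tree Newick string or phylo; must contain `reference` as a leaf.
#' @param reference reference species leaf name.
#' @param n_genes number of conserved genes.
#' @param n_loss_genes number of genes additionally simulated with an
#'   inactivation event.
#' @param loss_branches character vector of branch labels the losses are
#'   injected on, each a leaf name or `"a+b"` (the branch above the MRCA of
#'   leaves a and b); recycled over loss genes.  Default: picked from the
#'   non-reference leaves.
#' @param loss_switch fraction of the loss branch evolved under selection
#'   before the inactivation (default 0.5).
#' @param exons_per_gene,exon_len,intron_len,flank_len gene-structure ranges
#'   (bp); exon count and lengths are sampled uniformly.
#' @param genes_per_contig reference/query contig size in genes.
#' @param alt_iso_prob fraction of genes carrying an alternative isoform
#'   (one frame-preserving internal exon skipped).
#' @param omega_sel target Ka/Ks under selection.
#' @param indel_rate in-frame codon indel events per codon per unit branch
#'   length (conserved-gene indels; never frameshifting).
#' @param err_sub,err_indel per-base assembly substitution / 1-bp indel
#'   error rates in the query species.
#' @param gap_rate expected assembly N runs per bp; `gap_len` length range.
#' @param splice_shift_prob,intron_del_prob,misplace_prob,pseudogene_prob
#'   per-gene-per-species rates of: a +3 bp donor shift, a precise intron
#'   deletion, a 1-column misplacement of an evolved indel by the emitting
#'   aligner, and alignment to a retroposed copy on a different contig.
#' @param read_len,read_err,coverage read-sampling parameters.
#' @param seed integer random seed; a fixed seed gives byte-identical output.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(tree = "(((qA:0.06,qB:0.06):0.04,(qC:0.05,qD:0.05):0.05):0.05,(qE:0.12,ref:0.12):0.03);",
                       reference = "ref", n_genes = 50, n_loss_genes = 0,
                       loss_branches = NULL, loss_switch = 0.5,
                       exons_per_gene = c(3L, 8L), exon_len = c(60L, 180L),
                       intron_len = c(60L, 120L), flank_len = 100L,
                       genes_per_contig = 50L, alt_iso_prob = 0.2,
                       omega_sel = 0.2, indel_rate = 0.003,
                       err_sub = 2e-5, err_indel = 2e-6,
                       gap_rate = 1e-5, gap_len = c(50L, 300L),
                       splice_shift_prob = 0.02, intron_del_prob = 0.01,
                       misplace_prob = 0.2, pseudogene_prob = 0.005,
                       read_len = 800L, read_err = 0.01, coverage = 20,
                       seed = 1L) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"), reference %in% tree$tip.label)
  cfg <- as.list(environment())
  stopifnot(cfg$omega_sel >= 0, cfg$indel_rate >= 0, cfg$err_sub >= 0,
            cfg$err_indel >= 0, cfg$gap_rate >= 0, cfg$coverage >= 0,
            cfg$loss_switch >= 0, cfg$loss_switch <= 1)
  if (cfg$n_loss_genes > 0 && is.null(cfg$loss_branches)) {
    qs <- setdiff(tree$tip.label, reference)
    cfg$loss_branches <- qs[seq_len(min(3L, length(qs)))]
  }
  structure(cfg, class = "sim_config")
}

# resolve a branch label ("leaf" or "a+b") to the child node of the branch
branch_node <- function(tree, label) {
  if (grepl("+", label, fixed = TRUE)) {
    tips <- strsplit(label, "+", fixed = TRUE)[[1]]
    stopifnot(all(tips %in% tree$tip.label))
    ape::getMRCA(tree, tips)
  } else {
    stopifnot(label %in% tree$tip.label)
    match(label, tree$tip.label)
  }
}

# ---------------------------------------------------------------------------
# gene structure

rint <- function(n, lo, hi) lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L

sample_gene_struct <- function(id, cfg) {
  n_ex <- rint(1, cfg$exons_per_gene[1], cfg$exons_per_gene[2])
  lens <- rint(n_ex, cfg$exon_len[1], cfg$exon_len[2])
  extra <- (3 - sum(lens) %% 3) %% 3
  lens[n_ex] <- lens[n_ex] + extra
  offs <- cumsum(c(0L, lens))
  n_cod <- sum(lens) / 3L
  # codons usable for evolved indels: >= 1 codon away from any exon boundary
  codon_exon <- rep(NA_integer_, n_cod)
  for (e in seq_len(n_ex)) {
    lo <- offs[e]; hi <- offs[e + 1]
    c_ok <- which((seq_len(n_cod) - 1) * 3 >= lo + 3 &
                    seq_len(n_cod) * 3 <= hi - 3)
    codon_exon[c_ok] <- e
  }
  introns <- replicate(max(n_ex - 1L, 0L), {
    len <- rint(1, cfg$intron_len[1], cfg$intron_len[2])
    paste0("GT", random_dna(len - 4L), "AG")
  })
  alt_candidates <- which(lens %% 3 == 0 & seq_along(lens) > 1 &
                            seq_along(lens) < n_ex)
  alt_drop <- if (length(alt_candidates) > 0 && runif(1) < cfg$alt_iso_prob)
    alt_candidates[sample.int(length(alt_candidates), 1)] else NA_integer_
  list(id = id, n_exons = n_ex, exon_lens = lens, offs = offs,
       cds_len = sum(lens), n_codons = n_cod, codon_exon = codon_exon,
       anc_cds = random_cds(n_cod), introns = as.list(introns),
       alt_drop = alt_drop)
}

# ---------------------------------------------------------------------------
# sequence evolution at codon granularity

init_state <- function(gstruct) {
  list(cod = codons_of(gstruct$anc_cds), anc = seq_len(gstruct$n_codons),
       neutral = FALSE, injected = list(), lock = integer(0), ins_n = 0L)
}

evolve_branch <- function(st, t, cfg, gstruct, indels_ok = TRUE) {
  if (t <= 0) return(st)
  code <- ng86_tables()$code
  n_cod <- length(st$cod)
  n <- rpois(1, t * 3 * n_cod)
  if (n > 0) {
    idx <- sample.int(n_cod, n, replace = TRUE)
    pos <- sample.int(3L, n, replace = TRUE)
    base <- sample(BASES, n, replace = TRUE)
    locked <- if (length(st$lock)) st$anc[seq_along(st$cod)] %in% st$lock
    else rep(FALSE, length(st$cod))
    apply_sub <- function(i, p, b) {
      old <- st$cod[i]
      if (substr(old, p, p) == b) return()
      new <- old; substr(new, p, p) <- b
      if (locked[i] && !is_stop(new)) return()
      acc <- if (st$neutral) TRUE
      else if (is_stop(new)) FALSE
      else if (code[[new]] == code[[old]]) TRUE
      else runif(1) < cfg$omega_sel
      if (acc) st$cod[i] <<- new
    }
    if (anyDuplicated(idx) == 0L && !st$neutral) {
      old <- st$cod[idx]
      new <- old
      substr(new, pos, pos) <- base
      changed <- new != old
      aa_same <- vapply(seq_len(n), function(j)
        !is_stop(new[j]) && code[[new[j]]] == code[[old[j]]], logical(1))
      acc <- changed & !is_stop(new) & (aa_same | runif(n) < cfg$omega_sel) &
        !locked[idx]
      st$cod[idx[acc]] <- new[acc]
    } else if (anyDuplicated(idx) == 0L) {
      old <- st$cod[idx]
      new <- old
      substr(new, pos, pos) <- base
      acc <- !locked[idx] | vapply(new, is_stop, logical(1))
      st$cod[idx[acc]] <- new[acc]
    } else {
      for (j in seq_len(n)) apply_sub(idx[j], pos[j], base[j])
    }
  }
  if (indels_ok && cfg$indel_rate > 0) {
    n_ind <- rpois(1, cfg$indel_rate * t * n_cod)
    for (j in seq_len(n_ind)) {
      k <- sample(1:2, 1)
      ok <- codon_slot_ok(st, gstruct, k)
      if (length(ok) == 0) next
      at <- if (length(ok) == 1) ok else sample(ok, 1)
      if (runif(1) < 0.5) {    # deletion of k codons
        keep <- setdiff(seq_along(st$cod), at:(at + k - 1L))
        st$cod <- st$cod[keep]; st$anc <- st$anc[keep]
      } else {                 # insertion of k sense codons after slot `at`
        sense <- setdiff(names(ng86_tables()$code), STOP_CODONS)
        newc <- sample(sense, k, replace = TRUE)
        st$ins_n <- st$ins_n + k
        ids <- -(st$ins_n - seq_len(k) + 1L)
        st$cod <- append(st$cod, newc, after = at)
        st$anc <- append(st$anc, ids, after = at)
      }
    }
  }
  st
}

# live codon slots fully inside one exon (by ancestral id), k consecutive
codon_slot_ok <- function(st, gstruct, k) {
  a <- st$anc
  e <- rep(NA_integer_, length(a))
  e[a > 0] <- gstruct$codon_exon[a[a > 0]]
  ok <- !is.na(e)
  if (length(st$lock)) ok <- ok & !(a %in% st$lock)
  if (k == 1L) return(which(ok))
  which(ok[-length(ok)] & ok[-1] &
          e[-length(e)] == e[-1])
}

# inject 2-3 inactivating mutations (stop codons 5' of frameshifts, distinct
# exons where possible, within the central 25-75% of the CDS)
inject_loss <- function(st, gstruct, cfg) {
  offs <- gstruct$offs; L <- gstruct$cds_len
  band <- c(0.25 * L, 0.75 * L)
  spans <- lapply(seq_len(gstruct$n_exons), function(e) {
    lo <- max(offs[e] + 6, band[1]); hi <- min(offs[e + 1] - 6, band[2])
    if (hi - lo < 3) NULL else c(lo, hi)
  })
  elig <- which(!vapply(spans, is.null, logical(1)))
  # keep injections in constitutive exons: the alternative isoform must not
  # be able to splice the loss away
  if (!is.na(gstruct$alt_drop) && length(setdiff(elig, gstruct$alt_drop)) > 0)
    elig <- setdiff(elig, gstruct$alt_drop)
  events <- list()
  put_stop <- function(p) {
    ci <- floor(p / 3) + 1L
    j <- match(ci, st$anc)
    if (is.na(j)) return(FALSE)
    st$cod[j] <<- sample(STOP_CODONS, 1)
    st$lock <<- c(st$lock, ci)
    events[[length(events) + 1L]] <<- list(class = "STOP_SUBST",
                                           anc_pos = (ci - 1) * 3, len = NA)
    TRUE
  }
  put_fs <- function(p) {
    len <- sample(1:2, 1)
    kind <- sample(c("FS_DEL", "FS_INS"), 1)
    st$lock <<- c(st$lock, floor(p / 3) + 1L, floor((p + len) / 3) + 1L)
    events[[length(events) + 1L]] <<- list(
      class = kind, anc_pos = p, len = len,
      seq = if (kind == "FS_INS") random_dna(len) else NULL)
    TRUE
  }
  pick <- function(e, frac) {
    s <- spans[[e]]
    round(s[1] + frac * (s[2] - s[1]))
  }
  if (length(elig) >= 3) {
    es <- elig[round(seq(1, length(elig), length.out = 3))]
    put_stop(pick(es[1], runif(1, 0.2, 0.8)))
    put_fs(pick(es[2], runif(1, 0.2, 0.8)))
    put_fs(pick(es[3], runif(1, 0.2, 0.8)))
  } else if (length(elig) == 2) {
    put_stop(pick(elig[1], runif(1, 0.3, 0.7)))
    put_fs(pick(elig[2], runif(1, 0.3, 0.7)))
  } else {
    e <- if (length(elig) == 1) elig else which.max(gstruct$exon_lens)
    s <- spans[[e]] %||% (offs[e] + c(6, gstruct$exon_lens[e] - 6))
    put_stop(round(s[1] + 0.25 * (s[2] - s[1])))
    put_fs(round(s[1] + 0.75 * (s[2] - s[1])))
  }
  st$injected <- c(st$injected, events)
  st$neutral <- TRUE
  st
}

# evolve one gene over the whole tree; returns per-node states at the leaves
evolve_gene <- function(gstruct, tree, cfg, loss_node = NA,
                        ref_path_edges = integer(0)) {
  tree <- ape::reorder.phylo(tree, "cladewise")   # parents precede children
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  states <- vector("list", max(tree$edge))
  states[[root]] <- init_state(gstruct)
  for (k in seq_len(nrow(tree$edge))) {
    par <- tree$edge[k, 1]; chl <- tree$edge[k, 2]
    t <- tree$edge.length[k]
    st <- states[[par]]
    indels_ok <- !(k %in% ref_path_edges)
    if (!is.na(loss_node) && chl == loss_node) {
      st <- evolve_branch(st, t * cfg$loss_switch, cfg, gstruct, indels_ok)
      st <- inject_loss(st, gstruct, cfg)
      st <- evolve_branch(st, t * (1 - cfg$loss_switch), cfg, gstruct,
                          indels_ok)
    } else {
      st <- evolve_branch(st, t, cfg, gstruct, indels_ok)
    }
    states[[chl]] <- st
  }
  setNames(states[seq_len(n_tip)], tree$tip.label)
}

# ---------------------------------------------------------------------------
# materialisation: codon states -> bp-level alignment columns

# returns list(r, q, anc): char vectors of equal length; anc = 0-based
# ancestral CDS position of reference-bearing columns, NA for insertions
materialize_cds_alignment <- function(ref_st, q_st, gstruct) {
  n0 <- gstruct$n_codons
  anc_q <- q_st$anc
  anchor <- cummax(pmax(ifelse(anc_q > 0, anc_q, 0L), 0L))
  ref_entry_q <- rep("---", n0)
  hit <- anc_q > 0
  ref_entry_q[anc_q[hit]] <- q_st$cod[hit]
  keys <- c(seq_len(n0) * 2, anchor[!hit] * 2 + 1)
  tie <- c(rep(0L, n0), which(!hit))
  ref_str <- c(ref_st$cod, rep("---", sum(!hit)))
  qry_str <- c(ref_entry_q, q_st$cod[!hit])
  anc_id <- c(seq_len(n0), rep(NA_integer_, sum(!hit)))
  o <- order(keys, tie)
  ref_str <- ref_str[o]; qry_str <- qry_str[o]; anc_id <- anc_id[o]
  r <- chars(collapse0(ref_str))
  q <- chars(collapse0(qry_str))
  anc <- unlist(lapply(anc_id, function(a)
    if (is.na(a)) rep(NA_real_, 3) else (a - 1) * 3 + 0:2))
  # injected bp-level frameshifts
  for (ev in q_st$injected) {
    if (ev$class == "FS_DEL") {
      tgt <- which(!is.na(anc) & anc >= ev$anc_pos &
                     anc < ev$anc_pos + ev$len & q != "-")
      q[tgt] <- "-"
    } else if (ev$class == "FS_INS") {
      at <- which(!is.na(anc) & anc == ev$anc_pos)[1]
      if (is.na(at)) next
      ins <- chars(ev$seq)
      r <- append(r, rep("-", ev$len), after = at - 1L)
      q <- append(q, ins, after = at - 1L)
      anc <- append(anc, rep(NA_real_, ev$len), after = at - 1L)
    }
  }
  list(r = r, q = q, anc = anc)
}

# split CDS alignment columns into exons; insertion columns follow their
# last reference-bearing predecessor
split_alignment_exons <- function(aln, gstruct) {
  eff <- aln$anc
  last <- -1
  for (i in seq_along(eff)) {
    if (is.na(eff[i])) eff[i] <- last else last <- eff[i]
  }
  lapply(seq_len(gstruct$n_exons), function(e) {
    lo <- gstruct$offs[e]; hi <- gstruct$offs[e + 1]
    cols <- which(eff >= lo & eff < hi | (e == 1 & eff < 0))
    list(r = aln$r[cols], q = aln$q[cols])
  })
}
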