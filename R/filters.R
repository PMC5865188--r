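# Filter cascade removing artifact mutations from conserved genes, applied in
# fixed order: exon presence/assembly gaps -> conserved gene order (synteny)
# -> rescue realignment (splice shifts, precise intron deletions, local
# realignment) -> terminal-20% trim -> isoform selection.

#' Remove mutations explained by assembly gaps
#'
#' Point mutations within 1 query bp of an N run are sequencing/assembly
#' suspects and are marked `filtered_reason = "near_gap"`.  (Deleted or
#' unaligned exons whose inter-anchor region overlaps a gap have already been
#' reclassified `missing_data` by [classify_exon_presence()].)
#'
#' @param muts mutation table.
#' @param gaps assembly-gap intervals of the query contig (matrix/data.frame,
#'   columns start/end, 0-based half-open), or `NULL`.
#' @return `muts` with near-gap events marked.
#' @export
gap_filter <- function(muts, gaps) {
  if (is.null(gaps) || NROW(gaps) == 0 || nrow(muts) == 0) return(muts)
  g <- as.matrix(gaps[, 1:2, drop = FALSE])
  hit <- vapply(seq_len(nrow(muts)), function(i) {
    p <- muts$qry_pos[i]
    if (is.na(p) || muts$filtered_reason[i] != "" ||
        muts$class[i] %in% c("EXON_DELETED", "EXON_UNALIGNED")) return(FALSE)
    span <- if (!is.na(muts$length[i])) muts$length[i] else 1
    any(g[, 1] - 1 <= p + span & g[, 2] + 1 >= p)
  }, logical(1))
  muts$filtered_reason[hit] <- "near_gap"
  muts
}

#' Conserved-gene-order (synteny) check
#'
#' A gene passes when its aligned query locus lies on the same query contig
#' as, and strictly between, the query loci of its nearest up- and downstream
#' reference neighbours (a jointly inverted order is fine: strand flips
#' invert whole neighbourhoods).  Failure indicates alignment to a processed
#' pseudogene or paralog; such genes are excluded from loss calling entirely.
#' Unaligned neighbours give a pass with a warning (insufficient evidence to
#' fail).
#'
#' @param gene_locus list/vector with `contig` and `pos` of the gene's query
#'   alignment.
#' @param up_locus,dn_locus same for the nearest up/downstream reference
#'   neighbours (`NULL`/`NA` when unaligned or at a contig end).
#' @return `"pass"` or `"fail"`.
#' @export
synteny_filter <- function(gene_locus, up_locus, dn_locus) {
  bad <- function(l) is.null(l) || is.na(l[["contig"]]) || is.na(l[["pos"]])
  if (bad(up_locus) || bad(dn_locus)) {
    warning("neighbour loci unaligned; synteny not assessable, passing")
    return("pass")
  }
  same <- identical(gene_locus[["contig"]], up_locus[["contig"]]) &&
    identical(gene_locus[["contig"]], dn_locus[["contig"]])
  if (!same) return("fail")
  p <- as.numeric(gene_locus[["pos"]])
  a <- as.numeric(up_locus[["pos"]]); b <- as.numeric(dn_locus[["pos"]])
  if ((a < p && p < b) || (b < p && p < a)) "pass" else "fail"
}

has_stop_inframe <- function(seq, start_phase) {
  # seq starts at codon position start_phase (0..2); checks complete codons
  o <- (3L - start_phase) %% 3L
  any(is_stop(codons_of(toupper(seq), from = o)))
}

#' Rescue mutations explained by exon-structure-aware realignment
#'
#' Three rescue rules for exons carrying candidate mutations:
#' \enumerate{
#' \item splice-site shift: scan +-`window` bp (default 18) around a
#'   disrupted splice site for a consensus dinucleotide whose use preserves
#'   the reading frame (offset divisible by 3) and introduces no stop codon
#'   in the gained sequence; if found, the splice mutation is marked
#'   `"splice_shift"`.
#' \item precise intron deletion: when the query aligns two neighbouring
#'   exons contiguously (a larger composite exon), the donor/acceptor
#'   mutations of that intron are marked `"intron_deletion"`.
#' \item local realignment: each mutation-bearing exon is re-aligned with an
#'   affine-gap global aligner, gaps are slid onto codon boundaries where
#'   score-neutral, and mutations absent from the re-scan are marked
#'   `"realign"`.
#' }
#' Rescue only removes (marks) records; it never adds any.
#'
#' @param galn a [gene_alignment()].
#' @param muts mutation table for this gene x species (all its exons).
#' @param qry_seq full query contig sequence (string) for splice-shift
#'   context; `NULL` disables rule 1.
#' @param window splice-shift search half-width in bp.
#' @param big_indel_min passed to the re-scan.
#' @return `muts` with rescue marks applied.
#' @export
rescue_realign <- function(galn, muts, qry_seq = NULL, window = 18L,
                           big_indel_min = 51L) {
  if (nrow(muts) == 0) return(muts)
  offsets <- exon_cds_offsets(galn)
  n_exons <- length(galn$exons)

  # rule 2: precise intron deletion (checked first: it explains both sites)
  for (i in seq_len(n_exons - 1L)) {
    e1 <- galn$exons[[i]]; e2 <- galn$exons[[i + 1L]]
    if (isTRUE(e1$present) && isTRUE(e2$present) &&
        !is.na(e1$qry_end) && !is.na(e2$qry_start) &&
        e2$qry_start == e1$qry_end) {
      don <- muts$class == "SPLICE_DONOR" & muts$exon == i - 1L &
        muts$filtered_reason == ""
      acc <- muts$class == "SPLICE_ACCEPTOR" & muts$exon == i &
        muts$filtered_reason == ""
      muts$filtered_reason[don | acc] <- "intron_deletion"
    }
  }

  # rule 1: splice-site shift
  if (!is.null(qry_seq)) {
    qlen <- nchar(qry_seq)
    cand <- which(muts$class %in% c("SPLICE_DONOR", "SPLICE_ACCEPTOR") &
                    muts$filtered_reason == "")
    for (m in cand) {
      i <- muts$exon[m] + 1L
      e <- galn$exons[[i]]
      if (!isTRUE(e$present)) next
      deltas <- setdiff(seq(-window, window, by = 3L), 0L)
      deltas <- deltas[order(abs(deltas))]
      found <- FALSE
      for (d in deltas) {
        if (muts$class[m] == "SPLICE_DONOR") {
          pos <- e$qry_end + d               # candidate intron start
          if (pos < 0 || pos + 2 > qlen) next
          dinuc <- toupper(substr(qry_seq, pos + 1, pos + 2))
          if (!(dinuc %in% c("GT", "GC"))) next
          if (d > 0) {   # exon gains d bases before the new donor
            gained <- substr(qry_seq, e$qry_end + 1, e$qry_end + d)
            if (has_stop_inframe(gained, (offsets[i] + e$ref_len) %% 3)) next
          }
        } else {
          pos <- e$qry_start + d - 2         # candidate intron last 2 bases
          if (pos < 0 || pos + 2 > qlen) next
          dinuc <- toupper(substr(qry_seq, pos + 1, pos + 2))
          if (dinuc != "AG") next
          if (d < 0) {   # exon gains |d| bases after the new acceptor
            gained <- substr(qry_seq, e$qry_start + d + 1, e$qry_start)
            if (has_stop_inframe(gained, offsets[i] %% 3)) next
          }
        }
        found <- TRUE
        break
      }
      if (found) muts$filtered_reason[m] <- "splice_shift"
    }
  }

  # rule 3: frame-aware local realignment of mutation-bearing exons
  realn_classes <- c("FS_INS", "FS_DEL", "STOP_SUBST", "STOP_IN_INS",
                     "BIG_INDEL")
  for (i in seq_len(n_exons)) {
    rows <- which(muts$exon == i - 1L & muts$class %in% realn_classes &
                    muts$filtered_reason == "")
    if (length(rows) == 0) next
    e <- galn$exons[[i]]
    if (!isTRUE(e$present)) next
    ref0 <- gsub("-", "", e$ref, fixed = TRUE)
    qry0 <- gsub("-", "", e$qry, fixed = TRUE)
    if (nchar(qry0) == 0) next
    re <- realign_exon(ref0, qry0)
    re <- slide_gaps_to_codons(re$ref, re$qry, phase = offsets[i] %% 3)
    rescan <- scan_exon(re$ref, re$qry, phase = offsets[i] %% 3,
                        cds_offset = offsets[i], cds_len = galn$cds_len,
                        exon = i - 1L, qry_start = e$qry_start,
                        big_indel_min = big_indel_min)
    rescan <- apply_compensation(rescan, cds_len = galn$cds_len)
    rescan <- surviving(rescan)
    for (m in rows) {
      hit <- rescan$class == muts$class[m] &
        abs(rescan$cds_pos - muts$cds_pos[m]) <= 3 &
        (is.na(muts$length[m]) | (!is.na(rescan$length) &
                                    rescan$length == muts$length[m]))
      if (!any(hit, na.rm = TRUE)) muts$filtered_reason[m] <- "realign"
    }
  }
  muts
}

# affine-gap global realignment of one exon (Biostrings engine)
realign_exon <- function(ref0, qry0) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(qry0), subject = Biostrings::DNAString(ref0),
    type = "global", substitutionMatrix = mat,
    gapOpening = 6, gapExtension = 2)
  list(ref = as.character(Biostrings::alignedSubject(pa)),
       qry = as.character(Biostrings::alignedPattern(pa)))
}

# slide indels onto codon boundaries where a score-neutral shift exists
slide_gaps_to_codons <- function(ref, qry, phase = 0L) {
  rs <- chars(ref); qs <- chars(qry)
  for (row in 1:2) {
    gapv <- if (row == 1) rs == "-" else qs == "-"
    other <- if (row == 1) qs else rs
    runs <- runs_of(gapv)
    for (k in seq_len(nrow(runs))) {
      a <- runs$start[k]; b <- runs$end[k]
      ref_before <- sum(rs[seq_len(a - 1L)] != "-")
      mis <- (ref_before + phase) %% 3L
      if (mis == 0L) next
      for (shift in c(-mis, 3L - mis)) {
        a2 <- a + shift; b2 <- b + shift
        if (a2 < 1L || b2 > length(gapv)) next
        moved <- if (shift < 0) other[a2:(a - 1L)] else other[(b + 1L):b2]
        stay <- if (shift < 0) other[(b + shift + 1L):b] else other[a:(a2 - 1L)]
        if (identical(moved, stay)) {   # score-neutral slide
          seg <- if (row == 1) rs else qs
          keep <- seg[c(setdiff(seq_len(length(seg)), a:b))]
          # rebuild with the gap at [a2, b2]
          newseg <- character(length(seg))
          newseg[a2:b2] <- "-"
          newseg[setdiff(seq_along(seg), a2:b2)] <- keep
          if (row == 1) rs <- newseg else qs <- newseg
          break
        }
      }
    }
  }
  list(ref = collapse0(rs), qry = collapse0(qs))
}

#' Trim mutations in the terminal 20% of the protein
#'
#' N and C termini are under weaker evolutionary constraint; surviving
#' mutations with relative CDS position strictly below `trim` or strictly
#' above `1 - trim` are marked `filtered_reason = "terminal"`.  Positions
#' exactly at the boundary are kept.
#'
#' @param muts mutation table with `rel_pos` filled in.
#' @param trim terminal fraction (default 0.2).
#' @return `muts` with terminal events marked.
#' @export
terminal_trim <- function(muts, trim = 0.2) {
  if (nrow(muts) == 0) return(muts)
  hit <- muts$filtered_reason == "" &
    (muts$rel_pos < trim | muts$rel_pos > 1 - trim)
  muts$filtered_reason[hit] <- "terminal"
  muts
}

#' Choose the isoform with the fewest surviving mutations
#'
#' Ties are broken by longer CDS, then lexicographically smaller transcript
#' id.  Isoforms that are missing data are not eligible; if all are, the
#' gene is missing data in this species.
#'
#' @param isoforms data.frame with columns `tx`, `n_mutations`, `cds_len`,
#'   `missing` (logical).
#' @return the chosen `tx`, or `NA_character_` when all isoforms are missing.
#' @export
select_isoform <- function(isoforms) {
  ok <- isoforms[!isoforms$missing, , drop = FALSE]
  if (nrow(ok) == 0) return(NA_character_)
  ok <- ok[order(ok$n_mutations, -ok$cds_len, ok$tx), , drop = FALSE]
  ok$tx[1]
}

#' Run the full filter cascade for one gene in one query species
#'
#' Applies, in order: per-exon scan (with presence/assembly-gap handling and
#' frameshift compensation), the near-gap point filter, the synteny check,
#' rescue realignment, the terminal-20% trim, and isoform selection; then
#' summarises the gene (%intact, classification).
#'
#' @param galns list of [gene_alignment()]s, one per isoform of one gene in
#'   one query species.
#' @param gaps assembly-gap intervals of the query contig, or `NULL`.
#' @param qry_seq query contig sequence for splice-shift rescue, or `NULL`.
#' @param synteny `NULL` (skip) or list with `gene`, `up`, `dn` loci for
#'   [synteny_filter()].
#' @param config thresholds from [run_config()].
#' @return list with `status` (one-row data.frame: `gene`, `species`, `tx`,
#'   `percent_intact`, `n_exons`, `n_exons_mutated`, `n_mutations`,
#'   `classification`), `muts` (all isoforms, with `filtered_reason`s), and
#'   `trace` (data.frame `gene`, `species`, `step`, `n_before`, `n_after`).
#' @export
filter_cascade <- function(galns, gaps = NULL, qry_seq = NULL,
                           synteny = NULL, config = run_config()) {
  stopifnot(length(galns) >= 1)
  gene <- galns[[1]]$gene_id; species <- galns[[1]]$species
  scans <- lapply(galns, scan_gene, gaps = gaps,
                  big_indel_min = config$big_indel_min)
  per_iso <- lapply(scans, `[[`, "muts")
  statuses <- lapply(scans, `[[`, "exon_status")
  steps <- character(0); befores <- integer(0); afters <- integer(0)
  n_surv <- function(lst) sum(vapply(lst, function(m) nrow(surviving(m)),
                                     integer(1)))
  log_step <- function(step, before, after) {
    steps <<- c(steps, step); befores <<- c(befores, before)
    afters <<- c(afters, after)
    NULL
  }
  n0 <- n_surv(per_iso)
  log_step("scan", n0, n0)

  # 1: assembly gaps (exon presence handled inside scan_gene)
  before <- n_surv(per_iso)
  per_iso <- lapply(per_iso, gap_filter, gaps = gaps)
  log_step("gap", before, n_surv(per_iso))

  # 2: conserved gene order
  before <- n_surv(per_iso)
  synteny_ok <- TRUE
  if (!is.null(synteny)) {
    synteny_ok <- synteny_filter(synteny$gene, synteny$up, synteny$dn) == "pass"
    if (!synteny_ok)
      per_iso <- lapply(per_iso, function(m) {
        m$filtered_reason[m$filtered_reason == ""] <- "synteny"
        m
      })
  }
  log_step("synteny", before, n_surv(per_iso))

  # 3: rescue realignment
  before <- n_surv(per_iso)
  if (synteny_ok)
    per_iso <- Map(function(g, m)
      rescue_realign(g, m, qry_seq = qry_seq,
                     window = config$splice_shift_window,
                     big_indel_min = config$big_indel_min),
      galns, per_iso)
  log_step("rescue", before, n_surv(per_iso))

  # 4: terminal-20% trim
  before <- n_surv(per_iso)
  per_iso <- lapply(per_iso, terminal_trim, trim = config$terminal_trim)
  log_step("terminal", before, n_surv(per_iso))

  # 5: isoform selection
  before <- n_surv(per_iso)
  iso_tab <- data.frame(
    tx = vapply(galns, function(g) g$tx_id, character(1)),
    n_mutations = vapply(per_iso, function(m) nrow(surviving(m)), integer(1)),
    cds_len = vapply(galns, function(g) g$cds_len, numeric(1)),
    missing = vapply(statuses, function(s)
      mean(s == "missing_data") > 0.5, logical(1)),
    stringsAsFactors = FALSE)
  if (!synteny_ok) iso_tab$missing <- TRUE
  chosen <- select_isoform(iso_tab)
  log_step("isoform", before,
           if (is.na(chosen)) 0L else
             iso_tab$n_mutations[iso_tab$tx == chosen])
  trace <- data.frame(gene = gene, species = species, step = steps,
                      n_before = befores, n_after = afters,
                      stringsAsFactors = FALSE)

  all_muts <- do.call(bind_mutations, per_iso)
  if (is.na(chosen)) {
    status <- data.frame(gene = gene, species = species, tx = NA_character_,
                         percent_intact = NA_real_, n_exons = NA_integer_,
                         n_exons_mutated = NA_integer_,
                         n_mutations = NA_integer_,
                         classification = "missing_data",
                         stringsAsFactors = FALSE)
    return(list(status = status, muts = all_muts, trace = trace))
  }
  ci <- which(iso_tab$tx == chosen)[1]
  surv <- surviving(per_iso[[ci]])
  # gene-level %intact: maximum over (assessable) isoforms
  pis <- vapply(which(!iso_tab$missing), function(j)
    percent_intact(surviving(per_iso[[j]])$rel_pos), numeric(1))
  status <- data.frame(
    gene = gene, species = species, tx = chosen,
    percent_intact = max(pis),
    n_exons = length(galns[[ci]]$exons),
    n_exons_mutated = length(unique(surv$exon)),
    n_mutations = nrow(surv),
    classification = NA_character_, stringsAsFactors = FALSE)
  status$classification <- classify_gene(
    status$percent_intact, status$n_exons, status$n_exons_mutated,
    status$n_mutations, missing = FALSE,
    intact_max = config$intact_max, exon_fraction = config$exon_fraction,
    single_exon_min_muts = config$single_exon_min_muts)
  list(status = status, muts = all_muts, trace = trace)
}
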