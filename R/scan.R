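# Scan aligned exons for gene-inactivating mutations:
#   (i)   insertions/deletions that shift the reading frame,
#   (ii)  frame-preserving insertions that create a premature stop codon,
#   (iii) substitutions that create an in-frame stop codon,
#   (iv)  splice-site disruptions (donor not GT/GC, acceptor not AG),
# plus frame-preserving indels longer than 50 bp and deleted/unaligned exons.

EMPTY_SHIFTED <- data.frame(qoff = integer(0), cds_pos = numeric(0),
                            codon = character(0), stringsAsFactors = FALSE)

runs_of <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Scan one aligned exon for inactivating mutations
#'
#' Detects frameshifting indels, frame-preserving indels longer than
#' `big_indel_min - 1` bp, stop codons created by substitution, and stop
#' codons inside frame-preserving insertions.  The query row is translated
#' continuously in the frame implied by the reference (the exon starts at
#' reference phase `phase`), so indels shift the frame of everything
#' downstream; stop codons found while the cumulative indel shift is not a
#' multiple of 3 are returned in the `"shifted_stops"` attribute (they are
#' consequences of a frameshift, not events of their own) and are consumed by
#' [apply_compensation()].
#'
#' @param ref,qry equal-length aligned strings (reference and query rows).
#' @param phase reference reading-frame phase at the exon start (0, 1 or 2:
#'   number of exon bases completing the upstream codon).
#' @param cds_offset 0-based CDS coordinate of the exon's first reference
#'   base.
#' @param cds_len total reference CDS length (for relative positions).
#' @param exon 0-based exon index.
#' @param qry_start 0-based query coordinate of the exon's first query base
#'   (for downstream gap-proximity filtering; `NA` if unknown).
#' @param big_indel_min minimum length (bp) at which a frame-preserving indel
#'   is inactivating (default 51: "longer than 50 bp").
#' @param gene,tx,species identifiers stamped on the rows.
#' @return [mutation_table()] rows, with attribute `shifted_stops` (a
#'   data.frame of stop codons seen in shifted frame).
#' @export
scan_exon <- function(ref, qry, phase, cds_offset = 0, cds_len = NULL,
                      exon = 0L, qry_start = NA_real_, big_indel_min = 51L,
                      gene = NA, tx = NA, species = NA) {
  if (nchar(ref) != nchar(qry)) stop("aligned rows differ in length")
  # fast path: ungapped pair -> only in-frame stop substitutions possible
  if (!grepl("-", ref, fixed = TRUE) && !grepl("-", qry, fixed = TRUE)) {
    ref <- toupper(ref); qry <- toupper(qry)
    if (is.null(cds_len)) cds_len <- cds_offset + nchar(ref)
    o <- (3L - phase) %% 3L
    n <- nchar(qry)
    out <- EMPTY_MUTATIONS
    if (n - o >= 3L) {
      starts <- seq.int(o + 1L, n - 2L, by = 3L)
      qcod <- substring(qry, starts, starts + 2L)
      hits <- which(qcod %in% STOP_CODONS)
      if (length(hits) > 0)
        hits <- hits[substring(ref, starts[hits], starts[hits] + 2L) !=
                       qcod[hits]]
      if (length(hits) > 0) {
        cds_pos <- cds_offset + starts[hits] - 1L
        out <- mutation_table(
          gene = gene, tx = tx, species = species, exon = exon,
          class = "STOP_SUBST", cds_pos = cds_pos,
          rel_pos = pmin(pmax(cds_pos / cds_len, 0), 1),
          detail = qcod[hits],
          qry_pos = if (is.na(qry_start)) NA_real_ else
            qry_start + starts[hits] - 1)
      }
    }
    attr(out, "shifted_stops") <- EMPTY_SHIFTED
    return(out)
  }
  rs <- chars(toupper(ref)); qs <- chars(toupper(qry))
  rgap <- rs == "-"; qgap <- qs == "-"
  if (any(rgap & qgap)) stop("gap aligned to gap")
  if (is.null(cds_len)) cds_len <- cds_offset + sum(!rgap)
  refpos <- cumsum(!rgap)   # reference bases consumed, inclusive
  qpos <- cumsum(!qgap)
  rel <- function(p) pmin(pmax(p / cds_len, 0), 1)
  muts <- EMPTY_MUTATIONS

  add <- function(class, cds_pos, length = NA_real_, detail = "",
                  qry_pos = NA_real_) {
    mutation_table(gene = gene, tx = tx, species = species, exon = exon,
                   class = class, cds_pos = cds_pos, rel_pos = rel(cds_pos),
                   length = length, detail = detail, qry_pos = qry_pos)
  }

  # --- indels ---------------------------------------------------------------
  ins_runs <- runs_of(rgap)
  for (k in seq_len(nrow(ins_runs))) {
    a <- ins_runs$start[k]; b <- ins_runs$end[k]
    len <- b - a + 1L
    cds_pos <- cds_offset + refpos[a]
    qp <- if (is.na(qry_start)) NA_real_ else qry_start + qpos[a] - 1
    if (len %% 3 != 0) {
      muts <- bind_mutations(muts, add("FS_INS", cds_pos, len,
                                       collapse0(qs[a:b]), qp))
    } else if (len >= big_indel_min) {
      muts <- bind_mutations(muts, add("BIG_INDEL", cds_pos, len,
                                       "insertion", qp))
    }
  }
  del_runs <- runs_of(qgap)
  for (k in seq_len(nrow(del_runs))) {
    a <- del_runs$start[k]
    len <- del_runs$end[k] - a + 1L
    cds_pos <- cds_offset + refpos[a] - 1
    qp <- if (is.na(qry_start)) NA_real_ else qry_start + qpos[a]
    if (len %% 3 != 0) {
      muts <- bind_mutations(muts, add("FS_DEL", cds_pos, len, "", qp))
    } else if (len >= big_indel_min) {
      muts <- bind_mutations(muts, add("BIG_INDEL", cds_pos, len,
                                       "deletion", qp))
    }
  }

  # --- stop codons in the continuously translated query ---------------------
  qcols <- which(!qgap)
  Q <- qs[qcols]
  o <- (3L - phase) %% 3L               # first complete codon start (0-based)
  shifted <- data.frame(qoff = integer(0), cds_pos = numeric(0),
                        codon = character(0), stringsAsFactors = FALSE)
  k0 <- o
  while (k0 + 3L <= length(Q)) {
    codon <- collapse0(Q[(k0 + 1L):(k0 + 3L)])
    if (!grepl("[^ACGT]", codon) && is_stop(codon)) {
      cols <- qcols[(k0 + 1L):(k0 + 3L)]
      r_before <- refpos[cols[1]] - as.integer(!rgap[cols[1]])
      shift <- (k0 - r_before) %% 3L
      cds_pos <- cds_offset + r_before
      qp <- if (is.na(qry_start)) NA_real_ else qry_start + k0
      if (shift == 0L) {
        if (any(rgap[cols])) {
          muts <- bind_mutations(muts, add("STOP_IN_INS", cds_pos, NA, codon, qp))
        } else {
          refc <- collapse0(rs[cols])
          if (!identical(refc, codon)) {
            muts <- bind_mutations(muts, add("STOP_SUBST", cds_pos, NA, codon, qp))
          } else if (cols[3] - cols[1] != 2L) {
            # stop spliced together across a frame-preserving deletion
            muts <- bind_mutations(muts,
                                   add("STOP_SUBST", cds_pos, NA,
                                       paste0(codon, ":junction"), qp))
          }
        }
      } else {
        shifted <- rbind(shifted, data.frame(qoff = k0, cds_pos = cds_pos,
                                             codon = codon,
                                             stringsAsFactors = FALSE))
      }
    }
    k0 <- k0 + 3L
  }
  attr(muts, "shifted_stops") <- shifted
  muts
}

#' Mark compensated frameshift pairs
#'
#' Maximal runs of consecutive frameshifting indels whose signed lengths sum
#' to 0 mod 3 restore the downstream reading frame; if the shifted stretch
#' between them contains no stop codon (in the shifted frame), the protein is
#' effectively intact and the events are marked
#' `filtered_reason = "compensated"`.  If a stop codon does arise in the
#' shifted stretch, the frameshifts are retained and the stop is promoted to
#' a mutation record of its own.
#'
#' @param muts mutation rows of one exon (as returned by [scan_exon()],
#'   including the `shifted_stops` attribute, which can also be passed
#'   explicitly).
#' @param shifted_stops data.frame of shifted-frame stops (`qoff`,
#'   `cds_pos`, `codon`); defaults to the attribute on `muts`.
#' @param cds_len CDS length used for relative positions of promoted stops;
#'   recovered from existing rows when possible.
#' @return `muts` with compensation marks applied and promoted stops added.
#' @export
apply_compensation <- function(muts, shifted_stops = NULL, cds_len = NULL) {
  if (is.null(shifted_stops))
    shifted_stops <- attr(muts, "shifted_stops") %||%
      data.frame(qoff = integer(0), cds_pos = numeric(0), codon = character(0))
  fs <- which(muts$class %in% c("FS_INS", "FS_DEL") & muts$filtered_reason == "")
  if (length(fs) < 2) return(muts)
  fs <- fs[order(muts$cds_pos[fs])]
  signed <- ifelse(muts$class[fs] == "FS_INS", muts$length[fs], -muts$length[fs])
  if (is.null(cds_len)) {
    with_rel <- which(!is.na(muts$rel_pos) & muts$rel_pos > 0)
    cds_len <- if (length(with_rel) > 0)
      muts$cds_pos[with_rel[1]] / muts$rel_pos[with_rel[1]] else
      max(muts$cds_pos, na.rm = TRUE) + 1
  }
  start <- 1L; cum <- 0
  for (j in seq_along(fs)) {
    cum <- cum + signed[j]
    if (cum %% 3 == 0) {
      lo <- muts$cds_pos[fs[start]]; hi <- muts$cds_pos[fs[j]]
      blockers <- shifted_stops[shifted_stops$cds_pos >= lo &
                                  shifted_stops$cds_pos <= hi, , drop = FALSE]
      if (nrow(blockers) == 0) {
        muts$filtered_reason[fs[start:j]] <- "compensated"
      } else {
        promoted <- mutation_table(
          gene = muts$gene[fs[1]], tx = muts$tx[fs[1]],
          species = muts$species[fs[1]], exon = muts$exon[fs[1]],
          class = "STOP_SUBST", cds_pos = blockers$cds_pos,
          rel_pos = pmin(pmax(blockers$cds_pos / cds_len, 0), 1),
          detail = paste0(blockers$codon, ":shifted_frame"))
        muts <- bind_mutations(muts, promoted)
      }
      start <- j + 1L; cum <- 0
    }
  }
  muts
}

#' Check query splice-site dinucleotides against the consensus
#'
#' The donor (intron 5' end) must be GT or GC and the acceptor (intron 3'
#' end) must be AG.  The first exon has no acceptor and the last exon no
#' donor; single-exon transcripts are skipped entirely.  Dinucleotides
#' containing N (assembly-gap flank) yield no event - the exon is flagged as
#' unassessable downstream.
#'
#' @param donor,acceptor query intron dinucleotides in transcript
#'   orientation (`NA` when unavailable).
#' @param exon 0-based exon index; `n_exons` total exon count.
#' @param cds_offset,exon_len,cds_len positions for the report.
#' @param gene,tx,species identifiers.
#' @return [mutation_table()] rows (possibly empty).
#' @export
check_splice_sites <- function(donor, acceptor, exon, n_exons,
                               cds_offset = 0, exon_len = 0, cds_len = 1,
                               gene = NA, tx = NA, species = NA) {
  muts <- EMPTY_MUTATIONS
  if (n_exons <= 1L) return(muts)
  usable <- function(x) !is.na(x) && toupper(x) %in% DINUCS
  if (exon < n_exons - 1L && usable(donor) &&
      !(toupper(donor) %in% c("GT", "GC"))) {
    p <- cds_offset + exon_len
    muts <- bind_mutations(muts, mutation_table(
      gene = gene, tx = tx, species = species, exon = exon,
      class = "SPLICE_DONOR", cds_pos = p,
      rel_pos = pmin(p / cds_len, 1), detail = toupper(donor)))
  }
  if (exon > 0L && usable(acceptor) && toupper(acceptor) != "AG") {
    muts <- bind_mutations(muts, mutation_table(
      gene = gene, tx = tx, species = species, exon = exon,
      class = "SPLICE_ACCEPTOR", cds_pos = cds_offset,
      rel_pos = pmin(cds_offset / cds_len, 1), detail = toupper(acceptor)))
  }
  muts
}

#' Is a frame-preserving indel long enough to inactivate?
#'
#' Frame-preserving indels longer than 50 bp count as inactivating
#' (big indels are rare in conserved genes); frameshifting indels are
#' classified by [scan_exon()] regardless of length.
#'
#' @param length indel length in bp (> 0).
#' @param frame_preserving logical.
#' @param big_indel_min threshold (default 51, i.e. strictly longer than 50).
#' @return `"BIG_INDEL"` or `NA_character_`.
#' @export
detect_big_indel <- function(length, frame_preserving, big_indel_min = 51L) {
  stopifnot(length > 0)
  if (frame_preserving && length >= big_indel_min) "BIG_INDEL" else NA_character_
}

#' Classify presence of one exon in the query
#'
#' An exon without aligned query sequence is a deletion when the query
#' region between the nearest up/downstream aligning anchors is shorter than
#' the exon (the sequence is absent), otherwise it is unaligned; either
#' becomes `missing_data` when that inter-anchor region overlaps an assembly
#' gap, or when no flanking anchors exist (gene at a contig edge).
#'
#' @param exon_len reference exon length (bp).
#' @param aligned logical: does the exon have aligned query sequence?
#' @param anchor_lo,anchor_hi query coordinates of the nearest aligning
#'   blocks up/downstream (`NA` when absent).
#' @param gaps matrix/data.frame of assembly-gap intervals
#'   (columns start, end; 0-based half-open) on the query contig, or `NULL`.
#' @return `"aligned"`, `"EXON_DELETED"`, `"EXON_UNALIGNED"` or
#'   `"missing_data"`.
#' @export
classify_exon_presence <- function(exon_len, aligned, anchor_lo, anchor_hi,
                                   gaps = NULL) {
  if (isTRUE(aligned)) return("aligned")
  if (is.na(anchor_lo) || is.na(anchor_hi)) return("missing_data")
  if (overlaps_gap(anchor_lo, anchor_hi, gaps)) return("missing_data")
  inter <- max(anchor_hi - anchor_lo, 0)
  if (inter < exon_len) "EXON_DELETED" else "EXON_UNALIGNED"
}

overlaps_gap <- function(lo, hi, gaps) {
  if (is.null(gaps) || NROW(gaps) == 0) return(FALSE)
  g <- as.matrix(gaps[, 1:2, drop = FALSE])
  any(g[, 1] < hi & g[, 2] > lo)
}

#' Scan a whole gene alignment for inactivating mutations
#'
#' Runs exon-presence classification, splice-site checks, the per-exon scan
#' and frameshift-compensation marking over every coding exon of one gene x
#' species alignment.
#'
#' @param galn a [gene_alignment()].
#' @param gaps assembly-gap intervals of the query contig (see
#'   [classify_exon_presence()]), or `NULL`.
#' @param big_indel_min see [scan_exon()].
#' @return list with `muts` (mutation table) and `exon_status` (character
#'   vector per exon).
#' @export
scan_gene <- function(galn, gaps = NULL, big_indel_min = 51L) {
  n_exons <- length(galn$exons)
  offsets <- exon_cds_offsets(galn)
  cds_len <- galn$cds_len
  status <- character(n_exons)
  muts <- mutation_table()
  aligned_idx <- which(vapply(galn$exons, function(e) isTRUE(e$present),
                              logical(1)))
  for (i in seq_len(n_exons)) {
    e <- galn$exons[[i]]
    if (!isTRUE(e$present)) {
      before <- aligned_idx[aligned_idx < i]
      after <- aligned_idx[aligned_idx > i]
      lo <- if (length(before) > 0)
        galn$exons[[max(before)]]$qry_end else unname(galn$anchors["up"])
      hi <- if (length(after) > 0)
        galn$exons[[min(after)]]$qry_start else unname(galn$anchors["dn"])
      status[i] <- classify_exon_presence(e$ref_len, FALSE, lo, hi, gaps)
      if (status[i] %in% c("EXON_DELETED", "EXON_UNALIGNED")) {
        muts <- bind_mutations(muts, mutation_table(
          gene = galn$gene_id, tx = galn$tx_id, species = galn$species,
          exon = i - 1L, class = status[i], cds_pos = offsets[i],
          rel_pos = pmin(offsets[i] / cds_len, 1), length = e$ref_len,
          qry_pos = if (is.na(lo)) NA_real_ else lo))
      }
      next
    }
    splice_na <- function(x) !is.na(x) && grepl("N", toupper(x))
    if ((i < n_exons && splice_na(e$donor)) ||
        (i > 1 && splice_na(e$acceptor))) {
      status[i] <- "missing_data"   # splice flank inside an assembly gap
      next
    }
    status[i] <- "aligned"
    ex_muts <- scan_exon(e$ref, e$qry, phase = offsets[i] %% 3,
                         cds_offset = offsets[i], cds_len = cds_len,
                         exon = i - 1L, qry_start = e$qry_start,
                         big_indel_min = big_indel_min,
                         gene = galn$gene_id, tx = galn$tx_id,
                         species = galn$species)
    ex_muts <- apply_compensation(ex_muts, cds_len = cds_len)
    sp <- check_splice_sites(e$donor, e$acceptor, exon = i - 1L,
                             n_exons = n_exons, cds_offset = offsets[i],
                             exon_len = e$ref_len, cds_len = cds_len,
                             gene = galn$gene_id, tx = galn$tx_id,
                             species = galn$species)
    muts <- bind_mutations(muts, ex_muts, sp)
  }
  list(muts = muts, exon_status = status)
}
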