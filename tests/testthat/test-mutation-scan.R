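# Detection of the inactivating-mutation classes in aligned exons.

test_that("frameshifting indels, stop substitutions and inserted stops are classed", {
  # 1-bp deletion mid-exon
  m <- scan_exon("ATGGCCAAACCC", "ATGGCC-AACCC", phase = 0)
  expect_equal(m$class, "FS_DEL")
  expect_equal(m$length, 1)
  # in-frame stop by substitution (CAA -> TAA)
  m <- scan_exon("ATGCAAAAACCC", "ATGTAAAAACCC", phase = 0)
  expect_equal(m$class, "STOP_SUBST")
  expect_equal(m$detail, "TAA")
  # frame-preserving 6-bp insertion containing TAA in the insertion frame
  m <- scan_exon("ATGGCC------AAACCC", "ATGGCCTAAGGGAAACCC", phase = 0)
  expect_equal(m$class, "STOP_IN_INS")
  # identical rows: nothing
  expect_equal(nrow(scan_exon("ATGGCCAAACCC", "ATGGCCAAACCC", phase = 0)), 0)
})

test_that("phase shifts the codon grid used for stop detection", {
  # TAA spans offsets 1-3; in phase 2 (one base completes upstream codon)
  # the codon grid starts at offset 1 and sees it
  expect_equal(nrow(scan_exon("ACAAGCC", "ATAAGCC", phase = 0)), 0)
  m <- scan_exon("ACAAGCC", "ATAAGCC", phase = 2)
  expect_equal(m$class, "STOP_SUBST")
})

test_that("big frame-preserving indels: strictly longer than 50 bp", {
  expect_equal(detect_big_indel(51, TRUE), "BIG_INDEL")
  expect_equal(detect_big_indel(50, TRUE), NA_character_)
  expect_equal(detect_big_indel(48, TRUE), NA_character_)
  expect_equal(detect_big_indel(200, FALSE), NA_character_)
  ref <- paste0("ATGGCC", strrep("-", 51), "AAACCCGGG")
  qry <- paste0("ATGGCC", strrep("GCA", 17), "AAACCCGGG")
  m <- scan_exon(ref, qry, phase = 0)
  expect_equal(m$class, "BIG_INDEL")
  expect_equal(m$length, 51)
  # 48-bp frame-preserving insertion is not inactivating
  ref <- paste0("ATGGCC", strrep("-", 48), "AAACCCGGG")
  qry <- paste0("ATGGCC", strrep("GCA", 16), "AAACCCGGG")
  expect_equal(nrow(scan_exon(ref, qry, phase = 0)), 0)
})

test_that("compensated frameshift pairs are filtered; stops in the shifted stretch block and are promoted", {
  # +1 then -1, clean shifted stretch -> both compensated
  m <- apply_compensation(
    scan_exon("ATGGCC-AAACCCGGGAAACCC", "ATGGCCAAAAC-CGGGAAACCC", phase = 0))
  expect_setequal(m$filtered_reason, "compensated")
  # +1 then -1 with TAA arising in the shifted stretch -> retained + stop
  m <- apply_compensation(
    scan_exon("ATGGC-TAATCGGGAAACCC", "ATGGCATAATCGGG-AACCC", phase = 0))
  expect_setequal(m$class[m$filtered_reason == ""],
                  c("FS_INS", "FS_DEL", "STOP_SUBST"))
  # single frameshift: retained
  m <- apply_compensation(scan_exon("ATGGCCAAACCC", "ATGGCC-AACCC", phase = 0))
  expect_equal(m$filtered_reason, "")
})

test_that("splice-site consensus: donor GT/GC, acceptor AG; boundary exons skipped", {
  expect_equal(nrow(check_splice_sites("GT", "AG", 1, 3)), 0)
  expect_equal(nrow(check_splice_sites("GC", "AG", 1, 3)), 0)
  m <- check_splice_sites("AT", "AG", 1, 3)
  expect_equal(m$class, "SPLICE_DONOR")
  m <- check_splice_sites("GT", "AC", 1, 3)
  expect_equal(m$class, "SPLICE_ACCEPTOR")
  # first exon: no acceptor check; last: no donor check
  expect_equal(nrow(check_splice_sites("GT", "CC", 0, 3)), 0)
  expect_equal(nrow(check_splice_sites("AA", "AG", 2, 3)), 0)
  # single-exon transcripts skipped entirely
  expect_equal(nrow(check_splice_sites("AA", "CC", 0, 1)), 0)
  # N in the flank (assembly gap): no event
  expect_equal(nrow(check_splice_sites("NN", "AG", 1, 3)), 0)
})

test_that("exon presence: deletion vs unaligned vs missing data", {
  # unaligned exon with clean inter-anchor region of length 0 -> deleted
  expect_equal(classify_exon_presence(100, FALSE, 500, 500, NULL),
               "EXON_DELETED")
  # room for the exon between anchors -> unaligned, not deleted
  expect_equal(classify_exon_presence(100, FALSE, 500, 900, NULL),
               "EXON_UNALIGNED")
  # inter-anchor region overlapping an N run -> missing data
  gaps <- cbind(start = 600, end = 700)
  expect_equal(classify_exon_presence(100, FALSE, 500, 900, gaps),
               "missing_data")
  # no anchors (contig edge) -> missing data
  expect_equal(classify_exon_presence(100, FALSE, NA, 900, NULL),
               "missing_data")
  expect_equal(classify_exon_presence(100, TRUE, 500, 900, NULL), "aligned")
})

test_that("reading-frame oracle: surviving FS/STOP events iff translation is broken", {
  set.seed(4711)
  n_checked <- 0
  for (rep in 1:300) {
    n_cod <- sample(20:60, 1)
    ref <- fix_cds(n_cod)
    edits <- list()
    n_ed <- sample(0:3, 1)
    at_used <- integer(0)
    for (j in seq_len(n_ed)) {
      at <- sample(3:(3 * n_cod - 9), 1)
      if (any(abs(at - at_used) < 6)) next
      at_used <- c(at_used, at)
      op <- sample(c("sub", "ins", "del"), 1)
      edits[[length(edits) + 1]] <- switch(op,
        sub = list(op = "sub", at = at, seq = sample(c("A", "C", "G", "T"), 1)),
        ins = list(op = "ins", at = at,
                   seq = paste(sample(c("A", "C", "G", "T"),
                                      sample(1:4, 1), replace = TRUE),
                               collapse = "")),
        del = list(op = "del", at = at, len = sample(1:4, 1)))
    }
    aln <- fix_align(ref, edits)
    m <- apply_compensation(scan_exon(aln$ref, aln$qry, phase = 0))
    surv <- m[m$filtered_reason == "" &
                m$class %in% c("FS_INS", "FS_DEL", "STOP_SUBST",
                               "STOP_IN_INS"), ]
    expect_equal(nrow(surv) > 0, oracle_broken(aln$ref, aln$qry, 0),
                 info = paste("rep", rep))
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 250)
})

test_that("a query identical to the reference yields no mutations in whole genes", {
  cfg <- sim_config(n_genes = 8, seed = 5, err_sub = 0, err_indel = 0,
                    gap_rate = 0, indel_rate = 0, splice_shift_prob = 0,
                    intron_del_prob = 0, misplace_prob = 0,
                    pseudogene_prob = 0,
                    tree = "((qA:0.0,qB:0.0):0.0,ref:0.0);")
  sim <- simulate_geneloss(cfg)
  for (g in sim$genes) for (sp in sim$species) {
    res <- scan_gene(sim$alignments[[g$id]][[sp]][[1]])
    expect_equal(nrow(res$muts), 0)
    expect_true(all(res$exon_status == "aligned"))
  }
})

test_that("relative CDS positions are reproducible from exon offsets", {
  cfg <- sim_config(n_genes = 10, n_loss_genes = 5, seed = 6)
  sim <- simulate_geneloss(cfg)
  for (gid in sim$loss_table$gene) {
    gi <- match(gid, vapply(sim$genes, `[[`, character(1), "id"))
    g <- sim$genes[[gi]]
    sp <- strsplit(sim$loss_table$species[match(gid, sim$loss_table$gene)],
                   ",")[[1]][1]
    res <- scan_gene(sim$alignments[[gid]][[sp]][[1]])
    m <- res$muts
    for (i in seq_len(nrow(m))) {
      offset_in_exon <- m$cds_pos[i] - g$offs[m$exon[i] + 1]
      expect_gte(offset_in_exon, 0)
      expect_lte(offset_in_exon, g$exon_lens[m$exon[i] + 1])
      expect_equal(m$rel_pos[i], m$cds_pos[i] / g$cds_len)
    }
  }
})
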