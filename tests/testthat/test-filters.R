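# The artifact-removal cascade: assembly gaps, synteny, rescue realignment,
# terminal trim, isoform selection.

test_that("point mutations within 1 bp of an N run are removed; distant ones kept", {
  muts <- mutation_table(gene = "g", species = "s", exon = 0L,
                         class = c("STOP_SUBST", "FS_DEL"),
                         cds_pos = c(10, 20), rel_pos = c(0.1, 0.2),
                         length = c(NA, 1), qry_pos = c(1000, 2000))
  gaps <- cbind(start = 2001, end = 2100)   # FS_DEL at 2000 is adjacent
  out <- gap_filter(muts, gaps)
  expect_equal(out$filtered_reason, c("", "near_gap"))
  far <- gap_filter(muts, cbind(start = 5000, end = 5100))
  expect_equal(far$filtered_reason, c("", ""))
})

test_that("synteny: between-neighbours passes, wrong contig fails, inversion passes", {
  g <- list(contig = "c1", pos = 4000)
  a <- list(contig = "c1", pos = 1000); b <- list(contig = "c1", pos = 9000)
  expect_equal(synteny_filter(g, a, b), "pass")
  expect_equal(synteny_filter(list(contig = "c9", pos = 4000), a, b), "fail")
  # jointly inverted neighbourhood (strand flip)
  expect_equal(synteny_filter(g, b, a), "pass")
  # gene outside the neighbour interval
  expect_equal(synteny_filter(list(contig = "c1", pos = 9500), a, b), "fail")
  expect_warning(r <- synteny_filter(g, list(contig = NA, pos = NA), b),
                 "not assessable")
  expect_equal(r, "pass")
})

test_that("processed-pseudogene placement in the simulator fails synteny", {
  cfg <- sim_config(n_genes = 40, seed = 33, pseudogene_prob = 0.5)
  sim <- simulate_geneloss(cfg)
  pg <- sim$truth[sim$truth$class == "processed_pseudogene", ]
  idx <- vapply(seq_len(nrow(pg)), function(k)
    match(pg$gene[k], sim$loci[[pg$species[k]]]$gene), integer(1))
  interior <- which(idx > 1 & idx < 40)
  expect_gt(length(interior), 0)
  k <- interior[1]; i <- idx[k]
  loci <- sim$loci[[pg$species[k]]]
  res <- synteny_filter(
    list(contig = loci$contig[i], pos = loci$pos[i]),
    list(contig = loci$contig[i - 1], pos = loci$pos[i - 1]),
    list(contig = loci$contig[i + 1], pos = loci$pos[i + 1]))
  expect_equal(res, "fail")
})

test_that("splice-shift rescue: a frame-preserving consensus nearby removes the splice event", {
  # exon [1000,1090) on contig; annotated donor AA, true donor GT at +3
  set.seed(11)
  exon_seq <- paste0(fix_cds(24), strrep("AAA", 6))  # GT/GC-free exon tail
  contig <- paste0(fix_cds(333), substr(exon_seq, 1, 90),
                   "AACGT", fix_cds(100))
  galn <- fix_galn(substr(exon_seq, 1, 90), substr(exon_seq, 1, 90),
                   donor = "AA", n_exons = 2)
  galn$exons[[1]]$qry_start <- 999; galn$exons[[1]]$qry_end <- 1089
  galn$exons[[2]] <- list(present = TRUE, ref = "AAA", qry = "AAA",
                          ref_len = 3, qry_start = 1200, qry_end = 1203,
                          donor = NA, acceptor = "AG")
  galn$cds_len <- 93
  muts <- check_splice_sites("AA", NA, 0, 2, cds_offset = 0, exon_len = 90,
                             cds_len = 93, gene = "g", species = "sp")
  out <- rescue_realign(galn, muts, qry_seq = contig)
  expect_equal(out$filtered_reason, "splice_shift")
  # without any consensus nearby the event stays
  contig2 <- paste0(fix_cds(333), substr(exon_seq, 1, 90),
                    strrep("A", 40), fix_cds(100))  # no consensus in window
  out2 <- rescue_realign(galn, muts, qry_seq = contig2)
  expect_equal(out2$filtered_reason, "")
})

test_that("precise intron deletion removes both splice events of that intron", {
  ex1 <- list(present = TRUE, ref = "ATGGCCAAA", qry = "ATGGCCAAA",
              ref_len = 9, qry_start = 1000, qry_end = 1009,
              donor = "CC", acceptor = NA)
  ex2 <- list(present = TRUE, ref = "GGGTTTAAACCA", qry = "GGGTTTAAACCA",
              ref_len = 12, qry_start = 1009, qry_end = 1021,
              donor = NA, acceptor = "CA")
  galn <- gene_alignment("g", "g.t1", "sp", "c1", list(ex1, ex2),
                         anchors = c(up = 900, dn = 1200))
  muts <- bind_mutations(
    check_splice_sites("CC", NA, 0, 2, 0, 9, 21, gene = "g"),
    check_splice_sites(NA, "CA", 1, 2, 9, 12, 21, gene = "g"))
  expect_equal(nrow(muts), 2)
  out <- rescue_realign(galn, muts, qry_seq = NULL)
  expect_setequal(out$filtered_reason, "intron_deletion")
})

test_that("realignment removes misplacement artifacts but keeps real frameshifts", {
  set.seed(12)
  ref0 <- fix_cds(40)
  # real 1-bp deletion: survives realignment
  aln <- fix_align(ref0, list(list(op = "del", at = 60, len = 1)))
  galn <- fix_galn(aln$ref, aln$qry)
  m <- apply_compensation(scan_exon(aln$ref, aln$qry, phase = 0))
  out <- rescue_realign(galn, m, qry_seq = NULL)
  expect_true(any(out$class == "FS_DEL" & out$filtered_reason == ""))
  # misplaced in-frame deletion faking a stop: removed by realignment
  cfg <- sim_config(n_genes = 60, seed = 41, misplace_prob = 1,
                    indel_rate = 0.02, err_sub = 0, err_indel = 0,
                    gap_rate = 0, splice_shift_prob = 0, intron_del_prob = 0,
                    pseudogene_prob = 0)
  sim <- simulate_geneloss(cfg)
  run <- run_pipeline(sim)
  spurious <- run$muts[run$muts$class %in% c("STOP_SUBST", "STOP_IN_INS"), ]
  expect_true(nrow(spurious) == 0 ||
                all(spurious$filtered_reason != ""))
})

test_that("terminal 20% trim uses strict inequalities", {
  muts <- mutation_table(gene = "g", species = "s", exon = 0L,
                         class = "STOP_SUBST", cds_pos = c(10, 20, 50, 80, 90),
                         rel_pos = c(0.10, 0.20, 0.50, 0.80, 0.90))
  out <- terminal_trim(muts)
  expect_equal(out$filtered_reason,
               c("terminal", "", "", "", "terminal"))
})

test_that("isoform selection: fewest mutations, then longer CDS, then transcript id", {
  iso <- data.frame(tx = c("t1", "t2"), n_mutations = c(3L, 1L),
                    cds_len = c(900, 600), missing = FALSE)
  expect_equal(select_isoform(iso), "t2")
  iso$n_mutations <- c(2L, 2L)
  expect_equal(select_isoform(iso), "t1")     # longer CDS wins the tie
  iso$cds_len <- c(600, 600)
  expect_equal(select_isoform(iso), "t1")     # lexicographic id
  iso$missing <- c(TRUE, TRUE)
  expect_true(is.na(select_isoform(iso)))
  expect_equal(select_isoform(data.frame(tx = "only", n_mutations = 5L,
                                         cds_len = 100, missing = FALSE)),
               "only")
})

test_that("cascade counts are monotone and artifact-caused mutations are removed", {
  cfg <- sim_config(n_genes = 150, seed = 77, splice_shift_prob = 0.15,
                    intron_del_prob = 0.1, misplace_prob = 0.5,
                    gap_rate = 3e-5)
  sim <- simulate_geneloss(cfg)
  run <- run_pipeline(sim)
  # per gene x species monotone decrease over the cascade
  tr <- run$trace
  expect_true(all(tr$n_after <= tr$n_before))
  key <- paste(tr$gene, tr$species)
  for (k in unique(key)[1:50]) {
    sub <- tr[key == k, ]
    expect_true(all(diff(c(sub$n_before[1], sub$n_after)) <= 0))
  }
  # every splice event caused by a recorded splice-shift or intron-deletion
  # artifact is filtered out
  art <- sim$truth[sim$truth$class %in% c("splice_shift", "intron_deletion"), ]
  m <- run$muts[grepl("\\.t1$", run$muts$tx), ]   # principal isoform: exon
  for (i in seq_len(nrow(art))) {                 # indices match the truth
    rows <- m[m$gene == art$gene[i] & m$species == art$species[i] &
                m$class %in% c("SPLICE_DONOR", "SPLICE_ACCEPTOR") &
                m$exon %in% c(art$exon[i], art$exon[i] + 1L), ]
    expect_true(all(rows$filtered_reason != ""),
                info = paste(art$gene[i], art$species[i], art$class[i]))
  }
  # no conserved gene ends up a loss candidate in this artifact-heavy run
  expect_lte(mean(apply(run$classification == "loss_candidate", 1, any,
                        na.rm = TRUE)), 0.005)
})

test_that("rescue never invents mutation records", {
  cfg <- sim_config(n_genes = 60, n_loss_genes = 6, seed = 13)
  sim <- simulate_geneloss(cfg)
  for (gid in vapply(sim$genes, `[[`, character(1), "id")[41:66]) {
    for (sp in sim$species[1:2]) {
      galn <- sim$alignments[[gid]][[sp]][[1]]
      m0 <- scan_gene(galn)$muts
      m1 <- rescue_realign(galn, m0,
                           qry_seq = sim$assemblies[[sp]]$sequences[[galn$qry_contig]])
      expect_equal(nrow(m1), nrow(m0))
      expect_true(all(m1$class == m0$class & m1$cds_pos == m0$cds_pos))
    }
  }
})
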