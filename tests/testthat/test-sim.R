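# The synthetic-evolution generator: determinism, truth propagation,
# estimator consistency, corruption and read sampling.

test_that("a fixed seed reproduces byte-identical study directories", {
  cfg <- sim_config(n_genes = 6, n_loss_genes = 2, seed = 55, gap_rate = 5e-5)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  sim_write(simulate_geneloss(cfg), d1, reads = TRUE)
  sim_write(simulate_geneloss(cfg), d2, reads = TRUE)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_setequal(f1, f2)
  h1 <- tools::md5sum(file.path(d1, sort(f1)))
  h2 <- tools::md5sum(file.path(d2, sort(f2)))
  expect_equal(unname(h1), unname(h2))
  # a different seed changes the output
  d3 <- withr::local_tempdir()
  cfg3 <- cfg; cfg3$seed <- 56
  sim_write(simulate_geneloss(cfg3), d3)
  expect_false(all(unname(tools::md5sum(file.path(d3, "genomes", "ref.fa")))
                   == unname(tools::md5sum(file.path(d1, "genomes", "ref.fa")))))
})

test_that("null config without losses or artifacts leaves every gene intact", {
  cfg <- sim_config(n_genes = 15, seed = 42, err_sub = 0, err_indel = 0,
                    gap_rate = 0, splice_shift_prob = 0, intron_del_prob = 0,
                    misplace_prob = 0, pseudogene_prob = 0)
  run <- run_pipeline(simulate_geneloss(cfg))
  expect_true(all(run$classification == "intact"))
  expect_true(all(run$matrix == 100, na.rm = TRUE))
})

test_that("a loss injected on an internal branch marks both descendants with one shared mutation", {
  cfg <- sim_config(n_genes = 3, n_loss_genes = 3, seed = 77,
                    loss_branches = "qC+qD")
  sim <- simulate_geneloss(cfg)
  expect_true(all(sim$loss_table$species == "qC,qD"))
  for (g in sim$loss_table$gene) {
    mC <- scan_gene(sim$alignments[[g]][["qC"]][[1]])$muts
    mD <- scan_gene(sim$alignments[[g]][["qD"]][[1]])$muts
    key <- function(m) paste(m$class, m$exon, m$cds_pos, m$length)
    expect_gte(length(intersect(key(mC), key(mD))), 1)
  }
})

test_that("selected-regime evolution reproduces the configured Ka/Ks", {
  # ~10 kb of simulated coding sequence, two independent branches at
  # divergence 0.2, pooled NG86 estimate should come back near omega 0.2
  set.seed(61)
  cfg <- sim_config(seed = 61, omega_sel = 0.2)
  pairs <- lapply(1:4, function(i) {
    g <- list(id = "g", n_exons = 1L, exon_lens = 2700L, offs = c(0L, 2700L),
              cds_len = 2700L, n_codons = 900L, codon_exon = rep(1L, 900),
              anc_cds = fix_cds(900), introns = list(), alt_drop = NA_integer_)
    st0 <- genelossr:::init_state(g)
    a <- genelossr:::evolve_branch(st0, 0.1, cfg, g, indels_ok = FALSE)
    b <- genelossr:::evolve_branch(st0, 0.1, cfg, g, indels_ok = FALSE)
    list(paste(a$cod, collapse = ""), paste(b$cod, collapse = ""))
  })
  k <- kaks_pool(pairs)
  expect_gte(k$ratio, 0.15)
  expect_lte(k$ratio, 0.25)
})

test_that("corrupt is the identity at zero rates and adds N gaps otherwise", {
  set.seed(62)
  asm <- genome_assembly("q", c(c1 = random_dna(20000)))
  cfg0 <- sim_config(seed = 1, err_sub = 0, gap_rate = 0)
  expect_identical(corrupt(asm, cfg0), asm)
  cfg1 <- sim_config(seed = 1, err_sub = 1e-3, gap_rate = 2e-4)
  out <- corrupt(asm, cfg1)
  expect_gt(nrow(out$gaps$c1), 0)
  expect_false(identical(out$sequences, asm$sequences))
  expect_equal(nchar(out$sequences[["c1"]]), 20000)
})

test_that("gap corruption produces missing-data exon calls downstream", {
  cfg <- sim_config(n_genes = 60, seed = 63, gap_rate = 3e-4,
                    err_sub = 0, err_indel = 0, splice_shift_prob = 0,
                    intron_del_prob = 0, misplace_prob = 0,
                    pseudogene_prob = 0)
  sim <- simulate_geneloss(cfg)
  run <- run_pipeline(sim)
  expect_gt(run$manifest$n_missing, 0)
  expect_lte(mean(run$classification == "loss_candidate", na.rm = TRUE),
             0.005)
})

test_that("read sampling hits the requested depth and error profile", {
  set.seed(64)
  asm <- genome_assembly("q", c(c1 = random_dna(60000)))
  cfg <- sim_config(seed = 2, coverage = 20, read_len = 150, read_err = 0)
  reads <- sample_reads(asm, cfg)
  depth <- sum(nchar(reads)) / 60000
  expect_lt(abs(depth - 20) / 20, 0.1)       # Lander-Waterman expectation
  expect_true(all(nchar(reads) == 150))
  # with errors, reads differ from the template at roughly the given rate
  cfgE <- sim_config(seed = 2, coverage = 5, read_len = 500, read_err = 0.02)
  readsE <- sample_reads(asm, cfgE, seed = 9)
  # align a few forward reads back by their recorded start positions
  starts <- as.integer(sub(".*_", "", names(readsE)))
  mm <- vapply(seq_len(100), function(i) {
    tpl <- substr(asm$sequences[["c1"]], starts[i] + 1, starts[i] + 500)
    mean(strsplit(tpl, "")[[1]] != strsplit(readsE[[i]], "")[[1]])
  }, numeric(1))
  mm <- mm[mm < 0.25]                        # forward-orientation reads
  expect_gt(length(mm), 20)
  expect_lt(abs(mean(mm) - 0.02), 0.01)
})
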