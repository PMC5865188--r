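# %intact, loss classification, ancestral presence, shared mutations.

test_that("%intact is the largest mutation-free stretch", {
  expect_equal(percent_intact(c(0.20, 0.55)), 45)
  expect_equal(percent_intact(numeric(0)), 100)
  expect_equal(percent_intact(c(0.10, 0.30, 0.90)), 60)
  expect_error(percent_intact(c(0.5, 1.2)), "0, 1")
})

test_that("%intact matches segment enumeration and is monotone under insertion", {
  set.seed(101)
  for (rep in 1:100) {
    pos <- runif(sample(0:8, 1))
    expect_equal(percent_intact(pos), oracle_percent_intact(pos))
    extra <- runif(1)
    expect_lte(percent_intact(c(pos, extra)), percent_intact(pos))
  }
  # 100 iff no surviving mutations
  expect_identical(percent_intact(numeric(0)), 100)
  expect_lt(percent_intact(0.5), 100)
})

test_that("loss classification thresholds behave exactly as printed", {
  # %intact<60 and >=20% exons mutated
  expect_equal(classify_gene(55, 10, 2, 2), "loss_candidate")
  expect_equal(classify_gene(55, 10, 1, 1), "intact")     # 10% of exons
  expect_equal(classify_gene(60, 10, 2, 2), "intact")     # %intact not <60
  expect_equal(classify_gene(59.99, 10, 2, 2), "loss_candidate")
  expect_equal(classify_gene(65, 10, 5, 9), "intact")
  # single-exon rule: at least two mutations, %intact not consulted
  expect_equal(classify_gene(90, 1, 1, 2), "loss_candidate")
  expect_equal(classify_gene(30, 1, 1, 1), "intact")
  expect_equal(classify_gene(NA, 5, NA, NA, missing = TRUE), "missing_data")
})

test_that("ancestral presence: MRCA of reference and intact species", {
  tree <- ape::read.tree(text = "(((qA:1,qB:1):1,(qC:1,qD:1):1):1,(qE:2,ref:2):1);")
  # intact everywhere -> root; all candidates eligible
  r <- infer_ancestral_presence(tree, c("qA", "qB", "qC", "qD", "qE"), "ref",
                                loss_species = "qB")
  expect_setequal(r$eligible, tree$tip.label)
  expect_length(r$dropped, 0)
  # intact only in one subclade: candidate outside is dropped
  r <- infer_ancestral_presence(tree, c("qE"), "ref", loss_species = "qA")
  expect_setequal(r$eligible, c("qE", "ref"))
  expect_equal(r$dropped, "qA")
  # intact in reference only -> no query loss countable
  r <- infer_ancestral_presence(tree, character(0), "ref",
                                loss_species = c("qA", "qC"))
  expect_equal(r$eligible, "ref")
  expect_setequal(r$dropped, c("qA", "qC"))
  expect_error(infer_ancestral_presence(tree, "nosuch", "ref"), "nosuch")
})

test_that("shared mutations group identical events across species", {
  muts <- mutation_table(
    gene = "g", species = c("qA", "qB", "qA", "qB", "qC"),
    exon = c(1L, 1L, 2L, 3L, 1L),
    class = c("FS_DEL", "FS_DEL", "STOP_SUBST", "STOP_SUBST", "FS_DEL"),
    cds_pos = c(100, 100, 200, 250, 100), rel_pos = 0.5,
    length = c(1, 1, NA, NA, 1))
  sh <- shared_mutation_support(muts)
  expect_equal(nrow(sh), 1)
  expect_equal(sh$n_species, 3)
  expect_equal(sh$species, "qA,qB,qC")
  # disjoint sets: nothing shared
  expect_equal(nrow(shared_mutation_support(
    mutation_table(gene = "g", species = c("qA", "qB"), exon = 1L,
                   class = "FS_DEL", cds_pos = c(1, 2), rel_pos = 0.1,
                   length = 1))), 0)
})

test_that("losses injected on an internal branch are shared by the sister species", {
  cfg <- sim_config(n_genes = 5, n_loss_genes = 4, seed = 19,
                    loss_branches = "qA+qB")
  sim <- simulate_geneloss(cfg)
  run <- run_pipeline(sim)
  for (g in sim$loss_table$gene) {
    surv <- run$muts[run$muts$gene == g & run$muts$filtered_reason == "" &
                       grepl("\\.t1$", run$muts$tx), ]
    sh <- shared_mutation_support(surv)
    expect_gte(nrow(sh), 1)
    expect_true(any(grepl("qA", sh$species) & grepl("qB", sh$species)))
  }
})

test_that("call_losses assembles matrix and classification consistently", {
  st <- data.frame(gene = rep(c("g1", "g2"), each = 2),
                   species = rep(c("qA", "qB"), 2),
                   percent_intact = c(100, 45, 80, NA),
                   classification = c("intact", "loss_candidate", "intact",
                                      "missing_data"))
  out <- call_losses(st)
  expect_equal(dim(out$matrix), c(2, 2))
  expect_equal(out$matrix["g1", "qB"], 45)
  expect_true(is.na(out$matrix["g2", "qB"]))
  expect_equal(out$classification["g2", "qB"], "missing_data")
})
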