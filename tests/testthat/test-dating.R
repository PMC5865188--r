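# Ka/Ks estimation and neutral-time dating.

test_that("kaks basics: identical, synonymous-only, saturation flags", {
  s <- strrep("TTTGCTAACGGA", 10)
  expect_warning(k <- kaks(substr(s, 1, 27), substr(s, 1, 27)), "30")
  suppressWarnings({
    k <- kaks(s, s)
    expect_equal(k$ka, 0)
    expect_equal(k$ks, 0)
    expect_equal(k$flag, "ks_zero")
    # single third-position synonymous change: Ka 0, Ks > 0
    s2 <- s; substr(s2, 3, 3) <- "C"   # TTT -> TTC (both Phe)
    k <- kaks(s, s2)
    expect_equal(k$ka, 0)
    expect_gt(k$ks, 0)
  })
})

test_that("kaks matches the brute-force pathway-enumeration oracle", {
  set.seed(77)
  worst <- 0
  for (rep in 1:250) {
    n_cod <- sample(1:20, 1)
    s1 <- fix_cds(n_cod)
    s2c <- strsplit(s1, "")[[1]]
    nmut <- rbinom(1, 3 * n_cod, 0.12)
    if (nmut > 0) {
      at <- sample(3 * n_cod, min(nmut, 3 * n_cod))
      s2c[at] <- sapply(s2c[at], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1))
    }
    s2 <- paste(s2c, collapse = "")
    got <- suppressWarnings(kaks(s1, s2))
    want <- oracle_ng86(s1, s2)
    expect_equal(got$S, want$S, tolerance = 1e-10)
    expect_equal(got$Sd, want$Sd, tolerance = 1e-10)
    expect_equal(got$Nd, want$Nd, tolerance = 1e-10)
    ok <- function(a, b) (is.na(a) && is.na(b)) ||
      (!is.na(a) && !is.na(b) && abs(a - b) < 1e-10)
    expect_true(ok(got$ka, want$ka))
    expect_true(ok(got$ks, want$ks))
  }
})

test_that("pooled counts equal the sum of per-pair counts", {
  set.seed(5)
  p1 <- list(fix_cds(40), fix_cds(40))
  p2 <- list(fix_cds(40), fix_cds(40))
  pooled <- suppressWarnings(kaks_pool(list(p1, p2)))
  k1 <- suppressWarnings(kaks(p1[[1]], p1[[2]]))
  k2 <- suppressWarnings(kaks(p2[[1]], p2[[2]]))
  expect_equal(pooled$Sd, k1$Sd + k2$Sd)
  expect_equal(pooled$S, k1$S + k2$S)
})

test_that("neutral time: limits, worked value, clamping, error cases", {
  expect_equal(neutral_time(0.2, 0.2, 10), 0)    # K = Ks: loss at branch end
  expect_equal(neutral_time(1, 0.2, 10), 10)     # fully neutral branch
  expect_equal(neutral_time(0.6, 0.2, 10), 5)
  # clamping keeps the estimate physical
  expect_equal(neutral_time(0.1, 0.2, 10), 0)
  expect_equal(neutral_time(1.3, 0.2, 10), 10)
  expect_error(neutral_time(0.5, 1.0, 10), "< 1")
  expect_error(neutral_time(0.5, 0.2, 0), "positive")
})

test_that("neutral time inverts the branch mixture and is monotone", {
  set.seed(31)
  for (rep in 1:50) {
    ks <- runif(1, 0.05, 0.8); t <- runif(1, 1, 50)
    k <- runif(1, ks, 1)
    tn <- neutral_time(k, ks, t)
    # substituting back recovers K exactly
    expect_equal(ks * (t - tn) / t + 1 * tn / t, k, tolerance = 1e-12)
    # monotone in K and in T
    expect_gte(neutral_time(min(k + 0.05, 1), ks, t), tn)
    expect_gte(neutral_time(k, ks, t * 2), tn)
  }
})

test_that("date_loss picks the closest intact proxy and scales with T bounds", {
  set.seed(9)
  cfg <- sim_config(seed = 9)
  g <- list(id = "gX", n_exons = 1L, exon_lens = 900L, offs = c(0L, 900L),
            cds_len = 900L, n_codons = 300L, codon_exon = rep(1L, 300),
            anc_cds = fix_cds(300), introns = list(), alt_drop = NA_integer_)
  st0 <- genelossr:::init_state(g)
  near <- genelossr:::evolve_branch(st0, 0.02, cfg, g, indels_ok = FALSE)
  far <- genelossr:::evolve_branch(st0, 0.3, cfg, g, indels_ok = FALSE)
  lost <- genelossr:::evolve_branch(st0, 0.15, cfg, g, indels_ok = FALSE)
  lost$neutral <- TRUE
  lost <- genelossr:::evolve_branch(lost, 0.15, cfg, g, indels_ok = FALSE)
  d <- date_loss(paste(lost$cod, collapse = ""),
                 c(near = paste(near$cod, collapse = ""),
                   far = paste(far$cod, collapse = "")),
                 20, 30, gene = "gX", branch = "qA")
  expect_equal(d$proxy, "near")
  expect_equal(d$Tn_upper / d$Tn_lower, 30 / 20, tolerance = 1e-12)
  expect_gte(d$Tn_lower, 0)
  expect_lte(d$Tn_upper, 30)
  expect_error(date_loss("ATG", c(a = "ATG"), 1, 2), ">= 2 intact")
})
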