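# Brownian covariance, gene prefilters, pGLS, ranking.

test_that("Brownian covariance: star tree, hand-computed tree, scaling", {
  star <- ape::read.tree(text = "(A:2,B:2,C:2);")
  expect_equal(unname(brownian_covariance(star)), 2 * diag(3))
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  C <- brownian_covariance(tr)
  expect_equal(C["A", "B"], 1)
  expect_equal(C["A", "C"], 0)
  expect_equal(C["A", "A"], 2)
  tr2 <- tr; tr2$edge.length <- tr$edge.length * 3.5
  expect_equal(brownian_covariance(tr2), C * 3.5)
  tr0 <- tr; tr0$edge.length <- rep(0, length(tr$edge.length))
  expect_error(brownian_covariance(tr0), "zero")
})

test_that("prefilters: missing-data and background-intactness rules at their boundaries", {
  g <- setNames(rep(c("trait1", "trait2"), c(4, 10)), paste0("s", 1:14))
  ok <- setNames(c(rep(50, 4), rep(100, 10)), paste0("s", 1:14))
  expect_equal(gene_prefilter(ok, g), "")
  # 8 of 10 background species >=90 (80% < 90%) -> excluded
  y <- ok; y[c("s5", "s6")] <- 85
  expect_equal(gene_prefilter(y, g), "t2_not_intact")
  # >=5% of background <60 -> excluded (1 of 10 = 10%)
  y <- ok; y["s5"] <- 55
  expect_equal(gene_prefilter(y, g), "t2_not_intact")
  # exactly 50% of trait-1 missing is allowed (rule is "more than 50%")
  y <- ok; y[c("s1", "s2")] <- NA
  expect_equal(gene_prefilter(y, g), "")
  y[c("s3")] <- NA   # 75% missing
  expect_equal(gene_prefilter(y, g), "missing_t1")
  # >50% of trait-2 missing
  y <- ok; y[paste0("s", 5:10)] <- NA
  expect_equal(gene_prefilter(y, g), "missing_t2")
})

test_that("pGLS with identity covariance equals closed-form OLS", {
  set.seed(7)
  y <- c(100, 96, 42, 31, 99, 97)
  x <- c(0, 0, 1, 1, 0, 0)
  f <- pgls_fit(y, x, diag(6))
  o <- summary(stats::lm(y ~ x))$coefficients
  expect_equal(f$slope, o[2, 1], tolerance = 1e-10)
  expect_equal(f$se, o[2, 2], tolerance = 1e-10)
  expect_equal(f$t, o[2, 3], tolerance = 1e-10)
  expect_equal(f$p, o[2, 4], tolerance = 1e-10)
  expect_equal(f$df, 4L)
  # identity times any sigma^2 gives the same inference
  f2 <- pgls_fit(y, x, 17 * diag(6))
  expect_equal(f2$p, f$p, tolerance = 1e-12)
})

test_that("pGLS agrees with nlme::gls under Brownian correlation", {
  skip_if_not_installed("nlme")
  set.seed(8)
  tr <- ape::rcoal(15)
  tr$tip.label <- paste0("s", 1:15)
  y <- rnorm(15, 90, 6); x <- rbinom(15, 1, 0.4)
  f <- pgls_fit(y, x, brownian_covariance(tr))
  df <- data.frame(y = y, x = x, sp = tr$tip.label)
  g <- nlme::gls(y ~ x, data = df,
                 correlation = ape::corBrownian(1, tr, form = ~sp))
  tt <- summary(g)$tTable
  expect_equal(f$slope, tt[2, 1], tolerance = 1e-8)
  expect_equal(f$t, tt[2, 3], tolerance = 1e-8)
  expect_equal(f$p, tt[2, 4], tolerance = 1e-8)
})

test_that("noise-free group difference is recovered exactly; p invariant to tree rescaling", {
  tr <- ape::read.tree(
    text = "(((a:1,b:1):1,(c:1,d:1):1):1,((e:1,f:1):1,(g:1,h:1):1):1);")
  x <- setNames(c(1, 1, 0, 0, 0, 0, 0, 0), tr$tip.label)
  y <- 100 - 80 * x
  f <- pgls_fit(y, unname(x), brownian_covariance(tr))
  expect_equal(f$slope, -80, tolerance = 1e-9)
  tr2 <- tr; tr2$edge.length <- tr$edge.length * 100
  set.seed(3)
  y2 <- y + rnorm(8, 0, 3)
  f1 <- pgls_fit(y2, unname(x), brownian_covariance(tr))
  f2 <- pgls_fit(y2, unname(x), brownian_covariance(tr2))
  expect_equal(f1$p, f2$p, tolerance = 1e-10)
})

test_that("constant %intact gives slope 0 and p 1", {
  f <- pgls_fit(rep(100, 6), c(0, 0, 1, 1, 0, 0), diag(6))
  expect_equal(f$slope, 0)
  expect_equal(f$p, 1)
})

test_that("ranking selects p<1e-6 with the loss direction only", {
  res <- data.frame(gene = c("a", "b", "c", "d"),
                    slope = c(-50, 60, -40, NA), se = 1,
                    t = c(-50, 60, -4, NA),
                    p = c(1e-7, 1e-7, 1e-5, NA),
                    n = 10, excluded_reason = c("", "", "", "missing_t1"))
  out <- rank_and_select(res)
  expect_equal(out$gene[1:2], c("a", "b"))    # ascending p among tested
  expect_equal(out$selected[out$gene == "a"], TRUE)
  expect_equal(out$selected[out$gene == "b"], FALSE)  # wrong direction
  expect_equal(out$selected[out$gene == "c"], FALSE)  # p too large
  expect_equal(out$selected[out$gene == "d"], FALSE)  # excluded
})

test_that("screen finds convergent losses on a 40-leaf tree and controls the null", {
  set.seed(12)
  tr <- ape::rcoal(40)
  tr$tip.label <- paste0("s", 1:40)
  grp <- setNames(rep("trait2", 40), tr$tip.label)
  grp[c("s3", "s4", "s17", "s18", "s30", "s31")] <- "trait1"  # 3 lineages
  simm <- simulate_intact_matrix(tr, grp, n_null = 500, n_convergent = 25,
                                 seed = 13)
  res <- rank_and_select(forward_genomics(simm$matrix, tr, grp))
  conv <- simm$truth[match(res$gene, rownames(simm$matrix))] == "convergent"
  tested <- res$excluded_reason == ""
  expect_gte(mean(res$selected[conv & tested]), 0.9)
  expect_gte(mean(!res$selected[!conv & tested]), 0.99)
})
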