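# Convergent-loss screen: regress %intact on a binary trait with error
# covariance from Brownian motion on the species tree (pGLS), gene by gene.

#' Brownian-motion covariance of tip values on a species tree
#'
#' Entry (i, j) is the shared root-to-MRCA path length of tips i and j; the
#' diagonal holds root-to-tip path lengths.  This is the expected covariance
#' of a trait evolving by Brownian motion on the tree.
#'
#' @param tree an [ape::read.tree()] phylo object with branch lengths.
#' @param species optional subset (and ordering) of tip names.
#' @return symmetric positive semidefinite matrix with species dimnames.
#' @export
brownian_covariance <- function(tree, species = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (sum(tree$edge.length) <= 0) stop("tree has zero total branch length")
  C <- ape::vcv.phylo(tree)
  if (!is.null(species)) {
    unknown <- setdiff(species, rownames(C))
    if (length(unknown) > 0)
      stop("species not in tree: ", paste(unknown, collapse = ", "))
    C <- C[species, species, drop = FALSE]
  }
  C
}

#' Per-gene eligibility filter for the convergent-loss screen
#'
#' A gene is excluded when more than `missing_fraction` (default 0.5) of
#' either trait group is missing data, when fewer than `t2_intact_fraction`
#' (default 0.9) of the assessable background (trait-2) species have %intact
#' >= `t2_intact_cut` (default 90), or when at least `t2_broken_fraction`
#' (default 0.05) of them have %intact < `t2_broken_cut` (default 60): the
#' screen targets genes lost in the derived-phenotype group but intact in the
#' background.
#'
#' @param intact named numeric vector of %intact values (NA = missing data).
#' @param groups named vector/factor assigning each species to `"trait1"`
#'   (derived phenotype) or `"trait2"` (background).
#' @param missing_fraction,t2_intact_fraction,t2_intact_cut,t2_broken_fraction,t2_broken_cut
#'   thresholds as above.
#' @return `""` when the gene is testable, otherwise the exclusion reason
#'   (`"missing_t1"`, `"missing_t2"`, `"t2_not_intact"`).
#' @export
gene_prefilter <- function(intact, groups, missing_fraction = 0.5,
                           t2_intact_fraction = 0.9, t2_intact_cut = 90,
                           t2_broken_fraction = 0.05, t2_broken_cut = 60) {
  groups <- as.character(groups)[match(names(intact), names(groups))]
  stopifnot(all(groups %in% c("trait1", "trait2")))
  t1 <- intact[groups == "trait1"]; t2 <- intact[groups == "trait2"]
  if (length(t1) == 0 || length(t2) == 0) stop("both trait groups required")
  if (mean(is.na(t1)) > missing_fraction) return("missing_t1")
  if (mean(is.na(t2)) > missing_fraction) return("missing_t2")
  t2 <- t2[!is.na(t2)]
  if (mean(t2 >= t2_intact_cut) < t2_intact_fraction) return("t2_not_intact")
  if (mean(t2 < t2_broken_cut) >= t2_broken_fraction) return("t2_not_intact")
  ""
}

#' Phylogenetic generalized least squares fit of %intact on a binary trait
#'
#' Fits `y = a + b x` by generalized least squares with error covariance
#' proportional to `C`; with `C` the identity this reduces exactly to
#' ordinary least squares.  The two-sided p value for `b = 0` comes from the
#' t distribution with n - 2 degrees of freedom; p values are invariant under
#' rescaling of `C` (hence of the tree's branch lengths).
#'
#' @param y numeric response (%intact per species).
#' @param x numeric covariate (1 = derived-phenotype group, 0 = background).
#' @param C covariance matrix aligned with `y`/`x` (see
#'   [brownian_covariance()]).
#' @return list: `slope`, `intercept`, `se`, `t`, `p`, `n`, `df`.
#' @export
pgls_fit <- function(y, x, C) {
  n <- length(y)
  stopifnot(length(x) == n, all(dim(C) == n), n >= 3)
  if (stats::var(y) == 0 || stats::var(x) == 0)
    return(list(slope = 0, intercept = mean(y), se = NA_real_, t = 0,
                p = 1, n = n, df = n - 2L))
  L <- tryCatch(chol(C), error = function(e) stop("singular covariance"))
  X <- cbind(intercept = 1, slope = x)
  # whiten: solve L' z = v  =>  z = (L')^{-1} v, so z'z = v' C^{-1} v
  Xw <- backsolve(L, X, transpose = TRUE)
  yw <- backsolve(L, y, transpose = TRUE)
  fit <- stats::lm.fit(Xw, yw)
  beta <- unname(fit$coefficients)   # (intercept, slope)
  rss <- sum(fit$residuals^2)
  df <- n - 2L
  sigma2 <- rss / df
  XtX_inv <- chol2inv(chol(crossprod(Xw)))
  se <- sqrt(sigma2 * XtX_inv[2, 2])
  tval <- if (se > 0) beta[2] / se else 0
  p <- if (se > 0) 2 * stats::pt(-abs(tval), df) else 1
  list(slope = beta[2], intercept = beta[1],
       se = se, t = tval, p = max(p, .Machine$double.xmin), n = n, df = df)
}

#' Screen every gene of a %intact matrix for association with a trait
#'
#' Applies [gene_prefilter()], drops missing species row-wise, subsets the
#' Brownian covariance accordingly, and fits [pgls_fit()] per gene.
#'
#' @param intact_matrix genes x species matrix of %intact values (NA =
#'   missing data), as produced by [call_losses()].
#' @param tree species tree (phylo) covering the matrix columns.
#' @param groups named assignment of species to `"trait1"`/`"trait2"`.
#' @param ... thresholds passed to [gene_prefilter()].
#' @return data.frame with one row per gene: `gene`, `slope`, `se`, `t`,
#'   `p`, `n`, `excluded_reason` (`""` for tested genes).
#' @export
forward_genomics <- function(intact_matrix, tree, groups, ...) {
  species <- colnames(intact_matrix)
  unknown <- setdiff(species, tree$tip.label)
  if (length(unknown) > 0)
    stop("species not in tree: ", paste(unknown, collapse = ", "))
  unknown <- setdiff(species, names(groups))
  if (length(unknown) > 0)
    stop("species without trait assignment: ", paste(unknown, collapse = ", "))
  C_full <- brownian_covariance(tree, species)
  x_full <- as.numeric(as.character(groups[species]) == "trait1")
  rows <- lapply(rownames(intact_matrix), function(g) {
    yv <- intact_matrix[g, ]
    reason <- gene_prefilter(setNames(yv, species), groups, ...)
    if (reason != "")
      return(data.frame(gene = g, slope = NA_real_, se = NA_real_,
                        t = NA_real_, p = NA_real_, n = sum(!is.na(yv)),
                        excluded_reason = reason, stringsAsFactors = FALSE))
    use <- !is.na(yv)
    fit <- pgls_fit(yv[use], x_full[use], C_full[use, use, drop = FALSE])
    data.frame(gene = g, slope = fit$slope, se = fit$se, t = fit$t,
               p = fit$p, n = fit$n, excluded_reason = "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Rank screened genes and select convergent-loss hits
#'
#' Tested genes are ordered by ascending p value; the selected set contains
#' genes with `p < p_threshold` (default 1e-6) whose slope points towards
#' lower %intact in the derived-phenotype group (negative slope): a
#' significant association in the opposite direction is not a convergent
#' loss.
#'
#' @param results data.frame from [forward_genomics()].
#' @param p_threshold selection threshold on the p value.
#' @return `results` reordered, with a logical `selected` column.
#' @export
rank_and_select <- function(results, p_threshold = 1e-6) {
  tested <- results$excluded_reason == "" & !is.na(results$p)
  results <- results[order(!tested, results$p), , drop = FALSE]
  tested <- results$excluded_reason == "" & !is.na(results$p)
  results$selected <- tested & results$p < p_threshold & results$slope < 0
  rownames(results) <- NULL
  results
}
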