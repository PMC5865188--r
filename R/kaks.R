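# Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor correction.
#
# Conventions (documented here once, used consistently): single-nucleotide
# changes that produce a stop codon count as nonsynonymous for site counting;
# when averaging substitution pathways between two codons, pathways passing
# through a stop-codon intermediate are excluded unless every pathway does;
# codon columns containing a non-ACGT base or a stop codon in either sequence
# are skipped entirely.

.ng86 <- new.env(parent = emptyenv())

ng86_tables <- function() {
  if (!is.null(.ng86$sites)) return(invisible(.ng86))
  code <- Biostrings::GENETIC_CODE
  codons <- names(code)
  syn_sites <- setNames(numeric(length(codons)), codons)
  for (c1 in codons) {
    ch <- chars(c1)
    s <- 0
    for (i in 1:3) for (b in setdiff(BASES, ch[i])) {
      c2 <- ch; c2[i] <- b; c2 <- collapse0(c2)
      if (!is_stop(c2) && code[[c2]] == code[[c1]]) s <- s + 1 / 3
    }
    syn_sites[c1] <- s
  }
  .ng86$code <- code
  .ng86$sites <- syn_sites
  .ng86$paths <- new.env(parent = emptyenv())
  invisible(.ng86)
}

# average (syn, nonsyn) difference counts between two codons over mutation
# pathways, excluding stop intermediates where possible; memoised
ng86_pair_diffs <- function(c1, c2) {
  tb <- ng86_tables()
  key <- paste0(c1, c2)
  hit <- tb$paths[[key]]
  if (!is.null(hit)) return(hit)
  pos <- which(chars(c1) != chars(c2))
  k <- length(pos)
  if (k == 0L) {
    res <- c(sd = 0, nd = 0)
  } else {
    perms <- switch(k, list(1L), list(1:2, 2:1),
                    list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                         c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
    walk <- function(order) {
      cur <- chars(c1); tgt <- chars(c2)
      sd <- nd <- 0; via_stop <- FALSE
      for (j in seq_along(order)) {
        p <- pos[order[j]]
        nxt <- cur; nxt[p] <- tgt[p]
        a <- collapse0(cur); b <- collapse0(nxt)
        if (is_stop(b) && j < length(order)) via_stop <- TRUE
        if (is_stop(a) || is_stop(b)) {
          nd <- nd + 1  # endpoint stops never occur here (callers skip them)
        } else if (tb$code[[a]] == tb$code[[b]]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd = sd, nd = nd, via_stop = as.numeric(via_stop))
    }
    steps <- t(vapply(perms, walk, numeric(3)))
    use <- steps[, "via_stop"] == 0
    if (!any(use)) use <- rep(TRUE, nrow(steps))
    res <- c(sd = mean(steps[use, "sd"]), nd = mean(steps[use, "nd"]))
  }
  tb$paths[[key]] <- res
  res
}

#' Ka/Ks of a pair of in-frame coding sequences (Nei-Gojobori 1986)
#'
#' Counts synonymous and nonsynonymous sites per codon (averaged over the two
#' sequences), averages synonymous/nonsynonymous differences over all
#' substitution pathways per differing codon, and applies the Jukes-Cantor
#' multiple-hit correction to both proportions.  Fewer than 30 codons triggers
#' a warning (estimates are noisy).
#'
#' @param seq1,seq2 in-frame nucleotide strings of equal length divisible
#'   by 3; alignment gap columns must already be removed.
#' @return list with `ka`, `ks`, `ratio` (`NA` and `flag` set when `ks` is 0
#'   or a corrected proportion is >= 3/4), site/difference counts `S`, `N`,
#'   `Sd`, `Nd`, `n_codons`, and `flag` (`""` when clean).
#' @export
#' @examples
#' kaks("TTTGCT", "TTCGCT")$ks > 0   # synonymous third-position change
kaks <- function(seq1, seq2) {
  seq1 <- toupper(seq1); seq2 <- toupper(seq2)
  if (nchar(seq1) != nchar(seq2)) stop("sequences must have equal length")
  if (nchar(seq1) %% 3 != 0) stop("length must be divisible by 3")
  co1 <- codons_of(seq1); co2 <- codons_of(seq2)
  ok <- !grepl("[^ACGT]", co1) & !grepl("[^ACGT]", co2) &
    !is_stop(co1) & !is_stop(co2)
  co1 <- co1[ok]; co2 <- co2[ok]
  if (length(co1) < 30) warning("fewer than 30 usable codons; Ka/Ks unstable")
  counts <- kaks_counts(co1, co2)
  kaks_from_counts(counts)
}

kaks_counts <- function(co1, co2) {
  tb <- ng86_tables()
  S <- (sum(tb$sites[co1]) + sum(tb$sites[co2])) / 2
  N <- 3 * length(co1) - S
  Sd <- Nd <- 0
  diff <- which(co1 != co2)
  for (i in diff) {
    d <- ng86_pair_diffs(co1[i], co2[i])
    Sd <- Sd + d[["sd"]]; Nd <- Nd + d[["nd"]]
  }
  list(S = S, N = N, Sd = Sd, Nd = Nd, n_codons = length(co1))
}

kaks_from_counts <- function(counts) {
  jc <- function(p) {
    if (p >= 3 / 4) return(NA_real_)
    -3 / 4 * log(1 - 4 / 3 * p)
  }
  ps <- if (counts$S > 0) counts$Sd / counts$S else 0
  pn <- if (counts$N > 0) counts$Nd / counts$N else 0
  ks <- jc(ps); ka <- jc(pn)
  flag <- ""
  if (is.na(ks) || is.na(ka)) flag <- "saturated"
  ratio <- NA_real_
  if (flag == "") {
    if (ks == 0) flag <- "ks_zero" else ratio <- ka / ks
  }
  c(list(ka = ka, ks = ks, ratio = ratio, flag = flag), counts)
}

#' Pool NG86 counts over several sequence pairs
#'
#' Site and difference counts of each pair are summed before the
#' Jukes-Cantor correction, giving one pooled Ka/Ks (used to estimate the
#' selected-regime baseline from several intact-species comparisons).
#'
#' @param pairs list of two-element character vectors (or lists) of in-frame
#'   sequences.
#' @return as [kaks()].
#' @export
kaks_pool <- function(pairs) {
  tot <- list(S = 0, N = 0, Sd = 0, Nd = 0, n_codons = 0L)
  for (p in pairs) {
    co1 <- codons_of(toupper(p[[1]])); co2 <- codons_of(toupper(p[[2]]))
    ok <- !grepl("[^ACGT]", co1) & !grepl("[^ACGT]", co2) &
      !is_stop(co1) & !is_stop(co2)
    cnt <- kaks_counts(co1[ok], co2[ok])
    tot <- Map(`+`, tot, cnt)
  }
  kaks_from_counts(tot)
}
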