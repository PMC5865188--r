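# Independent oracles, coded separately from the package internals.

# --- brute-force Nei-Gojobori oracle ---------------------------------------
# Conventions match the documented ones: stop-producing single-base changes
# are nonsynonymous sites; pathways through stop intermediates are excluded
# from difference averaging unless every pathway is; codon columns with
# non-ACGT bases or endpoint stops are skipped.  Translation comes from
# seqinr, independent of the package's Biostrings-based tables.
oracle_aa <- function(codon) seqinr::translate(strsplit(codon, "")[[1]])
oracle_is_stop <- function(codon) oracle_aa(codon) == "*"

oracle_ng86 <- function(s1, s2) {
  split_codons <- function(s)
    substring(s, seq(1, nchar(s) - 2, 3), seq(3, nchar(s), 3))
  c1 <- split_codons(toupper(s1)); c2 <- split_codons(toupper(s2))
  keep <- !grepl("[^ACGT]", c1) & !grepl("[^ACGT]", c2) &
    !sapply(c1, oracle_is_stop) & !sapply(c2, oracle_is_stop)
  c1 <- c1[keep]; c2 <- c2[keep]
  syn_sites <- function(codon) {
    ch <- strsplit(codon, "")[[1]]
    s <- 0
    for (i in 1:3) for (b in c("A", "C", "G", "T")) {
      if (b == ch[i]) next
      alt <- ch; alt[i] <- b; alt <- paste(alt, collapse = "")
      if (!oracle_is_stop(alt) && oracle_aa(alt) == oracle_aa(codon))
        s <- s + 1 / 3
    }
    s
  }
  # recursive pathway enumeration between two codons
  paths <- function(from, to) {
    pos <- which(strsplit(from, "")[[1]] != strsplit(to, "")[[1]])
    if (length(pos) == 0) return(list(list(sd = 0, nd = 0, stop = FALSE)))
    out <- list()
    for (p in pos) {
      f <- strsplit(from, "")[[1]]; t <- strsplit(to, "")[[1]]
      nxt <- f; nxt[p] <- t[p]; nxt <- paste(nxt, collapse = "")
      is_syn <- !oracle_is_stop(nxt) && !oracle_is_stop(from) &&
        oracle_aa(nxt) == oracle_aa(from)
      via_stop <- oracle_is_stop(nxt) && nxt != to
      for (rest in paths(nxt, to)) {
        out[[length(out) + 1]] <- list(
          sd = rest$sd + as.numeric(is_syn),
          nd = rest$nd + as.numeric(!is_syn),
          stop = rest$stop || via_stop)
      }
    }
    out
  }
  S <- (sum(vapply(c1, syn_sites, numeric(1))) +
          sum(vapply(c2, syn_sites, numeric(1)))) / 2
  N <- 3 * length(c1) - S
  Sd <- Nd <- 0
  for (i in which(c1 != c2)) {
    pl <- paths(c1[i], c2[i])
    ok <- !sapply(pl, `[[`, "stop")
    if (!any(ok)) ok <- rep(TRUE, length(pl))
    Sd <- Sd + mean(sapply(pl[ok], `[[`, "sd"))
    Nd <- Nd + mean(sapply(pl[ok], `[[`, "nd"))
  }
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  list(S = S, N = N, Sd = Sd, Nd = Nd, ka = jc(pn), ks = jc(ps))
}

# --- reading-frame oracle ---------------------------------------------------
# A query exon is "broken" when its continuous translation in the frame
# implied by the reference contains a premature stop, or when the net indel
# shift at the exon end is not a multiple of 3.
oracle_broken <- function(ref, qry, phase) {
  q <- gsub("-", "", qry, fixed = TRUE)
  r <- gsub("-", "", ref, fixed = TRUE)
  o <- (3 - phase) %% 3
  n_cod <- (nchar(q) - o) %/% 3
  has_stop <- FALSE
  if (n_cod > 0) {
    starts <- o + 1 + 3 * (seq_len(n_cod) - 1)
    cods <- substring(q, starts, starts + 2)
    has_stop <- any(cods %in% c("TAA", "TAG", "TGA"))
  }
  has_stop || ((nchar(q) - nchar(r)) %% 3 != 0)
}

# largest mutation-free stretch, by direct segment enumeration
oracle_percent_intact <- function(pos) {
  pts <- sort(c(0, pos, 1))
  100 * max(pts[-1] - pts[-length(pts)])
}
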