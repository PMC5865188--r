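# Dating a gene loss: how long has the gene evolved neutrally on its loss
# branch?  The Ka/Ks of the whole branch (K) is modelled as the time-weighted
# average of the selected-regime value Ks_sel (for the fraction Ts/T of the
# branch before the loss) and the neutral value 1 (for Tn/T after it):
#   K = Ks_sel * Ts/T + 1 * Tn/T,   Ts = T - Tn
# which inverts to Tn = T * (K - Ks_sel) / (1 - Ks_sel).

#' Time a lost gene has evolved neutrally
#'
#' Inverts the branch mixture model of Ka/Ks: a gene under selection
#' (Ka/Ks = `ks_sel` < 1) until its inactivation and neutral (Ka/Ks = 1)
#' afterwards shows a whole-branch Ka/Ks of `k`; the neutral time is
#' `T * (k - ks_sel) / (1 - ks_sel)`, clamped into \[0, T\] because sampling
#' noise can push `k` outside \[`ks_sel`, 1\].
#'
#' @param k Ka/Ks of the whole loss branch.
#' @param ks_sel Ka/Ks under selection (from species with the intact gene);
#'   must be < 1.
#' @param t divergence time of the branch (any time unit; typically My).
#' @return neutral time on the same scale as `t`.
#' @export
#' @examples
#' neutral_time(0.6, 0.2, 10)  # 5
neutral_time <- function(k, ks_sel, t) {
  if (any(ks_sel >= 1)) stop("ks_sel must be < 1 (selection below neutral)")
  if (any(t <= 0)) stop("t must be positive")
  tn <- t * (k - ks_sel) / (1 - ks_sel)
  pmin(pmax(tn, 0), t)
}

#' Date one gene loss from codon alignments
#'
#' Estimates the selected-regime baseline `ks_sel` by pooling NG86 counts over
#' all pairs of intact-species sequences, estimates the loss-branch Ka/Ks `K`
#' by comparing the loss-species sequence against its closest intact relative
#' (the intact sequence with the smallest raw nucleotide distance, used as a
#' proxy for the ancestral sequence), and converts `K` into neutral-time
#' bounds for the lower and upper divergence-time bounds of the loss branch.
#'
#' @param loss_seq in-frame coding sequence of the loss species.
#' @param intact_seqs named character vector (>= 2) of in-frame coding
#'   sequences from species in which the gene is intact.
#' @param t_lower,t_upper divergence-time bounds (e.g. My) of the loss branch.
#' @param gene,branch identifiers carried through to the output.
#' @return one-row data.frame: `gene`, `branch`, `K`, `Ks_sel`, `proxy`
#'   (closest intact species), `T_lower`, `T_upper`, `Tn_lower`, `Tn_upper`.
#' @export
date_loss <- function(loss_seq, intact_seqs, t_lower, t_upper,
                      gene = NA_character_, branch = NA_character_) {
  if (length(intact_seqs) < 2)
    stop("need >= 2 intact species to estimate the selected-regime Ka/Ks")
  if (is.null(names(intact_seqs)))
    names(intact_seqs) <- paste0("intact", seq_along(intact_seqs))
  stopifnot(t_lower <= t_upper)
  pairs <- utils::combn(seq_along(intact_seqs), 2, simplify = FALSE)
  ks_fit <- kaks_pool(lapply(pairs, function(p)
    list(intact_seqs[[p[1]]], intact_seqs[[p[2]]])))
  if (ks_fit$flag != "" || is.na(ks_fit$ratio))
    stop("selected-regime Ka/Ks not estimable: ", ks_fit$flag)
  ks_sel <- ks_fit$ratio
  if (ks_sel >= 1) stop("intact-species Ka/Ks >= 1; no selected baseline")
  rawdist <- vapply(intact_seqs, function(s) {
    a <- chars(toupper(s)); b <- chars(toupper(loss_seq))
    use <- a %in% BASES & b %in% BASES
    mean(a[use] != b[use])
  }, numeric(1))
  proxy <- names(which.min(rawdist))
  k_fit <- kaks(loss_seq, intact_seqs[[proxy]])
  if (k_fit$flag != "" || is.na(k_fit$ratio))
    stop("loss-branch Ka/Ks not estimable: ", k_fit$flag)
  k <- min(k_fit$ratio, 1)  # clamp: K cannot exceed neutral
  data.frame(gene = gene, branch = branch, K = k, Ks_sel = ks_sel,
             proxy = proxy, T_lower = t_lower, T_upper = t_upper,
             Tn_lower = neutral_time(k, ks_sel, t_lower),
             Tn_upper = neutral_time(k, ks_sel, t_upper),
             stringsAsFactors = FALSE)
}
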