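# Shared fixture builders + the one large cascade simulation (computed once).

# random in-frame coding sequence without internal stops
fix_cds <- function(n_codons) {
  sense <- setdiff(mkAllCodonsFix(), c("TAA", "TAG", "TGA"))
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}
mkAllCodonsFix <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(b, b, b, stringsAsFactors = FALSE)
  paste0(g[[3]], g[[2]], g[[1]])
}

# apply an edit script to a reference string, producing aligned rows.
# edits: list of list(op = "sub"/"ins"/"del", at = 0-based ref offset,
# len =, seq =)
fix_align <- function(ref, edits) {
  r <- strsplit(ref, "")[[1]]
  ra <- as.list(r); qa <- as.list(r)
  for (ed in edits) {
    if (ed$op == "sub") {
      qa[[ed$at + 1]] <- ed$seq
    } else if (ed$op == "del") {
      for (i in seq_len(ed$len)) qa[[ed$at + i]] <- "-"
    } else if (ed$op == "ins") {
      ra[[ed$at + 1]] <- c(r[ed$at + 1], rep("-", nchar(ed$seq)))
      qa[[ed$at + 1]] <- c(qa[[ed$at + 1]][1], strsplit(ed$seq, "")[[1]])
    }
  }
  list(ref = paste(unlist(ra), collapse = ""),
       qry = paste(unlist(qa), collapse = ""))
}

# simple single-exon gene_alignment around an aligned pair
fix_galn <- function(ref, qry, gene = "g", species = "sp", cds_len = NULL,
                     donor = NA, acceptor = NA, n_exons = 1) {
  ex <- list(list(present = TRUE, ref = ref, qry = qry,
                  ref_len = nchar(gsub("-", "", ref)), qry_start = 1000,
                  qry_end = 1000 + nchar(gsub("-", "", qry)),
                  donor = donor, acceptor = acceptor))
  gene_alignment(gene, paste0(gene, ".t1"), species, "c1", ex,
                 anchors = c(up = 900, dn = 2000), cds_len = cds_len)
}

# the large filter-cascade experiment shared by the acceptance tests:
# computed lazily, once per test run
cascade_env <- new.env()
cascade_experiment <- function() {
  if (!is.null(cascade_env$run)) return(cascade_env)
  cfg <- sim_config(n_genes = 2000, n_loss_genes = 40, seed = 20240101,
                    loss_branches = c("qA", "qC", "qA+qB"))
  sim <- simulate_geneloss(cfg)
  run <- run_pipeline(sim)
  cascade_env$cfg <- cfg
  cascade_env$sim <- sim
  cascade_env$run <- run
  cascade_env
}

# random DNA without package internals
random_dna <- function(n)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
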