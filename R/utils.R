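# Shared low-level helpers: sequences as character strings over A,C,G,T,N,-.

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")
DINUCS <- as.vector(outer(BASES, BASES, paste0))  # all unambiguous 2-mers

#' Reverse complement of a nucleotide string
#'
#' Handles A/C/G/T/N and gap characters; case-insensitive, returns upper case.
#'
#' @param x character vector of nucleotide strings.
#' @return character vector of reverse-complemented strings.
#' @export
revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N", `-` = "-")
  vapply(x, function(s) {
    ch <- rev(strsplit(toupper(s), "", fixed = TRUE)[[1]])
    paste(comp[ch], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# split a string into a character vector of single bases
chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# paste a character vector back into one string
collapse0 <- function(x) paste(x, collapse = "")

# extract codon triplets from a bare sequence string starting at `from`
# (0-based); incomplete trailing codon dropped
codons_of <- function(s, from = 0L) {
  n <- nchar(s)
  if (n - from < 3L) return(character(0))
  starts <- seq.int(from + 1L, n - 2L, by = 3L)
  substring(s, starts, starts + 2L)
}

is_stop <- function(codon) codon %in% STOP_CODONS

# random DNA string without constraint
random_dna <- function(n) collapse0(sample(BASES, n, replace = TRUE))

# random in-frame coding sequence of n_codons codons, no internal stops
random_cds <- function(n_codons) {
  sense <- setdiff(mkAllCodons(), STOP_CODONS)
  collapse0(sample(sense, n_codons, replace = TRUE))
}

mkAllCodons <- function() {
  g <- expand.grid(BASES, BASES, BASES, stringsAsFactors = FALSE)
  paste0(g[[3]], g[[2]], g[[1]])
}

# stable tiny checksum used in the run manifest (text files only; base R)
content_hash <- function(object) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  saveRDS(object, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
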