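---
title: "Detecting, screening and dating gene losses from genome alignments"
author: "genelossr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting, screening and dating gene losses from genome alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genelossr)
```

## The problem

A gene that became dispensable in one lineage decays into a unitary
pseudogene: frameshifting insertions and deletions, premature stop codons,
splice-site mutations and exon deletions accumulate because nothing removes
them.  Catalogues of such losses across many species are a window into which
functions a lineage gave up, and convergent losses in lineages that share a
derived phenotype point at genes whose loss is connected to that phenotype.

`genelossr` detects losses from *reference-anchored pairwise genome
alignments*: the coding exons of an annotated reference genome, each aligned
to its orthologous locus in every query species.  Working from alignments
rather than from query annotations matters because a missing annotation can
reflect a gap or an annotation pipeline quirk rather than a missing gene.
The hard part is not finding candidate inactivating mutations -- they are
everywhere -- but removing the ones that are artifacts of assembly,
alignment, or evolutionary change in gene structure.

## Mutation classes

`scan_exon()` and `scan_gene()` report:

* `FS_INS` / `FS_DEL` -- indels whose length is not a multiple of 3 (they
  shift the reading frame);
* `STOP_IN_INS` -- a premature stop codon inside a frame-preserving
  insertion;
* `STOP_SUBST` -- an in-frame stop codon created by substitution (or, a
  rare relative, spliced together across a frame-preserving deletion --
  flagged `junction` in the detail column);
* `SPLICE_DONOR` / `SPLICE_ACCEPTOR` -- query dinucleotides deviating from
  the GT/GC donor or AG acceptor consensus;
* `BIG_INDEL` -- frame-preserving indels strictly longer than 50 bp, which
  are rare in conserved genes;
* `EXON_DELETED` / `EXON_UNALIGNED` -- exons without aligned query
  sequence, split by whether the region between the nearest aligning
  anchors has room for the exon.

The query row of each exon is translated continuously in the frame implied
by the reference, so the frame tracks cumulative indels.  Stops that appear
only in a shifted frame are consequences of a frameshift, not events of
their own; they matter for exactly one decision: a run of frameshifts whose
signed lengths sum to 0 mod 3 restores the frame and is *compensated*
(`apply_compensation()`) -- unless a stop codon arose in the shifted
stretch, in which case the frameshifts stay and the stop is promoted to a
record.  Selenocysteine recoding of TGA and minor-spliceosome AT--AC introns
are not modelled; both would need reference-side annotations this pipeline
does not consume.

## The filter cascade

`filter_cascade()` applies, in a fixed order:

1. **Assembly gaps.** Deleted or unaligned exons whose inter-anchor region
   overlaps an N run are unknowable, not deleted (`missing_data`); point
   mutations within 1 bp of an N are discarded as sequencing suspects.
2. **Conserved gene order.** A gene whose aligned locus is not on the same
   query contig as, and between, the loci of its reference neighbours is
   likely a processed pseudogene or paralog alignment; it is excluded from
   loss calling entirely.  Unaligned neighbours are insufficient evidence
   to fail a gene (pass with a warning).
3. **Rescue realignment.** Three ways an exon-structure-aware look at the
   locus explains a mutation away: a splice site that *moved* (a consensus
   dinucleotide within ±18 bp whose use keeps the frame and introduces no
   stop), a precisely deleted intron (two exons fused into one larger
   composite exon -- both splice records of that intron are dropped), and a
   local affine-gap realignment (Biostrings' aligner plus a score-neutral
   gap slide onto codon boundaries) in which the mutation does not recur.
   Rescue only ever removes records.
4. **Terminal trim.** Mutations in the first or last 20% of the coding
   sequence are discarded; termini are weakly constrained and truncated
   proteins missing 10% of their C terminus are often functional.
5. **Isoform choice.** Among annotated principal/alternative isoforms the
   one with the fewest surviving mutations speaks for the gene (ties: the
   longer CDS, then the lexicographically smaller transcript id).

The ±18 bp splice-search window is a package choice (six codons; covers the
common small shifts without inviting spurious rescues), as are the strict
inequalities of the terminal trim at 0.2/0.8 and the decision to trim before
isoform selection.  Worth knowing: in random intronic sequence the chance of
*some* frame-compatible GT/GC within ±18 bp is high, so a real splice-site
mutation is often rescued away.  Splice records are therefore weak loss
evidence on their own; the loss thresholds below never depend on a single
record.

## %intact and loss calling

The surviving mutations of an isoform, as fractions of its coding length,
divide [0, 1] into segments; 100 times the largest segment is the maximum
percentage of the intact reading frame, `percent_intact()`.  Mutations at
20% and 55% leave `percent_intact(c(0.20, 0.55))` = `r percent_intact(c(0.20, 0.55))`%.
At the gene level the value is the maximum over isoforms.  Indel and
exon-deletion records enter as point positions (their start), because the
statistic is defined on mutation positions, not spans.

A gene in a query species is a **loss candidate** when %intact < 60 *and*
at least 20% of its exons carry surviving mutations; single-exon genes
instead require at least two surviving mutations (`classify_gene()`).  A
gene excluded by synteny, or with most of its exons unknowable, is
`missing_data`.

Because a reference annotation contains genes younger than the species
ancestor, a loss is only countable in species descending from the most
recent common ancestor of the reference and all species where the gene is
intact -- zero surviving mutations *after* filtering, which is what the
filters are for (`infer_ancestral_presence()`).  Mutations identical in
class, exon, position and length across species
(`shared_mutation_support()`) both corroborate a call and place the loss on
the shared ancestral branch.

## The convergent-loss screen

`forward_genomics()` regresses each gene's %intact on a binary trait
(derived phenotype = trait group 1) by generalized least squares whose
error covariance is Brownian motion on the species tree
(`brownian_covariance()`): without this, six aquatic mammals look like six
independent observations when they are mostly one clade.  Brownian motion
with no additional transform is the default of the framework we follow; the
fit is closed-form (whitening by the Cholesky factor), reduces exactly to
OLS when the covariance is the identity, and its p value is invariant to
rescaling the tree.  Missing species are dropped row-wise with the
covariance subset to match.

Before testing, `gene_prefilter()` removes genes that cannot inform the
screen: more than 50% of either trait group missing, fewer than 90% of the
background species at %intact ≥ 90, or at least 5% of them below 60 -- the
screen wants genes lost in the derived group and *intact elsewhere*.
Selection takes tested genes with p < 1e-6; since the p value is two-sided,
selection additionally requires the slope to point at *lower* %intact in
the derived group (`rank_and_select()`), otherwise the screen would also
return the mirror-image pattern.

## Dating a loss

After inactivation a gene evolves neutrally, so the Ka/Ks of a loss branch
is a time-weighted mixture of the selected-regime value and 1:

$$K = K_s \cdot T_s/T + 1 \cdot T_n/T, \qquad
  T_n = T\,(K - K_s)/(1 - K_s).$$

`kaks()` implements Nei--Gojobori (1986) counting with Jukes--Cantor
correction: closed-form, assumption-light, and checkable against a
brute-force pathway enumeration (the test suite does exactly that, to
1e-10).  Conventions: stop-producing changes count as nonsynonymous sites;
pathways through stop intermediates are excluded from difference averaging
unless all of them are; codon columns with non-ACGT bases or endpoint stops
are skipped.  `date_loss()` estimates the selected baseline by pooling NG86
counts over all intact-species pairs, measures the loss branch against the
*closest intact relative* as an ancestral proxy (a deliberate shortcut --
full ancestral reconstruction is out of scope and the proxy's extra branch
biases $T_n$ slightly toward the selected side, visible in the simulation
tests), computes $K$, clamps it at 1, and converts both divergence-time
bounds into $T_n$ bounds, clamped into $[0, T]$ because noise can push $K$
outside $[K_s, 1]$.

## Read validation

A mutation is confirmable against unassembled reads when the assembly
context -- the mutated allele with 50 bp of flank on each side -- occurs as
an exact substring of at least 10 reads, in either orientation (reads are
unstranded); `extract_context()` and `count_support()` implement exactly
that, and nothing fuzzier.  The full context must sit inside a single read,
so reads shorter than ~101 bp can never validate a point mutation, and even
long reads at modest coverage carry fewer full-window copies than their
nominal depth: at 20x with 800 bp reads the expected number of reads
containing a 101-bp window is about $20 \times (700/800) \approx 17$
*before* any sequencing error, and each 1%-error read retains the exact
context only with probability $0.99^{101} \approx 0.36$.  Validation at
such coverage therefore demands either deeper data or error-free reads;
the package reports honest match counts and leaves the threshold to the
caller.

## The synthetic study

`simulate_geneloss()` generates a complete, truth-labelled study: coding
genes with exon--intron structure evolve along a species tree at
codon granularity -- proposals at the neutral rate (branch lengths are
substitutions per neutral site), synonymous changes accepted, nonsynonymous
accepted with probability `omega_sel` (default 0.2, a typical conserved-gene
Ka/Ks), stops rejected; in-frame 1--2-codon indels in exon interiors; after
a configurable switch point on a loss branch (default halfway), everything
is accepted.  Injected inactivating mutations (a stop 5' of one or two
frameshifts, in distinct constitutive exons, within the central 25--75% of
the CDS) define the truth labels; the codons they occupy are pinned during
subsequent neutral evolution so that every injected mutation remains
recoverable from the emitted alignments -- the generator's contract with the
tests.

Alignments are emitted from the known homology rather than recomputed with
an aligner, so detected mutations are attributable to recorded causes.  On
top of the clean signal the generator layers what real data adds: assembly
substitution/indel errors (defaults 2e-5 and 2e-6 per base, matching
finished-to-good-draft genomes in coding regions), N runs, donor shifts by
+3 bp, precise intron deletions, one-column indel misplacement by the
emitting "aligner", and relocation of a gene to a different contig
(processed-pseudogene mimic).  It does not emulate repeats, GC isochores,
empirical indel spectra, or alignment failure over long distances -- so
passing tests say the *logic* is right under the stated noise model, not
that any particular real assembly is this well behaved.

Default problem sizes in the test suite -- 2,000 conserved plus 40 loss
genes over five query species for the cascade experiment, a 40-leaf tree
with three convergent lineages at the %intact level for the screen, 50
replicates of 1,000 codons for dating -- are chosen so each experiment has
enough events to measure its rate against its threshold while a full run
stays a desk-scale computation.

## Numerical and design notes

* Internal coordinates are 0-based half-open everywhere; GFF (1-based
  closed) and MAF semantics are converted exactly once, at parse/write.
* Any run of N, length ≥ 1, counts as an assembly gap -- the most
  conservative reading, since the gap filter only ever discards evidence.
* `percent_intact()` rounds at the ninth decimal to absorb binary
  floating-point noise (1 − 0.55 is not 0.45 in a double).
* The pipeline runs in memory end to end; at these problem sizes a resume
  mechanism for intermediate stages would cost more complexity than it
  saves, so the run manifest records config and output hashes instead.
* MAF has no reader among the installed format libraries, so the package
  carries a minimal parser/writer for the subset it emits; everything else
  (FASTA, GFF3/GTF, Newick) goes through Biostrings, rtracklayer and ape.
* Start-codon (ATG) disruption is not a mutation class: the inactivating
  classes are the frame, stop and splice lesions listed above, and a
  handful of genes initiate at non-AUG codons anyway.

## Limitations

The synteny rule is one concrete realisation of "conserved gene order";
real pipelines may want chain-level context.  The rescue realigner is a
frame-aware affine aligner plus explicit structure rules, not a
splice-HMM; exotic exon-structure changes (novel query exons, multi-intron
rearrangements) are out of scope.  Dating ignores ancestral-sequence
uncertainty and uses a single nearest intact relative as proxy.  The
minus strand is handled in the reference annotation but the MAF collector
expects positive-strand query rows, as the generator emits.
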