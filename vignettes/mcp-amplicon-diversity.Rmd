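---
title: "Methods: MCP amplicon diversity analysis with cyanomcp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MCP amplicon diversity analysis with cyanomcp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyanomcp)
```

## The problem

Myocyanophages — T4-like viruses infecting cyanobacteria — are tracked in
environmental samples through marker-gene surveys of the g23 major capsid
protein (MCP) gene. A short (~145 bp, primer-inclusive) fragment of that
gene can be amplified from both water-column and sediment DNA with a single
degenerate primer pair, which makes it usable for ancient sedimentary DNA
where long amplicons fail. `cyanomcp` implements the complete analysis that
such a survey needs: recognising and demultiplexing the barcoded amplicons,
a reading-frame-aware filter exploiting the fact that the marker is
protein-coding, OTU clustering at several identity levels, and alpha/beta
diversity with phylogenetic (UniFrac) distances.

Everything is exercised against a bundled synthetic amplicon generator with
full ground truth, so the whole pipeline is testable offline.

## Degenerate primer model

Primers are IUPAC strings plus `I` for inosine, a universal base that we
treat as matching all four nucleotides; its complement is defined as `I`
again, since inosine pairs indiscriminately on either strand (no standard
fixes this — it is our documented choice). The default pair is mcp-821F
(`CTKGCDGARATYAACMGIGAART`, 384 concrete expansions) and mcp-966R
(`ADDAGWCCYTTGAAYTTYTCAAC`, 144 expansions). An `N` in a *reference*
sequence matches every primer code: absence of information is not treated
as evidence of a mismatch.

In-silico PCR pairs each plus-strand forward-primer site with every
downstream reverse-primer binding site and reports all qualifying
amplicons, sorted by total mismatches then span length — there is no silent
"best hit". Coordinates are 1-based inclusive throughout. Amplicon length
is **primer-inclusive**: note that a forward site at 748 and a reverse site
ending at 893 give a 146-nt span even though the fragment is conventionally
called "~145 bp"; whether reported amplicon lengths include both primers is
genuinely ambiguous in the field, and we adopt the primer-inclusive
convention consistently rather than resolving the ambiguity. The package
ships a small *synthetic* g23-like reference
(`inst/extdata/spm2_g23_synthetic.fasta`, labelled synthetic in its name)
with the two binding sites planted at 748–893 so that coordinate reporting
is verifiable offline.

## Read filtering

Two filters run before clustering:

* **Quality**: a read is kept iff its mean Phred score is at or above the
  threshold (default 25; the boundary is kept). The summary statistic is a
  choice — "low quality" could equally mean the minimum base score — and a
  `stat = "min"` mode is available; mean is the default because platform
  quality summaries are conventionally reported as means. Reads without
  qualities (e.g. Sanger clone libraries supplied as FASTA) bypass this
  stage with a message so clone data flow through the same downstream code.

* **Frame filter**: the marker is protein-coding, so admissible read
  lengths differ from the canonical 145 nt by whole codons: `145 ± 3n`
  within an inclusive window of 136–154 nt, i.e. exactly
  {136, 139, 142, 145, 148, 151, 154}. Reads of other lengths are
  frame-shift artefacts. Surviving reads are translated and any read whose
  translation contains a stop codon is discarded. The screen uses frame
  offset 0 on the (barcode-trimmed, primer-inclusive) read by default: the
  generator constructs amplicons stop-free in that frame, and with primers
  attached the three length classes share a single frame phase. The frame
  is configurable, and an `any-frame-open` mode keeps a read if *any* of
  the three frames is stop-free, for data whose frame convention is
  unknown. Every discarded read is counted under exactly one reason
  (`out_of_window`, `non_codon_length`, `stop_codon`), checked in that
  order, so the discard ledger can be re-aggregated under any accounting.

The per-sample composition of the surviving 142/145/148-nt length classes
is the pipeline's first scientific readout; the 142/145 read-count ratio is
reported as a relative index of terrestrial input versus in-situ
cyanophage production (142-nt fragments are enriched in non-cyanophage,
soil-associated hits). A sample with no 145-nt reads has no defined ratio
and errors rather than returning infinity.

## Pairwise identity and OTU clustering

Identity between two reads is defined on a Needleman–Wunsch global
alignment with affine gaps: match +1, mismatch −1, a gap of length *l*
costs 2 + 0.5·*l*, end gaps charged. Identity = identical aligned positions
/ total alignment columns, gaps included. The aligner is implemented in
compiled code for clustering-scale throughput; its optimal scores are
verified in the test suite against both an independent textbook dynamic
program and `Biostrings::pairwiseAlignment` under the same scoring. Where
several alignments are co-optimal the traceback is deterministic and the
argument order is canonicalised internally so identity is symmetric. An
`end_gaps = "free"` (overlap) mode is available for clustering mixed
142/145/148-nt fragments without charging the biological length
difference; the default charges end gaps, which keeps cross-length
clustering conservative.

Clustering is greedy centroid assignment: dereplicate exact duplicates,
sort uniques by descending abundance (ties by input order; a pure
input-order mode is retained for order-sensitivity experiments), and scan
once — each unique joins the first centroid at or above the threshold or
founds a new OTU. The first-assigned member (the centroid) is the OTU's
representative. This reproduces the behaviour, not the bit-exact output,
of the greedy centroid tools commonly used for this task, whose internal
identity definition differs subtly; behavioural equivalence (abundance
ordering, threshold semantics, determinism) is the contract. A singleton is
an OTU with total count 1 *across all samples* — an OTU with one read in
each of two samples is kept. Dominance is strictly greater than 2%
relative abundance within a sample.

## Alpha diversity

Exact rarefaction uses the hypergeometric closed form
E[S~n~] = Σ~i~ (1 − C(N−N~i~, n)/C(N, n)) evaluated with log-gamma
arithmetic, stable at deep-sequencing scale (10^5 reads and beyond);
Monte Carlo mode subsamples without replacement under a caller-supplied
seed. Good's coverage C = 1 − F₁/n is computed on the (sub)sampled
community, with the exact mode using the analogous expectation for the
singleton count F₁. Depths beyond the community size are errors, not
extrapolations.

## Trees and beta diversity

Representative sequences are placed on a distance tree with d = 1 −
identity, clustered by UPGMA (default; rooted and ultrametric) or neighbor
joining (midpoint-rooted, negative branch lengths clamped to zero). A
maximum-likelihood amino-acid phylogeny is out of scope: UniFrac and the
sample-clustering topology, not phylogenetics per se, are the analysis
surface here, and distance trees serve that purpose.

UniFrac is computed from a per-edge tip-incidence decomposition of the
tree. Unweighted UniFrac is unique branch length over the branch length of
the union of the two communities; weighted UniFrac is Σ b~k~·|p~kA~ −
p~kB~| over edges with subtree read proportions p, normalised by default
by the abundance-weighted root-to-tip depth so values lie in [0, 1] (raw
values available by flag). The implementation is cross-checked in the test
suite against a naive branch-enumeration oracle (to 1e−12) and against an
independent published implementation.

PCoA is classical metric scaling via `stats::cmdscale`: double-centre
−½D², eigendecompose, keep positive-eigenvalue axes. Negative eigenvalues
(non-Euclidean input) are reported, never silently dropped.

Sample clustering robustness uses jackknife resampling: every sample is
subsampled without replacement to a common depth — by default 75% of the
smallest sample total, a conventional compromise between resampling
perturbation and information loss, since no standard prescribes the depth —
and the UniFrac + UPGMA tree is recomputed; each internal node of the
full-data tree is annotated with the percentage of replicates containing
the same leaf bipartition (1000 replicates by default).

## The synthetic data generator

The generator emulates the statistical structure of a multi-sample MCP
amplicon survey:

* **Haplotypes** are full primer-inclusive amplicons: a concrete expansion
  of the forward primer, a random insert, and the reverse-complement of a
  concrete reverse-primer expansion, with total length in the 142/145/148
  classes (all ≡ 145 mod 3) and **no stop codon in frame 0 by
  construction** (rejection sampling of the offending codons, not post-hoc
  filtering). All pairs are kept below a divergence floor (default 20%
  divergence, i.e. ≤ 80% identity) so each haplotype is its own OTU at the
  90% level.
* **Abundances** follow a log-normal weight model (default meanlog 1,
  sdlog 1.5), giving the log-skewed, singleton-tailed distributions that
  exercise Good's coverage and singleton removal.
* **Length-class mixtures** are per-sample. The default eight-sample study
  has a marine-like group (145-nt class at 96–97%) and a lake-like group
  containing two "KS-like" sediment samples in which the 148-nt class
  dominates (~52%) and the 142/145 ratio is elevated — more in the deeper
  KS2-like sample (planted 0.21/0.27 ≈ 0.78) than in KS1 (0.15/0.32 ≈
  0.47) — mirroring the published contrast between surface and deep
  sediment. Group-private dominant haplotype pools (boosted 60×) with a
  shared rare tail plant a clean between-biome beta-diversity signal while
  keeping the groups connected.
* **Errors** are substitution-only at a flat per-base rate (default 1%).
  Indels are deliberately excluded from the default model because length
  classes are the analysis signal and indel noise would conflate generator
  error with biological length variation. Quality strings are drawn from a
  normal Phred model (default mean 30.8, sd 3, clamped to [2, 41]); they
  are Phred-plausible in range and shape but not coupled base-by-base to
  the planted errors — a realistic miscall-probability coupling is out of
  scope.
* **Determinism**: a fixed seed reproduces the study byte-for-byte.

What passing tests on this generator do *not* show: behaviour under real
Illumina error profiles (quality-dependent miscalls, indels), chimeras,
primer-site mutations in real templates, or the taxonomic composition of
real communities. The generator validates the *pipeline arithmetic* and
its ground-truth recovery, not platform realism.

## Problem sizes and numerical choices

The bundled tests and the acceptance script run the full study at reduced
sequencing effort (hundreds of reads per sample; 800 per sample in the
acceptance script; 10,000 reads where binomial recovery of class
proportions is asserted). These sizes were chosen so that every assertion
is statistically comfortable at its scale — e.g. class-proportion recovery
is asserted within three binomial standard errors, and the 20-haplotype
recovery experiment uses a moderate abundance spread (sdlog 0.5) and 800
reads so the rarest haplotype still receives ≈15 reads in expectation.
Haplotype-recovery assertions run over ten seeds. Other conventions:
quality boundary inclusive-keep; length window inclusive; dominance strict;
identity threshold inclusive (`>=`); ties in abundance sorting broken by
first appearance; jackknife and Monte Carlo seeds always explicit and
logged in the pipeline manifest.

## Known limitations

* No denoising/ASV inference and no chimera detection (not part of this
  analysis design).
* Greedy clustering is order-dependent by construction; the abundance
  ordering makes it reproducible but it is not a global optimum.
* The identity definition counts gap columns in the denominator; tools
  with subtly different denominators will report slightly different OTU
  counts near a threshold.
* Weighted UniFrac normalisation assumes a rooted tree with non-negative
  branch lengths; NJ trees are midpoint-rooted and clamped.
* The bundled g23-like reference is synthetic: it validates coordinate
  arithmetic, not primer performance on real templates.

## A worked miniature

```{r example, eval = FALSE}
study <- generate_study(design = study_design(reads_per_sample = 400), seed = 1)
rs <- frame_filter(quality_filter(study$reads)$kept)
glance(rs)
tab <- remove_singletons(cluster_greedy(rs$records, 0.90))
glance(tab)
tree <- build_tree(tab$representatives)
jk <- sample_upgma_with_jackknife(tab, tree, reps = 1000, seed = 1)
autoplot(pcoa(unifrac(tab, tree)))
```
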