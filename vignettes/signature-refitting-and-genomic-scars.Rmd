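---
title: "Signature refitting and genomic scar scores: models and methods"
author: "scarsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature refitting and genomic scar scores: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scarsig)
```

# Scope

`scarsig` implements the downstream statistical layer of a tumor/normal
whole-genome breast-cancer analysis: variant-class filtering of MAF-style
tables, tumor mutational burden, SBS96/ID83 mutation catalogs, refitting of
catalogs against fixed COSMIC-style reference signatures by
expectation-maximization, the three genomic scar scores with homologous
recombination deficiency (HRD) classification, and cohort-level statistics
(population allele-frequency comparison, panel concordance, HRD-signature
correlation, clinical summary tables). Upstream steps — alignment, variant
calling, annotation, and allele-specific copy-number segmentation — are out
of scope; their outputs (MAF-dialect variant tables and Sequenza-style
segment tables) are this package's inputs.

# Variant classes and filters

Variant tables use the MAF `Variant_Classification` vocabulary as a closed
set. Two filters recur throughout:

* the **germline discard set** — `Intron`, `RNA`, `Splice_Region`,
  `Splice_Site`, `3'UTR`, `5'UTR`, `Silent` — removed before germline gene
  analysis;
* the **somatic impact keep set** — frame-shift and in-frame indels,
  missense, nonsense, nonstop, splice region, splice site, translation
  start site — the classes retained for somatic gene analysis and the
  classes counted by TMB. Note the asymmetry: splice-region variants are
  discarded on the germline side but kept on the somatic side.

A variant is flagged (likely) pathogenic when ClinVar calls it
`pathogenic`/`likely_pathogenic`, SIFT calls it `deleterious`, or PolyPhen
calls it `possibly_damaging`/`probably_damaging`. ClinVar `conflicting` and
`not_reviewed` deliberately do **not** flag: an unreviewed significance
status is treated as no evidence.

TMB is the impact-class count divided by the coding territory in Mbp.
There is no universal coding denominator, so `codingMb` is an explicit
parameter (default 35, a common estimate of the GRCh38 coding + essential
splice territory); somatic mutational prevalence divides the *unfiltered*
count by the genome size in Mbp (default 3000, or the simulated layout's
total). For breast cancer, prevalence typically lies in 0–10 /Mbp, which
the default simulation profile (2.5 SNVs + 0.35 indels per Mbp) respects.

# Mutation catalogs

SNVs map to the 96 pyrimidine-centric trinucleotide channels: when the
reference base is a purine, variant and flanks are reverse-complemented, so
both strand descriptions of one event share a channel. Indels map to the 83
COSMIC indel channels. The indel classifier:

1. left-aligns the event against the reference (deterministic channel for
   equivalent indel descriptions);
2. counts additional tandem copies of the inserted/deleted sequence
   immediately 3' of the locus;
3. 1-bp events go to pyrimidine-represented homopolymer channels
   (deletion subtype 0–5 = additional copies, i.e. homopolymer length
   1–6+; insertion subtype 0–5 = reference copies 0–5+);
4. longer events with at least one tandem copy (or any longer insertion)
   go to repeat channels, length capped at "5+";
5. repeat-free deletions of 2+ bp go to microhomology channels, with
   microhomology the longer of the common prefix with the 3' flank and the
   common suffix with the 5' flank, capped at length − 1 (after
   left-alignment the 5'-side term is always 0, but both are computed);
   microhomology 0 falls back to the zero-repeat deletion channel.

Channel label strings and their canonical order follow the
COSMIC/SigProfilerMatrixGenerator convention so that bundled and downloaded
signature files align row-wise; loaders reorder file rows to this canon,
making on-disk row order irrelevant. Catalogs use **all** somatic
mutations, not the impact-filtered subset. Records that cannot be
classified (reference mismatch, contig edge) are counted and reported via
`nUnclassified()`, never silently dropped. Dinucleotide and
transcriptional-strand-bias channels are not implemented.

# EM signature refitting

A sample's catalog $m$ is modeled as multinomial over channels with
mixture probabilities $p_c = \sum_k \pi_k S_{kc}$, where $S$ is the fixed
signature matrix (rows sum to 1) and $\pi$ the unknown exposures. EM
maximizes $\ell(\pi) = \sum_c m_c \log \sum_k \pi_k S_{kc}$ with

* E-step responsibilities $r_{ck} = \pi_k S_{kc} / \sum_j \pi_j S_{jc}$,
* M-step $\pi_k = \sum_c m_c r_{ck} / \sum_c m_c$.

Initialization is uniform ($1/K$), so fits are deterministic and seed-free;
iteration stops when the largest absolute weight change falls below `tol`
(default 1e-8) or at `maxIter` (default 10000). The log-likelihood is
non-decreasing per iteration (asserted in tests via `trace = TRUE`). A
channel observed in the data but unreachable under every signature is an
explicit error — the model cannot explain the data, and renormalizing it
away would silently bias exposures. Fitting uses the full supplied
signature set with no sparsity pruning by default (`prune = 0`); an
optional threshold zeroes small weights and renormalizes. De novo signature
extraction and exposure confidence intervals are not implemented.

The bundled signature sets are synthetic stand-ins *shaped like* their
COSMIC namesakes (clock-like CpG C>T; APOBEC-like TpC channels; a flat
HRD-like substitution signature; homopolymer indel processes; a
microhomology-deletion process and a repeat-free long-deletion process).
They were designed once, before any benchmarking, with mutual
identifiability in mind — only one near-flat signature per scheme — because
a test of the optimizer should not be confounded by a deliberately
degenerate basis. Real analyses should load downloaded COSMIC v3.3
matrices with `readSignatureSet()`.

# Genomic scar scores

Segments are preprocessed by merging identical adjacent states and
iteratively removing segments shorter than the smoothing window (default
3 Mb), shortest first; matching neighbors merge across the gap, differing
neighbors extend to its midpoint so adjacency is preserved. The three
scores, following the scar definitions used with Sequenza-derived
allele-specific copy numbers:

* **HRD-LOH** — maximal runs of LOH state (minor copy 0, major ≥ 1) with
  total length strictly greater than 15 Mb that do not span the whole
  chromosome. Spanning is judged against the *layout* length rather than
  the observed segment extent, so an uncovered telomeric gap cannot turn a
  whole-chromosome LOH into a countable event.
* **LST** — per chromosome arm (segments split at the centromere first),
  breakpoints between adjacent segments in different states where both
  flanks are ≥ 10 Mb, counted after 3 Mb smoothing.
* **ntAI** — allelic-imbalance segments (major ≠ minor) that reach a
  recorded chromosome end (`telomereMargin` default 0 bp: the segment must
  abut it) and do not cross the centromere interval.

Each threshold is a named argument so users can match other
implementations. The HRD sum is LOH + LST + ntAI; the HRD-high call uses
the literature threshold 42 with an *inclusive* boundary (sum ≥ 42),
since 42 is described as the threshold line itself; the boundary is
configurable. Ploidy-dependent LST normalization (subtracting a ploidy
term, used by some pipelines) is **not** applied — it is not part of the
scar definitions adopted here — which users comparing against such
pipelines should keep in mind.

# Cohort statistics

The aggregated cohort allele frequency at a site assumes non-mutated
samples carry zero alternate alleles at the mean depth of the mutated
samples: $AF = \sum a_i / (\sum d_i + (N - k)\,\bar d)$. When both
reference populations report a variant, the comparison uses their mean;
with one source, that single value; variants in neither are flagged and
kept. Panel concordance matches on (chromosome, position, ref, alt) after
restricting WGS calls to the panel gene list and, optionally, to exonic
classes — defined as the complement of `Intron`, `RNA`, `3'UTR`, `5'UTR`
(splice categories stay, since they are targeted by panels even though the
germline filter drops them). HRD-versus-exposure association uses Pearson
correlation by default (the claim being linear co-variation), with
Spearman behind a flag; a constant column yields `NA`, never 0. Clinical
summary tables round percentages half away from zero to integers by
default (denominator = group size, `NA` as its own category), with a
one-decimal option because published tables mix precisions.

# The synthetic-data generators

The generators exist so every stage is testable with known ground truth —
the real study's patient-level data are controlled-access.

* `simGenome()` writes random sequence at GC 0.41 with tandem-repeat
  cassettes (unit 2–5 bp, 2–7 copies) embedded every 2 kb so that all ID83
  repeat channels are realizable on a megabase-scale toy genome;
  homopolymers arise naturally.
* `simMutations()` defines exposure ground truth at the channel-sampling
  level: channels are drawn i.i.d. from the mixture, then loci realizing
  each channel are found (trinucleotide-context lookup for SNVs;
  homopolymer/repeat/microhomology search with classify-verification for
  indels). Recovery error of the EM stage is therefore sampling noise plus
  optimizer, never placement artifact. An unplaceable channel raises a
  "context exhaustion" error instead of silently substituting.
* `simSegments()` plants scar events at non-interacting positions:
  telomeric 8 Mb (2,1) segments for ntAI (too short to be an LST flank),
  telomeric balanced 12 Mb (3,3) blocks whose single qualifying breakpoint
  is the planted LST, and interior 16 Mb (2,0) runs insulated by 4 Mb
  (3,2) spacers for LOH. Planted counts are recovered exactly by
  construction, which the tests assert.
* `simHrdCohort()` draws a latent HRD intensity per sample that jointly
  scales planted scar counts and the SBS3/ID6/ID8 mixture weights,
  emulating the situation in which scar sums and HRD-signature exposures
  are independent readouts of one underlying deficiency.
* `simPanelPair()` thins a WGS call set with per-variant retention
  probability `sharing` (default 0.9) and adds panel-only false positives
  (rate 0.05), emulating panel-versus-WGS asymmetry.

What the simulations do *not* emulate: replication-timing or chromatin
covariates of mutation density, purity/ploidy distortion of copy numbers,
sequencing error, or read-level data. Passing tests therefore demonstrate
correctness of the statistical layer on its stated inputs, not robustness
to upstream artifacts.

The synthetic clinicopathological table shipped in
`inst/extdata/cohort_metadata_synthetic.tsv` is a reconstruction: 29
patient rows (15 adjuvant, 14 neoadjuvant) whose per-variable marginal
counts — receptor status, IHC subtype, stage — and age mean, SD and range
match a published breast-cancer cohort description; the joint row-level
assignments are synthetic (subtypes consistent with receptor status,
integer ages found by search to match the printed moments).

# Problem sizes and numerical choices

The test suite and acceptance script use: 100 catalogs of 20000 mutations
against K = 5 signatures for EM recovery (mean absolute exposure error
bound 0.02); 200 random segment profiles per score against independent
brute-force oracles plus 100 planted configurations recovered exactly;
1000 planted SNVs and 1000 planted indels re-classified against a
string-scanning oracle; a 10-sample cohort at target TMB 2.0 over 35 Mbp
(tolerance ±0.2, ~Poisson error of the qualifying count); and a 29-sample
HRD-graded cohort for the correlation check (r > 0.9). These sizes keep
the whole suite to a few minutes on one core while leaving the Monte Carlo
error well inside each tolerance.

Numerical conventions worth knowing: coordinates are 1-based inclusive
(MAF convention) with 0-based conversion only at FASTA access; multi-allelic
rows must be pre-split (one record = one allele); EM convergence is on the
max weight change, not the likelihood change; percent rounding is half
away from zero (R's `round()` rounds half to even, which published tables
do not).

# Known limitations

* Scar-score parameterizations differ subtly between published
  implementations (ploidy terms, margin conventions); all knobs are
  exposed, but the defaults here are one specific, documented choice.
* The ID83 classifier assumes indels arrive in MAF allele convention;
  VCF-style anchored alleles must be converted upstream.
* Exposure uncertainty is not quantified; bootstrap over catalogs is the
  natural extension.
* Whether TMB should count multi-nucleotide variants separately is moot
  here: records are SNP/INS/DEL only.
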