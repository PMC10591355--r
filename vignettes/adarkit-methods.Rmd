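---
title: "Methods: guide design and A-to-I editing quantification with adarkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: guide design and A-to-I editing quantification with adarkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adarkit)
```

## The biology in brief

Adenosine deaminases acting on RNA (ADAR) deaminate adenosine to inosine
inside double-stranded RNA; downstream machinery reads inosine as guanosine,
so a targeted A-to-I edit is functionally an A>G substitution at the RNA
level. An ADAR-recruiting RNA (arRNA) is an antisense guide that pairs with
the target transcript around a chosen adenosine and places a cytidine
opposite it; the resulting A:C mismatch inside a long duplex is ADAR's
preferred substrate, and no exogenous enzyme is needed. Circularizing the
guide (by flanking it with Twister ribozymes whose cleavage leaves ends that
an endogenous ligase joins) makes expression durable in vivo.

The approach has two characteristic failure modes that this package's
analysis side addresses: *bystander editing* — other adenosines inside the
guide–target duplex get edited too — and apparent off-target edits elsewhere
in the transcriptome, which must be separated into sequence-dependent events
(the guide pairing somewhere it should not) and guide-independent noise.

## Guide design

A design is specified by the nomenclature `X-<base>-Y`: X bases pair 5' of
the target adenosine on the target strand, Y bases 3' of it, and the middle
base (a cytidine by default) sits opposite the target A and belongs to
neither arm. The realized guide is the reverse complement of the pairing
window with that substitution. Coordinates are 0-based and offsets are
signed relative to the target A (negative = 5' of it on the target strand),
so a bystander "at −28" is 28 nt upstream of the target.

Orientation of the two numbers is a community convention rather than
something the name itself encodes; `parse_design_name()` therefore exposes
`name_orientation` and defaults to reading the first number as the 5'
(upstream) arm. If a given lab uses the opposite convention, one switch
flips every design consistently.

Bystander mitigation is the ΔA strategy: deleting the guide uracil opposite
a bystander adenosine leaves that adenosine unpaired, which abolishes its
editing while the rest of the duplex is intact. `design_arrna()` enforces
that deletions address actual bystander adenosines and records the pairing
in a duplex map, so tests can verify structurally (not just by length) that
a deleted offset has no partner. Engineered bubbles/bulges — small
insertions or forced mismatches believed to help anchor ADAR — are supported
as a generic `(offset, bases, type)` mechanism rather than a fixed catalogue
of variants.

Unpaired poly(AC) linkers are appended at one or both guide ends; the repeat
starts with A ("ACAC…") and is truncated to exactly the requested length.
Empirically one-ended linkers outperform two-ended ones and ~30 nt is a good
default length, but both are left as parameters. The cassette assembly order
is Twister P3 U2A, 5' ligation stem, guide, 3' ligation stem, Twister P1;
the shipped part sequences are *synthetic placeholders* (the real ribozyme
and stem sequences are construct-specific) and must be replaced for any
wet-lab use. Guides are emitted in RNA alphabet, cassettes in DNA alphabet.

## Amplicon quantification and the noise threshold

Reads from a targeted amplicon are placed by a deterministic ungapped offset
scan against the known reference, in both orientations, keeping the
placement with the highest identity over the overlap (ties: smaller offset,
then forward strand). An ungapped scan is appropriate here because amplicon
reads are near-exact copies of a short known sequence; it is deterministic
and has no external dependency. Reads under 80% identity (default) are
discarded and counted. Externally aligned data can enter through
`pileup_matrix()` (a count table) or `pileup_from_bam()`; deletions in reads
count toward depth but never as substitutions.

Editing at a site is the fraction of G reads at a reference A. To decide
which frequencies are signal, the *noise threshold* pools the per-site
frequency of every substitution class **except** A>G across all positions
with depth ≥ `min_depth` (default 50, harmonized with the
transcriptome-wide depth filter) and sets the cutoff at mean + k·SD of that
empirical noise. The published rule is stated as "mean +/− SD"; we read it
as mean **plus** one sample SD, since subtracting would loosen the test, and
expose `k` (default 1) for sensitivity analyses. The threshold is computed
per amplicon (not pooled across samples); whether the original analysis
pooled is not stated, so the more conservative per-amplicon choice is the
default and a threshold computed elsewhere can always be passed in. With a
control sample, sites exceeding the threshold in *both* control and treated
pileups are vetoed as SNP/germline-like variants rather than edits.

Codon consequences (`codon_effect()`) apply A>G inside the affected codon
under the standard genetic code: the canonical therapeutic case is a
premature stop TAG edited at its middle position to TGG (tryptophan), a
stop-loss.

## Differential editing and off-target candidates

Input is a long-format table of ref/alt counts per site × group ×
replicate. The cascade is:

1. **Filter** (`filter_sites()`): drop sites with fewer than 50 total reads
   across all replicates of both groups, then sites whose *pooled* editing
   level stays below 5% in every group. The 5% rule is evaluated on pooled
   (replicate-summed) levels; per-replicate evaluation is a defensible
   alternative, but pooling matches the replicate-combining used for
   testing, so one convention governs both steps.
2. **Test** (`fisher_differential()`): replicate counts are pooled per group
   ("combining the data from replicates"); each site's 2×2 table (ref/alt ×
   control/treatment) gets a two-sided Fisher exact test (two-sided because
   editing can move in either direction); BH adjustment is applied across
   the sites actually tested — filtering precedes testing, so the multiplicity
   burden is the tested set. A site is *differential* iff adjusted p < 0.01
   **and** |Δ| > 10 percentage points of editing level.
3. **Novel sites** (`novel_site_candidates()`): candidate off-targets must
   reach the 5% detection level in *every* treatment replicate and in *no*
   control replicate — the consistency rule that separates reproducible
   treatment-only sites from replicate noise.
4. **Homology screen** (`homology_screen()`): a candidate is
   sequence-dependent only if the guide could plausibly pair there. We score
   the best local alignment of the guide against the reverse complement of
   the ±100-nt window (match +1, mismatch −1, linear gap −2) and compare it
   with an empirical null: the same score on composition-preserving shuffles
   of the window (default 200 shuffles, cutoff at their 99th percentile,
   fixed internal seed so the cutoff is reproducible). Local alignment with
   an empirical null replaces thermodynamic folding deliberately: it is
   deterministic, dependency-free, and the conclusion it supports
   (duplex / no plausible duplex) is qualitative; a folding-based score can
   be substituted upstream of the boolean if desired.

Ties in the BH ordering are resolved by site id so output order is
reproducible; a site with a zero-depth group is excluded with an explicit
reason rather than propagating NaN.

## Alu Editing Index

The AEI summarizes global ADAR activity as the depth-weighted A>G mismatch
rate over expressed Alu repeats: at every position of the (merged) Alu
intervals carrying the strand-appropriate reference base — A on `+`
intervals, T on `-` intervals where editing appears as C in sense space —
pool edited reads and total reads, and report `100 * edited / total`. This
is intentionally a *simplified* index: strand comes from the interval
annotation only (no expression-based strand inference), and known SNP
positions can be masked via a BED-style table (no mask means no exclusion).
Two properties pin the implementation down: strand-mirroring a dataset
leaves the index unchanged, and the pooled index equals the depth-weighted
mean of per-interval indices.

## Assay scalars

The RNAscope H-score weights the percentage of cells in five dot-density
bins by the bin index, `0·p0 + 1·p1 + 2·p2 + 3·p3 + 4·p4`, giving 0–400;
bin membership cut-points are taken as given (image analysis is out of
scope). qPCR absolute quantification fits Cq against log10(copies) by OLS;
amplification efficiency is `10^(−1/slope) − 1` (slope −3.32 ⇒ 100%), and
sample copies are `10^((Cq − intercept)/slope)` with technical replicates
averaged (SD reported) and out-of-range Cq flagged as extrapolated rather
than refused.

## What the simulators emulate — and what they do not

`simulate_amplicon_reads()` draws, per read, independent Bernoulli edits at
each declared site and then a uniform strand-symmetric per-base error
(default rate 0.1–0.5% range typical of amplicon sequencing; the error model
is uniform because no finer model is warranted by the data the pipeline
sees). `simulate_count_tables()` draws per-replicate depth from a negative
binomial (mean 200, size 10 — RNA-seq-like overdispersion) and alt counts
binomially; null sites share one Beta(2, 18) editing level (mean 10%,
typical of native A-to-I sites that survive depth filtering) across groups,
and effect sites add a fixed Δ in treatment. `simulate_alu_pileups()` makes
every interval position an editable site at a constant level.

These generators reproduce the *statistical* structure the estimators
assume — binomial sampling at known depth, replicate exchangeability,
strand mirroring — so passing tests demonstrate estimator correctness,
calibration of the null (≈0 differential calls on 20,000 null sites) and
power (recall ≥ 0.9 at Δ = 0.3, 200× coverage). They do not emulate PCR
duplicates, quality-score structure, splicing, alignment ambiguity, or
correlated errors, so they say nothing about upstream read processing on
real data. All generators are pure functions of (parameters, seed), restore
the caller's RNG state, and emit truth tables consumed by the tests.

## Numerical and scale choices

* Fisher tests run with `conf.int = FALSE`; p-values are exact, only the
  odds-ratio CI is skipped.
* The test suite verifies Fisher p-values against exhaustive hypergeometric
  enumeration for **all** 2×2 tables with row margins ≤ 30, using the
  p-preserving table symmetries to avoid redundant calls (and separately
  spot-checking those symmetries on the implementation).
* Calibration/power suites run at 20,000 null sites and 2,000 sites with
  100 effects respectively; amplicon recovery uses 5,000 reads; the AEI
  check uses 500 positions per strand at depth 100. These sizes make
  sampling error comfortably smaller than the assertion bands while keeping
  the default suite fast.
* Sample (n−1) standard deviations throughout.

## Known limitations

* The ungapped aligner is for amplicons only; indel-rich data should be
  aligned externally and imported.
* The duplex screen's score is not a free energy; borderline candidates
  deserve a folding follow-up.
* The AEI here is not a drop-in reimplementation of genome-scale AEI
  tooling (no expression-based strand inference, no genome download); it is
  meant for comparing conditions within one study.
* Placeholder cassette parts must be replaced with real ribozyme/stem
  sequences before synthesis.
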