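---
title: "Detecting small segmental duplications from pseudoheterozygous sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting small segmental duplications from pseudoheterozygous sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phsdup)
```

## The signal: pseudoheterozygosity

A haploid genome has one allele per site, so a confident heterozygous call in
haploid resequencing data is a contradiction — unless the "site" is really two
sites. When a genomic segment is duplicated in the sequenced individual but
present only once in the reference assembly, reads from both copies are forced
onto the single reference locus. Every position where the copies have diverged
then shows two alleles at roughly balanced depth: a *pseudoheterozygous site*
(PHS). Runs of linked PHS mark recent segmental duplications — including
interspersed duplications whose breakpoints short reads cannot place, because
the duplicate copy is absent from the reference and all of its reads pile onto
the source locus.

This package implements the full inference path from per-site pileup summaries
to population-genetic conclusions, and ships a synthetic-data generator so
that every stage can be validated against a known truth set.

## PHS calling

`call_candidate_sites()` keeps pileup columns with exactly two observed
alleles. Columns with three or more alleles are discarded outright: a true
two-copy duplication produces two alleles, and anything beyond that signals
sequencing error or collapsed higher-copy repeats outside this model.
`filter_phs()` then applies the filter battery:

* **allele support** — each allele needs at least 5 reads that carry base
  quality ≥ Q25 *and* place the site at least 15 bp from both read ends.
  Only such qualified observations count toward support; read-end positions
  are where alignment artifacts concentrate.
* **depth** — total column depth strictly greater than 8 reads, counting all
  reads. Whether the depth cutoff should also be quality-restricted is not
  decidable from the definition of the filters; counting all reads is the
  looser and simpler reading, and support is already quality-restricted.
* **masks** (`build_masks()`) — homopolymer runs of ≥ 6 identical bases (the
  run itself, no flank, since the rule speaks of sites *within* the run);
  repeat positions, defined as start positions of 30-mers occurring more than
  once in the reference — a deterministic, exactly testable stand-in for
  remapping-based multi-mapping detection; and indels with genotype quality
  > 30 and > 5 supporting reads, extended 5 bp to both sides.

All thresholds are strict inequalities where the rule says "larger than", and
every one of them is an argument with the canonical value as default.

## Independent duplication evidence

Two detectors corroborate PHS calls without using PHS at all.

**Read depth.** `compute_depth_profile()` divides each 200-bp window's depth
by the genome-wide mean to give a copy-number proxy (haploid baseline 1).
The mean excludes repeat-masked windows and is recalibrated by iteratively
dropping windows more than 3 SD from the running mean until convergence.
This recalibration matters: duplicated windows sit in the tail, and without
excluding them the baseline is inflated by the very signal being measured, so
every ratio is biased low — for strictly two-copy events the expected ratio
would fall below the detection threshold instead of sitting at 2.
`call_high_copy_regions()` emits maximal runs of windows with ratio > 1.25
containing at least one window with ratio > 2. Both cut-offs are strict; for
a two-copy region the expected peak ratio is exactly 2, so single-window
two-copy events are detected at roughly the noise-crossing rate — a genuine
limit of the rule, visible in the class-accuracy numbers below.

**Split reads.** A read spanning a tandem-duplication junction maps as two
fragments in reverse order; clusters of such reads define the breakpoints.
`call_tandem_duplications()` keeps clusters whose score
$S_1 = (n_+ + 1)(n_- + 1)$ strictly exceeds 15, which demands either balanced
support on both strands or very high one-strand support, guarding against
strand-biased artifacts.

**qPCR.** `qpcr_copy_number()` implements relative quantification:
$\Delta Ct$ against a single-copy reference fragment,
$\Delta\Delta Ct$ against a single-copy calibrator strain, copy number
$2^{\Delta\Delta Ct}$, duplication flag strictly above $2^{0.5} \approx 1.41$
(a two-fold change detected at half confidence). The placement of the
z-normalisation of $\Delta\Delta Ct$ is ambiguous in standard protocols;
the default applies the threshold to the raw fold change and reports z-scores
alongside, and `z_normalize = TRUE` switches the threshold to $2^{z}$.

## From PHS to duplication calls

`merge_phs()` chains PHS within 400 bp into one *PHS duplication* per genome
(single-linkage; the call spans its first to last PHS). The 400-bp gap is the
point where call counts stop changing appreciably over the 100–600-bp range,
which the merge-gap monotonicity property makes testable.
`classify_duplications()` labels a call `high_copy` or `tandem` when more
than 50% of its span overlaps the respective evidence, `both` for both and
`undetermined` otherwise. The 50% rule is stated for high-copy evidence; we
apply the same rule to tandem evidence for uniformity. The call span (not the
unknown true extent) is the denominator, because interspersed breakpoints are
unobservable.

`collate_population()` unions calls across genomes into population events
when they share at least one PHS position — the most conservative testable
identity; any-overlap identity is available via `identity = "overlap"`.
Event frequency is the carrier count, and member-call evidence is pooled: an
event counts as tandem or high-copy when any carrier shows that evidence,
since evidence in one genome validates the shared event.

## Frequency-spectrum statistics

Under the standard neutral model, the expected number of variants carried by
$i$ of $n$ genomes is proportional to $1/i$, so with $S$ events the expected
singleton count is $S/a_n$ with $a_n = \sum_{i=1}^{n-1} 1/i$
(`neutral_expectation()`). For $S = 2282$ events in 29 genomes that is
$2282/a_{29} \approx 581$ singletons and 1701 nonsingletons — an excess of
observed singletons beyond this is the signature of deleterious mutations
kept rare by purifying selection. `singleton_excess_test()` is the 1-df
Pearson chi-square (no continuity correction; the counts involved are large)
of the observed split against that expectation. `proportion_test()` wraps the
two-sided Fisher exact test; `false_positive_estimate()` converts a singleton
surplus in unvalidated calls into a false-positive fraction;
`diversity()` computes $\pi$ and Watterson's $\theta_W = S/(aL)$.

## Annotation and functional-element depletion

`assign_regions()` labels sites or calls CDS > 5'UTR > 3'UTR > intron >
intergenic when transcripts overlap — coding impact dominates interpretation,
and the ordering is the only decision; any fixed priority keeps the partition
property. `region_chi_square()` tests each region's count against a
length-proportional expectation (mappability correction is out of scope; the
expectation basis is a stated assumption). `permutation_enrichment()` draws,
10,000 times by default, one length-matched random fragment per observed call
and counts track overlaps (≥ 1 bp); the empirical p uses the add-one formula
$(1 + k)/(N + 1)$, so it is never zero and its floor is $1/(N+1)$ — 0.001 at
$N = 1000$, which is why permutation p-values bottom out there. Two-sided
p-values double the smaller tail, capped at 1. `age_group_trend()` stacks
these ratios into a tracks-by-age-groups matrix and runs a sign test per
group (H0: median ratio 1), a Friedman test across groups and pairwise
Bonferroni-corrected Wilcoxon signed-rank tests. Both one- and two-sided sign
p-values are reported since directionality is an interpretive choice.

## Paralog divergence

`reconstruct_paralogs()` materialises the two copies of a call: copy A takes
`allele1`, copy B `allele2` at every PHS, reference elsewhere. Phase is
arbitrary; substitution counting is phase-invariant. `dn_ds()` implements
Nei–Gojobori (1986) counting: fractional synonymous/nonsynonymous site counts
per codon averaged over both sequences (so $N + S = 3 \times$ codons
exactly), per-codon differences averaged with equal weights over all minimal
mutational pathways (pathways through stop codons excluded unless none
remain), Jukes–Cantor correction of both proportions. Counting was chosen
over maximum-likelihood codon models deliberately: PHS-derived pairs differ
at a handful of sites, a regime where counting and ML agree closely and the
multi-parameter ML machinery adds nothing but an external dependency. Pairs
with $d_S = 0, d_N > 0$ carry an undefined-ratio flag and form their own
reporting category; they are excluded from ratio-based sign tests
(`compare_paralog_ortholog()`). `filter_homology_hits()` applies the strict
cross-species homology rule (identity > 90%, aligned length > 50% of query)
and calls a query duplicated in the subject genome when two or more
non-overlapping qualifying loci exist.

## The synthetic-data generator

`simulate_population()` emulates a haploid-embryo resequencing study:

* **population** — 29 haploid genomes; duplications carry no reference copy
  of their second paralog, which is the PHS-generating configuration.
* **sizes** — log-normal(meanlog 5.2446, sdlog 1), clamped to 50–5000 bp.
  The parameters were solved analytically so that 83.4% of draws are < 500 bp;
  the same distribution then puts 11.8% in 500 bp–1 kb and 4.8% above 1 kb,
  matching the small-duplication regime this method targets.
* **frequencies** — carrier counts $\propto 1/i$ (neutral) or mixed with a
  singleton point mass of weight 0.63, the weight at which the expected
  singleton fraction equals the observed 72.6% in the motivating data.
* **divergence** — uniform per-site substitution between copies at 1% by
  default (binomially distributed per event). The true per-event divergence
  distribution is unknown; uniformity is a modelling choice, not an
  inference.
* **reads** — 73-bp effective reads at 30× haploid depth, base qualities
  uniform Q25–Q40 (so the Q25 filter boundary is exercised by tests that
  lower the range), per-base error 5×10⁻⁴.
* **tracks, not FASTQ** — pileup columns are emitted directly at informative
  positions (divergent sites of carried events and error-hit positions),
  split-read clusters at tandem junctions (support Poisson with rate
  `depth × (read_length − 20)/read_length`, i.e. reads with ≥ 10 bp on each
  side of the junction; strand split Binomial(1/2)), and window depths with
  the read-sampling noise of a Poisson read count per window. Mapping
  itself is out of scope, and skipping it isolates the package's own
  computation from aligner behaviour.
* **placement** — events are placed non-overlapping with ≥ 600 bp
  separation, so that distinct events remain distinguishable under 400-bp
  merging; heavily clustered duplication blocks are exactly what the
  exclusion stage removes in real analyses.

What the generator does *not* emulate: mapping ambiguity and mapping-quality
filtering, GC- and context-dependent coverage bias, indel errors beyond
isolated mask-test records, linked selection and demography, and duplications
above two copies. Passing end-to-end tests therefore demonstrates the
correctness and calibration of the decision rules under idealised mapping,
not robustness to real-world mapping artifacts.

## Numerical and scale choices

Internal coordinates are 1-based closed (the IRanges convention) everywhere;
conversion to 0-based half-open happens only at BED boundaries. Allele order
in a candidate is by read count with alphabetical tie-break. The default
test-scale scenario uses a 300-kb reference with 13 duplications carried per
genome — a deliberately compressed genome with elevated duplication density,
sized so the whole pipeline runs in well under a minute while leaving ~100
population events (~60 of them ≥ 200 bp) for recovery scoring; the
divergence, depth, read-length and frequency parameters are the study-scale
values, not compressed. At these settings the pipeline recovers in excess of
90% of events ≥ 200 bp. Classification accuracy sits near 75–90%: tandem
events are nearly always labelled correctly (split-read support is strong at
30×), while strictly two-copy interspersed events face the knife-edge of the
strict > 2× peak rule discussed above, exactly as the undetermined fraction
in real data reflects read-depth misses.

## Known limitations

* Interspersed duplications get no breakpoints, only source-locus spans.
* Events with fewer than one divergent site in their span are invisible to
  PHS calling by construction; sensitivity at 1% divergence falls off below
  ~200 bp.
* The strict > 2× rule under-detects two-copy regions whose span covers no
  complete window; higher-copy events do not suffer from this.
* The repeat mask's exact 30-mer rule is blind to near-identical repeats
  that a remapping-based definition would catch.
* The chi-square singleton test assumes independent events; linked events
  violate this mildly in dense regions.
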