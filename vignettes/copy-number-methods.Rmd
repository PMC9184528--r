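---
title: "Models and methods for paralog-specific copy number estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for paralog-specific copy number estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paracn)
```

## The problem

Low-copy repeats (segmental duplications) are stretches of the genome
present in two or more near-identical copies. Short reads from these
regions map ambiguously between copies, so ordinary depth-based CNV
callers mis-estimate copy number there, and variant callers confuse
paralogous sequence variants (PSVs — the few positions where the
reference copies differ) with real polymorphism.

`paracn` estimates two quantities for a duplicated locus from
whole-genome sequencing of a cohort:

* **Aggregate copy number** (aggregate CN): the total number of copies
  over all paralogs, per sample. A locus duplicated once in the
  reference has reference copy number $c_r = 4$ (two copies times two
  haplotypes).
* **Paralog-specific copy number** (paralog CN): the integer tuple
  $t = (t_1, \dots, t_{c_r/2})$, one entry per repeat copy, with
  $\sum_k t_k = c_s$ the sample's aggregate CN.

Instead of trying to resolve each read's copy of origin, reads from all
copies are **pooled** onto the primary copy through precomputed
alignments, which makes aggregate depth a clean, mapping-unambiguous
signal. Copy-of-origin information is then recovered separately, from
allele counts at PSVs.

## Homology table and PSVs

Pairwise self-alignment records of the reference (PAF or SAM with
CIGARs) are filtered by length (default ≥ 500 bp) and similarity
(default ≥ 0.97, matching columns over aligned columns) into a
*homology table*. Sequences taking part in more than 10 pairwise
alignments behave like interspersed repeats rather than low-copy
repeats; their records are flagged `tangled` and excluded from
copy-number analysis, but kept in the table so queries can warn.

Throughout the package, the stored CIGAR treats **region1 as the
reference side**: `D` consumes region1 only (bases absent from the other
copy), `I` consumes region2 only. This is the convention under which
coordinate projection (`project_position()`) walks region1 left to
right; PAF `cg:` tags are converted on input. PSVs are maximal runs of
non-matching alignment columns; indel PSVs are anchored at the preceding
matched base (VCF-style), so applying all PSV alleles of a duplication
to the region1 sequence reconstructs region2 exactly — a property the
test suite exercises as a round trip.

## Background depth model

Depth in unique (copy-number 2) sequence is tabulated in fixed 100 bp
windows; each read pair counts once, in the window containing the center
of its first-in-genome read. Windows with ≥ 10% low-MAPQ (< 10),
improperly paired, or soft-clipped reads are *irregular* and excluded.
Candidate windows keep a 500 bp buffer from every duplication in the
table, and windows with extreme GC (≤ 35% or ≥ 55%) may be recruited
from a 5 kb neighborhood of the core region set because they are
otherwise scarce.

Per sample and per GC percentage, counts are modeled as negative
binomial (NB). The mean is profiled — `prob = size / (size + mean)`
pins the fitted mean to the empirical mean — and the likelihood is
maximized over `log(size)` by 1-D search. If the empirical variance does
not exceed the mean, the fit falls back to a Poisson limit (`size` =
1e6, mean matched). GC values with fewer than 100 regular windows borrow
strength: log-mean interpolated linearly between fitted neighbors,
dispersion from the nearest fitted value.

## The aggregate copy-number HMM

For a region group (segments of equal reference copy number separated by
gaps < 2 kb), pooled counts $o_w^{(s)}$ over windows $w$ and samples $s$
feed a hidden Markov model whose states are candidate integer aggregate
CNs. The emission for state $c$ scales the sample's background NB by the
copy number:

$$b_w^{(s)}(c) = \mathrm{NB}\!\left(o_w^{(s)};\; n_w^{(s)} \cdot \tfrac{c}{2} \cdot m_w,\; p_w^{(s)}\right),$$

with $(n, p)$ the background parameters at the window's GC and $m_w$ a
shared per-window scale factor absorbing residual window biases.
Transitions between adjacent windows use two jump parameters per
boundary, $a^\nearrow_w, a^\searrow_w \in [0, 1/10]$: the probability of
jumping up by $d$ states is $(a^\nearrow_w)^d$, down by $d$ is
$(a^\searrow_w)^d$, and the diagonal takes the remainder. Both start at
$10^{-5}$.

Choices the package makes where the procedure was open:

* **State set.** A contiguous integer range covering
  $\mathrm{round}(2\,\bar o/\bar e) \pm 1$ over all samples
  (trimmed-mean normalized depth), intersected with
  $[0, c_r + 6]$ and always containing $c_r$.
* **Initial distribution.** The natural "rare non-reference" prior
  $\pi_{\neg ref} = 1/S$ per non-reference state does not leave a valid
  remainder for the reference state when written as $1 - K/S$; the
  package uses $\pi_{ref} = 1 - (K-1)/S$, floored and renormalized.
* **Zero-copy emission.** NB with size 0 is degenerate; state 0 emits a
  mixture $0.99\,\delta_0 + 0.01\,\mathrm{Geom}(1/2)$ so a few mismapped
  reads do not zero out the likelihood.
* **Iteration.** Forward–backward per sample, then joint updates: $m_w$
  by bounded 1-D maximization of the posterior-weighted NB
  log-likelihood (bounds $[0.1, 10]$); jump parameters by per-boundary
  maximum likelihood on pooled expected transition counts (jump distance
  weights the log-parameter), clamped to $[10^{-6}, 0.1]$; the initial
  distribution from pooled first-window posteriors with a $1/(10S)$
  floor. Iterate until the total log-likelihood improves by < 0.01 or
  30 iterations.
* **Boundary consolidation.** The geometric parametrization spreads
  elevated jump parameters over neighboring boundaries while the fit
  bootstraps, yet a shared deletion or duplication has a single
  breakpoint. After convergence, a *neutral* forward–backward pass
  (uniform jump parameters $10^{-3}$) collects per-sample boundary
  posteriors; within each cluster of elevated boundaries the consensus
  breakpoint maximizes the shared-breakpoint likelihood — the sum over
  jumping samples of log boundary-posterior — and all other boundaries
  return to the floor. A few constrained iterations then re-estimate the
  kept boundaries, concentrating the full jump mass on them. Two shared
  events with breakpoints within two windows of each other would be
  merged; that is below the resolution this window size offers anyway.
* **Decoding and quality.** Viterbi per sample; a segment's Phred
  quality is $-10\log_{10}(1 - \min_w \gamma_{\hat c, w})$ over its
  windows, capped at 100. Calls with quality ≥ 20 are treated as high
  quality downstream.

Frozen-parameter mode (`run_single_sample()`) replays one
forward–backward and Viterbi pass for a new sample using the stored
$\pi$, jump parameters, $m_w$, state set and window layout; training
samples decode to bit-identical paths.

### Detection power

At 30× PCR-free coverage, 100 bp windows hold about 10 read pairs at
copy number 2. A one-copy deletion on a four-copy background (CN 4 → 3)
then carries roughly 0.5–0.7 nats of evidence per window, so a 20-window
event yields ~10–14 nats against an entry-plus-exit transition cost of
~23 nats at the initial parameters. Detection therefore relies on the
joint fit: carriers sharing a breakpoint raise the local jump
parameters, which lowers the cost for every carrier. This works reliably
at the cohort scales the package targets (tens of carriers per hundred
samples), but individual carriers whose depth realization happens to be
uninformative (it happens: the per-sample evidence has a standard
deviation of ~5 nats) can remain undetected — the same samples would be
missed by an oracle decoder. Whole-copy deletions (CN 4 → 2) are
essentially always recovered.

## Paralog-specific copy number by EM

Given aggregate CN calls, allele counts at PSVs carry the
copy-of-origin signal. The population frequency of copy $k$'s reference
allele at PSV $v$ is $f_{vk} \in [0,1]$; a PSV is **reliable** when
$\min_k f_{vk} \ge 0.95$, i.e. its alleles mark their copies in nearly
every chromosome.

`em_fit()` runs EM over the samples whose aggregate CN equals $c_r$
(minimum 50), with the per-sample tuples hidden and $f$ unknown. Two
modeling points matter:

* **Carriage is latent and quantized.** Each chromosome of copy $j$
  carries copy $j$'s allele with probability $f_{vj}$, otherwise one of
  the other copies' alleles (uniformly). A sample's allele fraction at a
  PSV is therefore not the marginal mixture value but one of a few
  quantized levels set by which chromosomes carry what. The likelihood
  marginalizes this exactly: per-copy multinomial carriage draws are
  convolved into a distribution over allele-count compositions, and
  reads follow a multinomial on top with error mass
  $\varepsilon = 0.01$ diverted to "other". A marginal-fraction
  multinomial (ignoring carriage) is badly misspecified here — it lets a
  degenerate mode with $f \approx 0.5$ and per-sample tuple freedom fit
  the quantization noise better than the truth by hundreds of nats.
  `allele_prob()` exposes the read-level marginal of this model, which
  is what the counts converge to at high depth.
* **A reference-biased tuple prior.** With $f$ free, "all samples at
  the even split with marker-like $f$" and "all samples concentrated on
  one copy with $f$ near 0.5" are likelihood-equivalent. The prior
  places weight 0.5 on the even split at $c_s = c_r$ (remainder
  uniform), resolving the label degeneracy toward the biologically
  expected mode, in line with the HMM's reference-biased initial
  distribution. The same prior is used when genotyping individual
  samples.

The M-step updates each $f_{vk}$ by bounded 1-D search on the expected
complete-data log-likelihood, accepting a move only if it improves the
objective, so the observed-data log-likelihood never decreases (the
suite asserts this on every run). Multi-modality is handled by restarts:
a deterministic $f = 0.9$ start plus five seeded draws from
$U(0.5, 1)$, keeping the best final likelihood.

Individual samples are genotyped by the E-step over
`enumerate_tuples(c_r, c_s)` using **reliable PSVs only** (at least 3
covered), with per-copy qualities from the marginal posterior. Loci with
$c_r > 8$ or more than 500 tuples are skipped, as are samples with
low-quality aggregate CN.

### Estimation precision

At 100 reference-CN samples, each copy contributes ~200 chromosome
draws per PSV, so $\hat f$ has a standard error of ~0.012 near
$f = 0.97$ and the reliability call for such near-threshold PSVs flips
in roughly 4% of simulations — classification is statistically exact
only for PSVs well away from the 0.95 threshold. Pairs of mid-range
frequencies (e.g. $f = (0.5, 0.5)$) sit on a likelihood ridge (only the
carriage sum is well identified) and carry errors up to ~0.1–0.2; such
PSVs are reliably *classified* (far below 0.95) but not precisely
*estimated*. Loci dominated by them are the ones the caller skips on
real data.

## Trio concordance

Population frequencies of *haploid* paralog CN tuples are deconvolved
from diploid calls (quality ≥ 20, at least 20 calls) under random
mating: each diploid tuple is the sum of two independent haploid draws,
and the mixture weights are fitted by EM. The EM initializes from the
most balanced split of each observed diploid with a uniform floor — a
uniform start can stall on a symmetric stationary point — and its
log-likelihood is non-decreasing. Note that not every empirical diploid
distribution is a convolution square; the fit is the closest
random-mating law.

For a trio, each parent's call is decomposed into haploid pairs weighted
by the fitted frequencies (Bayes, conditioned on the parent's diploid
call); each parent transmits either haploid with probability 1/2, and
the reported probability is the transmission mass landing exactly on the
child's tuple. A trio is discordant when this probability falls below
0.01. Children are genotyped independently of their parents.

## What the simulator emulates

All validation runs on simulator output; its defaults are the study
conditions the package targets:

* **Depth**: 10 read pairs per 100 bp window at copy number 2 — 30×
  coverage with 150 bp paired reads — with NB dispersion `size = 30`
  (variance/mean ≈ 1.33), the PCR-free regime of modern population
  cohorts. PCR-based libraries are substantially more overdispersed and
  correspondingly less informative per window.
* **GC bias**: a smooth unimodal multiplier over GC 20–80% (strength
  0.3), mirroring the shape of real depth-vs-GC curves without modeling
  any specific chemistry.
* **PSV frequencies**: entries drawn from {1.0, 0.97, 0.5} with weights
  0.80/0.15/0.05, emulating loci amenable to paralog-specific
  genotyping, where the large majority of PSVs are reliable markers.
* **Genomes**: single-contig toys with 2–4 planted copies, exact
  alignment records, and known PSVs, so table construction and PSV
  extraction can be checked for exact recovery.

What it does **not** emulate — and hence what passing tests do not show
about real data: mapping ambiguity and alignment artifacts between
copies (real pooled counts inherit aligner behavior at copy-distinct
positions), index hopping and duplicate reads, gene conversion and
hybrid alleles (paralog CN is assumed constant across a
constant-aggregate-CN segment), population structure in PSV
frequencies, and reference errors such as missing copies.

## Problem sizes and runtime

The package's own validation uses cohorts of 100 samples × 60 windows
for the HMM, 100 samples × 20 PSVs for the EM, and 500 trios — sizes at
which the whole suite, including the end-to-end checks, completes in a
few minutes on one core. The same code paths run unchanged on larger
cohorts; the per-iteration costs are linear in samples and windows
(HMM) and in samples, PSVs and tuples (EM).
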