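# paracn

Aggregate and paralog-specific copy number of low-copy repeats
(segmental duplications) from short-read whole-genome sequencing.

Low-copy repeats hold hundreds of disease-relevant genes (*SMN1/2*,
*C4A/B*, *FCGR3A/B*, *RHCE/RHD*, ...) whose copies are so similar that
short reads map ambiguously between them, defeating ordinary depth-based
CNV callers and variant callers alike. `paracn` is for researchers who
need integer copy numbers — both the total over all copies and the
per-copy breakdown — for such loci across a sequenced cohort.

## The method in brief

Reads from all repeat copies are pooled onto one primary copy through
precomputed pairwise alignments (a *homology table*), turning depth into
a mapping-unambiguous signal for the **aggregate copy number**
$c_s = \sum_k t_k$. Per 100 bp window $w$ and sample $s$, pooled counts
$o_w^{(s)}$ enter a multi-sample HMM over integer CN states $c$ with
negative binomial emissions scaled by copy number,

$$b_w^{(s)}(c) = \mathrm{NB}\!\left(o_w^{(s)};\; n_w^{(s)}\tfrac{c}{2} m_w,\; p_w^{(s)}\right),$$

where $(n_w^{(s)}, p_w^{(s)})$ are per-sample, GC-stratified background
(diploid) parameters and $m_w$ a shared window scale. Adjacent windows
are linked by geometric jump probabilities
$a_{ij} = (a^\nearrow_w)^{\,j-i}$ (and $a^\searrow_w$ downward), fitted
jointly across samples so that shared deletion/duplication breakpoints
become cheap exactly where carriers agree. Viterbi decoding yields
per-sample segments with Phred qualities.

The **paralog-specific copy number** tuple
$t = (t_1, \dots, t_{c_r/2})$ is then estimated from allele counts at
paralogous sequence variants (PSVs). An EM algorithm over samples at the
reference copy number jointly estimates the population frequency
$f_{vk}$ of each PSV allele on each copy and the hidden tuples; PSVs
with $\min_k f_{vk} \ge 0.95$ are *reliable* copy markers, and only
those are used to genotype individual samples. Trio data are checked by
deconvolving haploid tuple frequencies from the diploid calls and
computing the Mendelian transmission probability of each child's call
(discordant below 0.01).

A bundled simulator generates toy genomes with planted PSVs, depth
matrices, PSV allele counts and trios, so the entire pipeline runs and
is tested without any external data.

## Worked example

One hundred samples at reference copy number 4 (a two-copy
duplication), ten of which carry a heterozygous 2 kb deletion of one
copy (aggregate CN 3 over windows 21–40):

```r
library(paracn)
library(dplyr)

cn <- matrix(4L, 60, 100)            # 60 windows x 100 samples
for (s in 1:10) cn[21:40, s] <- 3L   # ten carriers
sim <- sim_depth(seed = 1, cn, ref_cn = 4)
nb  <- sim_nb_model(mu = 10, size = 30, gc_bias_strength = 0.3)
nbs <- setNames(rep(list(nb), 100), colnames(sim$depth$counts))

fit <- run_multi_sample(sim$depth, nbs)
glance(fit)
#> # A tibble: 1 × 6
#>   n_samples n_windows n_states  loglik iterations converged
#>       <int>     <int>    <int>   <dbl>      <int> <lgl>
#> 1       100        60        4 -18353.         16 TRUE

tidy(fit) |> filter(agg_cn != 4, quality >= 20)
#> # A tibble: 7 × 7
#>   sample contig start   end agg_cn quality n_windows
#>   <chr>  <chr>  <int> <int>  <int>   <dbl>     <int>
#> 1 s001   sim1    2000  4000      3    22.7        20
#> 2 s003   sim1    2000  4000      3    23.9        20
#> 3 s005   sim1    2000  4000      3    22.6        20
#> 4 s006   sim1    2000  4000      3    32.9        20
#> 5 s008   sim1    2000  4000      3    31.2        20
#> 6 s009   sim1    2000  4000      3    24.8        20
#> 7 s010   sim1    2000  4000      3    23.3        20
```

Every confidently called event is a carrier with the exact simulated
extent `[2000, 4000)`; the remaining three carriers are detected below
the quality-20 threshold, and no non-carrier is called. `autoplot(fit,
nb_models = nbs)` draws normalized depth with the decoded profiles.

Paralog-specific genotyping picks up from there: fit the PSV frequency
matrix on the cohort and genotype a 3-copy sample from its allele
counts at reliable PSVs:

```r
f_true <- sim_f_matrix(5, n_psvs = 8)
counts <- sim_psv_counts(5, f_true, rep(list(c(2L, 2L)), 60), depth = 30)
em <- em_fit(counts, c_r = 4, min_samples = 50, n_restarts = 1, seed = 5)
glance(em)
#> # A tibble: 1 × 7
#>     c_r n_samples n_psvs n_reliable  loglik iterations skip
#>   <int>     <int>  <int>      <int>   <dbl>      <int> <chr>
#> 1     4        60      8          7 -10553.          4 <NA>

new <- sim_psv_counts(6, f_true, list(c(2L, 1L)), depth = 30, samples = "NA12878")
genotype_sample(new, tibble::tibble(sample = "NA12878", agg_cn = 3L), em)
#> # A tibble: 2 × 8
#>   sample   copy paralog_cn quality tuple posterior agg_cn skip
#>   <chr>   <int>      <int>   <dbl> <chr>     <dbl>  <int> <chr>
#> 1 NA12878     1          2     100 2,1       1.000      3 <NA>
#> 2 NA12878     2          1     100 2,1       1.000      3 <NA>
```

The sample's three copies split 2/1 across the two paralogs, recovered
with full posterior confidence.

A thin command-line wrapper ships in `exec/paracn` (subcommands
`table`, `sim`, `cn`, `cn-using`, `trio`); `run_pipeline()` orchestrates
the stages programmatically. See the vignette
(`vignettes/copy-number-methods.Rmd`) for the models, their assumptions
and the numerical choices.

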