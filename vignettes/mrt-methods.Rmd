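---
title: "Methods: mutation rate and selection inference for the mortal-germline phenotype"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mutation rate and selection inference for the mortal-germline phenotype}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrtline)
```

## The scientific problem

Some *Caenorhabditis elegans* lineages carry a heat-sensitive
*mortal germline* (Mrt) phenotype: propagated at the upper end of the
species' thermal range, the lineage becomes progressively sterile over a
few to a few tens of generations. The phenotype is transgenerationally
heritable and epigenetically mediated, but it has an underlying genetic
basis, and two population-genetic quantities decide how variation in it
is maintained in nature: the genome-wide rate $U$ of mutation to the
phenotype, and the frequency $\hat q$ of carriers among wild strains.
Under mutation–selection balance (MSB) in a highly selfing species the
two are linked through the strength of selection $s$ against carriers,

$$\hat q \;\approx\; \frac{U}{s},$$

so measuring $U$ (from mutation-accumulation lines) and $\hat q$ (from a
wild-isolate panel) yields an estimate $\hat s = U/\hat q$. `mrtline`
implements that full inference chain plus the simulations and the
phylogenetic dispersion analysis that probe its assumptions.

## Phenotype classification

The assay scores replicate lineages of each line at 25°C until sterility
or the end of the assay (the *horizon*: 21 generations in the N2 MA and
wild-isolate blocks, 14 in the PB306 MA block). A line's class is decided
by threshold rules on its replicate outcomes, applied in this order of
precedence:

1. **ts_sterile** — every replicate sterile after the first generation at
   25°C. This is a classical temperature-sensitive sterile mutation, not
   Mrt kinetics, and is tallied separately.
2. **excluded_low_fitness** — a strict majority of replicates annotated
   `non_mrt_failure` (slow growth, dead worms). Such failures are not the
   Mrt-sterile phenotype; the annotation is an input, because it reflects
   visual inspection that a survival table cannot reproduce. Lines with a
   minority of such replicates are scored on their remaining replicates.
3. **strong** — mean time to sterility < 10 generations and maximum < 15.
   A censored replicate's time to sterility exceeds the horizon and hence
   15, so strong lines necessarily have every replicate sterile.
4. **moderate** — mean time to sterility < 16 and no replicate still
   fertile at generation 21.
5. **weak** — at least 2/3 of replicates sterile by generation 21. The
   published rule is "at least 2 out of 3" for the 3-replicate
   wild-isolate design; the package generalises it proportionally
   (`3 * n_sterile >= 2 * n_replicates`, in exact integer arithmetic) so
   10-replicate MA lines are scored consistently.
6. **wild_type** — everything else; in particular at least 2/3 of
   replicates fertile at generation 21.

All threshold inequalities are strict, exactly as defined; a line with
mean time to sterility of exactly 10 is not strong. The mean is taken
over replicates that actually went sterile with the Mrt-type failure;
censored and excluded replicates are counted alongside, not averaged in.
Whether the published per-line means include censored replicates at the
horizon is not stated; excluding them is this package's convention.

For 14-generation assays the moderate and weak classes are undefined
(both require generation-21 information), so classification returns only
ts_sterile/strong/wild_type and attaches a caveat attribute to the
result.

Two properties are enforced by tests: the classes partition lines
(exactly one class each), and classification is monotone — making any
replicate fail earlier, or converting a censored replicate to a failure,
never moves a line to a weaker class.

## Rate estimation

With $k$ Mrt mutations observed among $n$ MA lines propagated $t$
generations, the point estimate is $U = k/(nt)$. This is the haploid
rate: mutations arise in diploids at rate $2U$, but a new neutral
mutation in a single-descent selfing line is lost with probability 1/2
(see below), and the factors cancel. The pooled design is $n = 67$ lines
(34 N2 + 33 PB306) and $t = 250$ generations, i.e. 16,750 meioses; with
the one observed strong-Mrt mutation, $U \approx 6\times10^{-5}$ per
genome per generation.

The interval estimate is Garwood's exact Poisson interval: the bounds
solve

$$\Pr(X \ge k \mid \lambda_L) = \alpha/2, \qquad
  \Pr(X \le k \mid \lambda_U) = \alpha/2,$$

computed through the chi-square identity — $2\lambda_L$ is the
$\alpha/2$ fractile of $\chi^2_{2k}$ and $2\lambda_U$ the $1-\alpha/2$
fractile of $\chi^2_{2(k+1)}$ — and divided by the number of meioses.
For $k = 0$ the lower bound is defined as 0 (the 0-df chi-square
degenerates), which matches the one-sided use of the upper bound for
phenotypes never observed to mutate. The production path uses base R's
`qchisq`; the test suite solves the Poisson tail-sum equations directly
by root finding as an independent oracle and requires agreement to a
relative $10^{-8}$ over $k = 0,\dots,20$ at three $\alpha$ levels. The
exact interval is conservative by construction; simulation tests confirm
at least nominal coverage.

Recomputing the $k=1$, 95% interval gives
$(1.51\times10^{-6},\ 3.33\times10^{-4})$; published values that round
to $(1.53\times10^{-6},\ 3.28\times10^{-4})$ differ by 1–2%, consistent
with rounding in intermediate steps. The implementation reports its own
full-precision values and is deliberately not tuned to reproduce printed
digits.

Dividing $U$ by a per-nucleotide rate of $2.8\times10^{-9}$ per
generation gives the implied mutational target, about 21,000 sites or
0.02% of the $10^8$ bp genome (up to ~0.1% at the interval's upper
bound).

## Mutation–selection balance

`s_from_frequency()` solves $\hat q = U/s$ for $s$. With
$\hat q \approx 0.06$ (strong Mrt among 95 wild isolates) and
$U = 6\times10^{-5}$, $\hat s \approx 0.001$; for heat-sensitive
sterility (one mutation in 16,750 meioses, one carrier in 95),
$\hat s \approx 0.006$. Because phenotype classification is
conservative, a carrier count like 6/95 is a lower bound on $\hat q$ and
the derived $\hat s$ is correspondingly an upper bound;
`msb_inference()` records that one-sided reading and propagates the
exact (Clopper–Pearson) binomial interval for $\hat q$, and optionally
the rate interval for $U$, by interval arithmetic. For the $s \approx
0.001$ inference the package defaults to the rounded 0.06 used in the
headline calculation where that is asked for explicitly, but
`msb_inference()` always works from the exact fraction; both appear in
its report.

The approximation $\hat q = U/s$ is validated by the deterministic
recursion for fully selfing, homozygous lineages,

$$q' = q + U(1-q), \qquad q'' = \frac{q'(1-s)}{1 - s\,q'},$$

iterated to relative tolerance $10^{-12}$ (default cap $10^6$
iterations; non-convergence is flagged, not thrown). Its fixed point
satisfies $q^\* = (U/s - U)/(1-U)$, so the relative deviation from
$U/s$ is $O(s)$ — about 0.1% at $U = 6\times10^{-5}, s = 10^{-3}$,
where $q^\* = 0.0599$, i.e. the ~6% carrier frequency. Two boundary
facts are worth noting: $U = 0$ makes $q = 0$ absorbing, and $q_0 = 1$
is itself absorbing (mutation is irreversible and selection purely
relative, so a population with no wild-type lineage cannot leave
$q = 1$); the independence-of-$q_0$ property therefore holds on
$[0, 1)$.

The package treats the population as fully homozygous selfing lineages,
ignoring the heterozygous phase; with near-complete self-fertilisation
the heterozygote's residence time is short and the homozygous selection
coefficient is the relevant one. No dominance, partial outcrossing, or
multilocus linkage is modelled.

## Simulators

**MA transmission** (`ma_transmission`). A new mutation in an MA line is
heterozygous; each generation the single surviving selfed offspring is
homozygous mutant / heterozygous / homozygous wild type with
probabilities 1/4, 1/2, 1/4. The walk absorbs with equal probability at
fixation or loss (mean two generations), grounding the loss-probability-
1/2 cancellation. The simulator ignores the 3-L4 transfer detail of the
sterility assay: the 1/2 applies to MA-line maintenance, which is
genuinely single-individual descent. Absorption times are reported so
users can check that absorption is effectively complete within an MA
experiment's duration (it is: the absorption time is geometric with mean
2, so 250 generations is astronomically safe).

**Finite-population dynamics** (`wf_selfing`). $N$ selfing lineages,
irreversible mutation wild type → Mrt at rate $U$, then multinomial
resampling with fitness $1$ vs $1-s$. At $N = 10^5$, $U = 6\times
10^{-5}$, $s = 10^{-3}$ the time-averaged late-generation frequency sits
within a few percent of the deterministic $q^\*$; tests require 20%,
generous relative to drift noise ($Ns = 100$). A reversible-mutation
option is deliberately absent: back mutation from loss-of-function Mrt
alleles is rare, and irreversibility is the modelled assumption.

**Parameter recovery** (`recover_U`). Simulated MA experiments
(mutations arise as Poisson with rate $2U$ per generation, each
surviving with probability 1/2; carrier lines express the strong-Mrt
sterility model) are classified, the strong-line count is taken as $k$,
and `rate_ci()` is applied. At the study design and $U = 6\times
10^{-5}$ the mean recovered $k$ matches $ntU = 1.005$ within Monte-Carlo
error and the exact interval covers the truth in ≥95% of experiments
(empirically ≈98%, reflecting the interval's conservatism).

## The synthetic-data generator

The generator emulates the study's designs — 34 N2 lines × 10 replicates
× 21 generations, 33 PB306 × 10 × 14, 18 ancestral pseudolines × 10, and
95 wild isolates × 3 × 21, all available as preset `assay_design`s —
with per-class time-to-sterility laws. The study defines classes by
thresholds and does not report a generative law, so the generator uses
discretised negative binomials truncated to class support windows, with
per-replicate sterility probabilities:

| class | mean | dispersion | support | P(sterile) |
|---|---|---|---|---|
| strong | 6 | 50 | 2–9 | 1 |
| moderate | 13 | 60 | 10–21 | 1 |
| weak | 18 | 30 | 16–21 | 0.95 |
| wild_type | 15 | 10 | 2–21 | 10/180 |
| ts_sterile | point mass at 1 | — | — | 1 |
| low_fitness | 5 | 10 | 1–14 | 0.9 |

The support windows are chosen so the class definitions hold by
construction where the thresholds allow: a strong draw in [2, 9] forces
mean < 10 and max < 15; a moderate draw in [10, 21] can never satisfy
the strong mean criterion; a weak draw in [16, 21] can never satisfy the
moderate mean criterion. The wild-type sterility probability 10/180 is
the observed pseudoline replicate failure rate; low-fitness lines emit
the `non_mrt_failure` annotation (the annotation is *generated*, because
in real data it comes from visual inspection). Remaining stochastic
leakage is small and one-directional — e.g. a 3-replicate wild-type line
has a ≈1% chance of two sporadic failures and hence a weak call — and is
accounted for in the tolerance of the mixture-recovery tests.

Seeding: one base seed expands deterministically into per-line
substreams, so identical seeds give byte-identical tables and enlarging
a design appends lines without perturbing existing ones.

What passing tests on these synthetics do *not* show: real wild isolates
carry segregating small-effect modifiers that blur class boundaries, and
real within-class timing distributions are unknown beyond their
thresholds — the generator demonstrates correctness of the analysis
chain, not distributional realism of *C. elegans* assay data.

## Distribution comparison

`compare_time_to_failure()` asks whether two tables (e.g. MA lines
without an Mrt mutation vs ancestral pseudolines) differ in their
replicate-level failure profiles. Censored replicates are assigned the
horizon value, so the comparison is of full censoring-aware profiles.
The statistic is the Kolmogorov–Smirnov distance; because generation
data are heavily tied integers, the asymptotic KS null is invalid and
the null is obtained by permuting table labels (p-values +1-smoothed,
never exactly 0). Tied statistics make the test mildly conservative:
across 1,000 null datasets the 5%-level rejection rate is measured at
≈3.5–4%, and power against an 8-generation shift at 100 replicates per
arm is essentially 1.

## Tree nearest-neighbour analysis

A phenotype maintained by MSB recurs by mutation and is quickly purged,
so carriers should appear on scattered tip branches whose nearest
phenotyped neighbour is wild type; balancing selection instead predicts
deeper clusters of carriers. `pheno_tree()` couples a Newick tree (read
with **ape**) with a partial tip→class map; distances are patristic
(sums of branch lengths, meaningful on a haplotype-similarity
dendrogram) with a hop-count alternative. Unphenotyped tips stay in the
tree but are never neighbours. Exact distance ties break
lexicographically by tip label, so results are deterministic, and a
small relative tolerance absorbs the float noise that re-rooting
introduces into otherwise equal path sums.

`scatter_statistic()` counts focal-class tips whose nearest phenotyped
neighbour is wild type; `scatter_permutation_test()` permutes class
labels over the phenotyped tips (the neighbour map itself is
label-independent, so it is computed once). With few focal tips the
count statistic is coarse and its permutation p-value correspondingly
lumpy-conservative; calibration approaches uniformity as the number of
phenotyped tips grows (tests use 60-tip trees). The direction
`alternative = "clustered"` tests the balancing-selection prediction.
No attempt is made to reproduce judgment calls about "ambiguous"
placements; the statistic is purely the neighbour count.

## Numerical and design choices

* Problem sizes in the test suite are chosen for desk-scale runs: $10^5$
  transmission replicates, 2,000 recovery experiments, 40,000
  Wright–Fisher generations at $N=10^5$, 1,000 permutation-null
  datasets — together under a minute of compute.
* `point_rate() * meioses` returns $k$ only to IEEE-754 precision
  (e.g. $5/8500 \cdot 8500 \ne 5$ exactly); tests use tolerance-based
  equality.
* Reported estimates carry full precision; rounding to headline figures
  (one significant digit for $U$ and $s$) happens only in report
  formatting, and both forms appear in CLI JSON reports.
* The command-line interface (`mrt_cli()`, with a thin `Rscript` wrapper
  in `inst/scripts/mrtline`) is a convenience over the exported
  functions; the functions are the primary interface.

## Known limitations

* Low-fitness exclusion requires the `non_mrt_failure` annotation; it
  cannot be inferred from timing alone, by design.
* The weak/moderate distinction needs a 21-generation assay; the PB306
  design cannot express it.
* Selection-coefficient intervals combine $U$ and $\hat q$ intervals by
  interval arithmetic, which overstates width relative to a joint
  likelihood treatment.
* The Wright–Fisher simulator tracks lineages, not diploid genotypes;
  heterozygous-phase dynamics and outcrossing are out of scope.
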