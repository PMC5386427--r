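---
title: "Non-recombining haplotype blocks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-recombining haplotype blocks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

phaxkit analyses phased haploid SNP haplotypes — the natural data produced
by sequencing the X chromosome in males, where haploidy makes phase exact
even for singleton variants. Its pipeline mirrors how such loci are treated
in human population genetics: find segments with no evidence of historical
recombination, summarise their diversity per population, draw the haplotype
genealogy as a median-joining network, and date nodes of the network with
the rho statistic. A built-in coalescent simulator supplies data with known
genealogy, mutation placement and demography, so every stage can be
validated against ground truth rather than against opaque reference output.

## Block detection

A *block* (PHAX) is a run of at least three adjacent SNPs in which every
site pair is consistent with a purely mutational history. Two criteria are
applied to each pair:

1. **Complete LD per scan population.** Lewontin's
   $|D'| = |p_{AB} - p_A p_B| / D_{\max}$ must equal 1 in every scan
   population, where $D_{\max} = \min(p_A p_b,\, p_a p_B)$ for positive $D$
   and $\min(p_A p_B,\, p_a p_b)$ otherwise. $|D'|$ is *undefined* — and
   treated as a vacuous pass — when a site is monomorphic in that
   population, carries more than two alleles there, or fewer than two
   complete haplotypes remain. A monomorphic pair simply offers no evidence
   of recombination, so it cannot break a block.
2. **At most three gametes, pooled, with ancestral inclusion.** Over all
   samples together, at most 3 of the 4 possible two-site haplotypes may
   occur, counting the (ancestral, ancestral) combination whether or not it
   was sampled. Including the ancestral haplotype makes the test strictly
   harder: a pair whose three observed gametes exclude the ancestral
   configuration still implies a crossing event. We read "three of four"
   as an upper bound (a two-gamete pair is at least as consistent with no
   recombination), and for the rare multiallelic pair we generalise the
   ceiling to $k_i k_j - 1$ observed combinations while declaring $|D'|$
   undefined.

For biallelic polymorphic pairs within one population the two criteria
coincide: $|D'| = 1$ exactly when at most three gametes occur. The test
suite checks this equivalence against a brute-force gamete enumerator on a
thousand random pairs. Because the statement is discrete, `d_prime()` snaps
values within $10^{-9}$ of 1 to exactly 1; the ratio of sample frequencies
is otherwise subject to float rounding that would turn a missing gamete
class into $|D'| = 0.999\ldots$.

Blocks are grown by greedy left-to-right maximal extension within each
chromosome, testing **all** within-run pairs, not only adjacent ones
(`pair_mode = "all"`, the default). Adjacent-only testing would admit runs
whose distal pairs show four gametes, contradicting the claim that the run
is historically non-recombining; the switch is retained because a
single-pass adjacent scan is cheaper on very dense data. Greedy extension
makes the output deterministic and independent of sample order, and
reported blocks never overlap. Runs shorter than `min_sites` (default 3)
are discarded.

Candidate filtering reflects which blocks are worth resequencing: free of
genes, separated from the nearest gene on each side by at least one
recombination hotspot strictly inside the gap (vacuously true on a side
with no gene), free of segmental duplications, and fully contained in a
region with an outgroup ortholog so ancestral states can be called.
Interval bookkeeping is delegated to `GenomicRanges`; BED input is 0-based
half-open and converted at the boundary. Ranking uses the number of
distinct haplotypes the block's SNPs define in a focal population,
descending, with deterministic tie-breaks (more SNPs, then leftmost).

## Diversity and neutrality statistics

Per group the package reports $n$, segregating sites $S$, derived
singletons, distinct haplotypes $K$, haplotype diversity
$H = \frac{n}{n-1}(1 - \sum_k p_k^2)$, and nucleotide diversity $\pi$ as
mean pairwise differences. $\pi$ is reported **both** per block and per
site ($\pi/L$), because the per-block numbers of a short locus and the
percentage-scaled per-site numbers seen in the literature are easily
confused; the output is explicit about units. $L$ defaults to the SNP
count and should be set to the called length of the block when diversity
per sequenced base is wanted.

* **Tajima's D** uses the 1989 constants exactly as published
  ($a_1, a_2, b_1, b_2, c_1, c_2, e_1, e_2$); it is undefined at $S = 0$.
* **Fu's Fs** evaluates $S' = P(K \ge k_{obs} \mid \theta = \hat\pi)$ under
  the Ewens sampling formula with unsigned Stirling numbers of the first
  kind, then $F_s = \ln(S'/(1-S'))$. The Stirling recurrence is run in log
  space with log-sum-exp, so $n$ in the hundreds is exact to double
  precision rather than overflowing (a plain recurrence overflows around
  $n = 170$); the suite verifies row sums against $\log n!$ at $n = 240$.
* **Fu & Li's D** uses the outgroup-rooted form on total mutations $\eta$
  and derived singletons $\eta_s$, with the original $u_D, v_D$ constants.
  It refuses to run when ancestral states are unknown, because the
  minor-allele fallback changes the meaning of a "singleton".

A *singleton* throughout is a derived allele carried by exactly one
chromosome in the **entire** data set, matching both the accounting of
rare variants and the tips of the networks. Population-level singleton
counts in `diversity_stats()` apply the same definition within the group.

Significance for all three statistics comes from coalescent simulation
conditioned on the observed $n$ and $S$ (Hudson's fixed-S scheme: neutral
genealogies with exactly $S$ mutations thrown multinomially on branches in
proportion to length). Under fixed-S the effective size cancels, so the
null needs no nuisance parameter. Tajima's D and Fu & Li's D are tested
two-tailed; Fu's Fs one-tailed on the low side, the convention for a
statistic whose signal of interest is an excess of haplotypes. The default
replicate count in the pipeline is user-set (`n_sim`); calibration is
verified in the suite by checking that the nominal 5% level is not
exceeded under neutrality.

**phi-st** is the AMOVA fixation index on squared molecular distances
(pairwise difference counts between haploid chromosomes): among-population
variance over total, from the standard two-level sums of squared
deviations, with significance by permuting population labels. Slightly
negative estimates are reported as computed — truncating at zero would
bias averages of near-zero comparisons upward. The implementation is
checked against independent variance-component arithmetic, and against
invariance under within-population relabelling.

The SNP-density chi-square applies Yates' continuity correction **per
cell** even for more than two categories. This is nonstandard (the
correction was derived for $2\times2$ tables) but is the form used for
three-locus density comparisons in the literature this package follows; it
is documented rather than hidden. The PCA on per-population haplotype
frequencies is a plain centred `prcomp`, and the Kolmogorov–Smirnov
comparison wraps `stats::ks.test` with the asymptotic p-value.

## Median-joining networks

`build_mj_network()` implements the Bandelt construction: iterate between
the minimum-spanning network (union of all minimum spanning trees under
Hamming distance; parameter $\varepsilon$ relaxes the merge criterion) and
the addition of median (Steiner) vectors — coordinate-wise majorities of
connected triplets — keeping, per round, the candidates whose connection
cost is within $\varepsilon$ of the minimum. At the fixed point,
superfluous median vectors (unsampled nodes of degree ≤ 2) are pruned.
$\varepsilon = 0$ is the default, as in common practice; larger values add
alternative equally-parsimonious connections. Determinism is guaranteed by
processing haplotypes in sorted order, and is tested by reversing input
order.

Ties in the majority vote at multi-state positions resolve toward the
ancestral character when it is among the three, else to the
lexicographically smallest — an arbitrary but fixed rule that only matters
for multiallelic sites. The ancestral haplotype (all-ancestral alleles) can
be injected as a frequency-zero node, providing the conventional root for
dating even when unsampled.

Reticulations are counted as the cycle-space rank
$E - V + C$. On infinite-sites tree data the network must be the true
mutation tree: zero reticulations, total cost equal to the number of
mutations. This is the package's strongest self-check, run over a hundred
simulated genealogies, because it couples the simulator's ground truth to
the network code with no tolerance at all.

## Rho dating

For a cluster of chromosomes and a chosen root node,
$\rho$ is the mean mutational distance from the root to each *chromosome*
(not each distinct haplotype — frequency weights the distances; collapsing
to haplotypes would bias $\rho$ toward rare outliers). The standard error
follows Saillard: on the rooted cluster tree,
$\sigma_\rho^2 = \sum_{\text{mutations}} (n_b/n)^2$ with $n_b$ the number
of chromosomes descending through that mutation. Calendar time is
$\rho \times$ years-per-mutation, where
`years_per_mutation(mu, L)` $= \lfloor 1/(\mu L)\rfloor$; the scaled rates
for the three bundled block lengths (36 857, 4983, 5763 bp at
$\mu = 6.59\times10^{-10}$/site/year) are 41 171, 304 525 and 263 309
years per mutation — these quoted values correspond to truncation, not
rounding, and the function follows that convention.

Paths from root to members must be unique shortest paths; a reticulation
inside the cluster makes the rooted tree ambiguous and raises an error
asking for cluster refinement rather than silently picking a path. Cluster
membership itself is a user decision (node ids plus multiplicities): which
star or subclade is worth dating is a judgement made on the network, not
something the package auto-detects.

The estimator is validated by simulating star expansions of known age
$T$: since $E[\rho] = \mu L T$, the mean dated age over replicates must sit
within Monte-Carlo error of $T$. The suite and the acceptance script run
this at $n = 20$ chromosomes, $T = 45\,000$ years, $L = 36\,857$ bp.

## The coalescent simulator

The simulator is deliberately minimal and fully inspectable:

* **Genealogies.** Haploid Kingman coalescent; with $k$ lineages in a deme
  of size $N$, waiting time $\sim \text{Exp}(k(k-1)/2N)$ generations.
  Demography is piecewise-constant: `"expansion"` is an instantaneous size
  change at `t_onset` (current $N_0$, ancestral $N_0/f$), and `"split"`
  holds isolated demes that merge into one ancestral deme at `split_time`.
  Exponential growth curves are not modelled; for the signatures of
  interest (star-like genealogies, singleton excess) the instantaneous
  change is the standard idealisation and keeps every expectation
  closed-form testable. Sizes are haploid effective sizes; X-specific
  scaling (¾ of autosomal) is the caller's responsibility and is
  documented, not hard-coded.
* **Mutations.** Infinite sites: each branch receives
  Poisson(length $\times \mu g L$) mutations, each at a fresh uniform
  position, derived allele below the branch, ancestral allele "0"
  everywhere. Recurrent mutation is thereby excluded by construction,
  which is exactly what makes "reticulation implies recombination (or
  recurrence)" a testable statement; recurrence can be emulated in
  fixtures by duplicating a site column manually.
* **Recombinants.** `inject_recombinants()` splices two sampled donors at
  a chosen breakpoint. A planted violation is only guaranteed detectable
  when one donor is derived where the other is ancestral on the left and
  vice versa on the right; the helper logic in the test suite selects
  donors accordingly, since a chimera of two differences on the same
  lineage is indistinguishable from an early-branching haplotype.

Closed forms verified by Monte Carlo: $E[T_2] = N$,
$E[\text{total length}] = 2N\sum_{i<n} 1/i$, $E[S] = \theta a_n$ with
$\theta = 2N\mu g L$, and $E[\xi_i] = \theta / i$ for the frequency
spectrum.

`make_study_fixture()` reproduces the shape of the study this toolchain
targets: 12 demes × 20 haploid chromosomes at three loci of 4983, 36 857
and 5763 bp — one constant-size deeply diverged African-like deme
($N = 12\,000$), and eleven non-African demes ($N = 10\,000$ each) that
coalesce into a bottleneck deme of $N = 500$ at 20 000 years ago
(generation time 30.8 y) and join the African deme at 70 000 years ago.
The 20 kya merge plays the role of the post-glacial expansion onset; the
size drop from 10 000 to 500 produces star-like genealogies, negative
Tajima's D and Fu's Fs in the non-African demes, strong Africa–Europe
phi-st and weak structure within Europe. These defaults were chosen once,
as round numbers in the range population-genetic studies of European
expansion use, and are not tuned: tests assert signs, orderings and
Monte-Carlo intervals, never point values of the fixture.

What the generator does **not** emulate: sequencing error, per-sample
callable masks and coverage-driven missingness, gene conversion, selection,
migration after splits, and recurrent mutation. Passing tests therefore
demonstrate correctness of the statistical machinery on clean phased
haplotypes, not robustness to upstream calling artefacts — those belong to
the variant-calling pipeline, which is out of scope here.

## Numerical and interface choices

* Internal interval arithmetic is `GenomicRanges` (1-based closed);
  BED (0-based half-open) and VCF (1-based) conventions are converted at
  the file boundary only.
* Missing calls are handled by complete-case deletion per comparison:
  pairwise per site pair in LD/distance computations, per haplotype in
  haplotype counting. Effective $n$ is whatever survives; no imputation.
* Heterozygous diploid VCF genotypes are a hard error naming sample and
  site — phased haploid input is the contract, and silently picking an
  allele would corrupt every downstream statistic. Homozygous diploid
  calls collapse with a warning.
* Block length for dating: `length_convention = "span"` (end − start + 1)
  by default, or the SNP count; when the called length of a block differs
  from its span (uncallable bases inside the span), the called length is
  the right $L$ for mutation-rate scaling and can be passed explicitly.
  The bundled region table carries called lengths for exactly this reason.
* The pipeline (`run_pipeline()`) validates its whole configuration up
  front and reports all problems at once, stages log attrition counts
  (sites read, blocks found, haplotypes per block), outputs are plain TSV,
  GraphML and a JSON manifest with seeds and versions, and a rerun is
  byte-identical. Problem sizes in the shipped tests (10–20 chromosomes,
  $\theta$ of a few units, hundreds of replicates for Monte-Carlo checks)
  were chosen so closed-form expectations are resolvable with 3-standard-
  error assertions.

## Known limitations

* The greedy scan returns one maximal tiling of non-overlapping runs; a
  different objective (e.g. maximising total covered SNPs) could tile
  differently when a violation sits between two overlapping candidate
  runs.
* $|D'|$-undefined pairs passing vacuously means blocks can extend through
  sites monomorphic in some populations on pooled evidence alone; that is
  intentional but worth remembering when scan populations are small.
* `phi_st` permutations are per pair, not a single global permutation
  scheme; p-values across many pairs should be multiplicity-corrected by
  the user (`stats::p.adjust`).
* The median-joining $\varepsilon > 0$ mode uses the common
  component-merge relaxation of the minimum-spanning network; for
  $\varepsilon = 0$ (the default and the tested mode) it is exact.
* Rho dating assumes the clock is right and the cluster tree is correct;
  its SD reflects only the mutational Poisson noise, as is standard for
  this estimator.
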