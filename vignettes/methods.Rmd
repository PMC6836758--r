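---
title: "Models and methods behind coalABC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind coalABC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

coalABC infers multi-population divergence histories from small
multi-locus sequence panels — the data regime of classical
phylogeography: one mitochondrial fragment and a handful of nuclear
introns, sequenced for tens of individuals per population. The package
bundles three layers: descriptive population-genetic statistics, a
coalescent simulator for competing divergence scenarios, and a
likelihood-free (ABC) inference engine for scenario choice and parameter
estimation. This vignette records the models, the defaults and the design
decisions, including those where reasonable implementations could differ.

## The study system and the synthetic-data generator

The built-in design mirrors a trans-Pacific rocky-shore gastropod study:
seven populations — ERI, KHO, STA and PET in the northwestern Pacific
(NWP), KOD, COR and JUN in the northeastern Pacific (NEP) — typed at four
loci: 433 bp of mitochondrial cytochrome b and three nuclear introns of
881, 612 and 597 bp. Individuals per population (ERI 11, KHO 16, STA 8,
PET 16, KOD 9, COR 12, JUN 8) match the field collections; mtDNA
contributes one gene copy per individual, each nuclear locus two phased
copies (the cloning protocol behind the data yields phase-known alleles,
and `read_panel()` treats the two records per individual accordingly).

`simulate_locus()` runs a standard n-coalescent inside a rooted population
tree. Within a branch of effective size $N$, each lineage pair coalesces
at rate $1/(c \cdot 2N)$ per generation, where $c$ is the inheritance
scalar (1 for autosomes, 0.25 for maternally inherited haploid mtDNA). At
each merge event, going backward in time, all lineages of the source
branch move into the destination branch, which keeps its own size.
Mutations are Poisson on branches at rate $\mu L$ per generation and
placed under the infinite-sites model; output is encoded over {A, G}
(ancestral/derived) so every downstream statistic sees an ordinary
alignment. If a simulation ever draws more mutations than sites the locus
falls back to finite sites (recurrent mutation toggles a position) and
flags the result; at the default rates this is essentially unreachable.

Mutation rates derive from a sequence divergence rate of 1% per million
years (0.5% per lineage, i.e. $5 \times 10^{-9}$/site/year) for the
mitochondrial locus, a rate repeatedly inferred for gastropod
protein-coding mtDNA from fossil-calibrated phylogenies. No published
nuclear rate exists for this system; the default is
$1 \times 10^{-9}$/site/year, an order of magnitude below the mtDNA rate,
as is typical for invertebrate nuclear introns. Generation time defaults
to one year. All three are configurable (`default_loci()`,
`scaling_config()`).

What the generator deliberately does **not** emulate: intra-locus
recombination, migration after divergence (full-likelihood analyses of this
system detected no gene flow, so migration is structurally zero), population growth
within branches, substitution-model complexity (infinite sites implies no
recurrent or back mutation), and sequencing artifacts. Tests passing on
synthetic data therefore validate the inference machinery, not robustness
to model misspecification in real alignments.

## The four divergence scenarios

`builtin_scenarios()` encodes four competing histories over the seven
populations, differing in how the NEP clade relates to the Kamchatka
population (PET):

* **scenario1** — single west-to-east colonization: backward in time,
  KOD→COR ($t_a$), COR→JUN ($t_b$), the NEP clade into PET ($t_c$), then
  STA→ERI ($t_d$), PET→ERI ($t_e$), KHO→ERI ($t_f$), with
  $t_a<t_b<t_c<t_e$ and $t_d<t_f$.
* **scenario2** — two colonizations: KOD and the (COR, JUN) clade merge
  into PET independently at distinct times.
* **scenario3** — east-to-west: PET derives from the ancestral NEP
  lineage.
* **scenario4** — null: the NEP clade is sister to all NWP populations,
  joining only at the root.

Each scenario has one size parameter per population lineage and one time
per merge: the destination of a merge retains its own size. This
13-parameter layout (for seven populations) matches the published
posterior summary for the single-colonization history, which lists
exactly seven sizes and six times; `scenario1_modal_parameters()` carries
those modes. Scenarios 2 and 4 admit more than one tree realization, so their
event lists are the package's own explicit, documented reading (two independent arrivals; NEP sister to everything), and both
are ordinary `scenario_spec()` objects a user can replace.

Priors default to $U(100, 10^6)$ individuals for every size and
$U(10, 6 \times 10^5)$ generations for every time — broad boxes that
bracket all published estimates for this system. Draws violating a
scenario's ordering constraints are rejected and redrawn.

## Descriptive statistics

All statistics operate on the sites free of gaps and ambiguity codes in
every sequence (listwise exclusion, the Arlequin/DNAsp convention).
Haplotype diversity uses Nei's correction $h = \frac{n}{n-1}(1 - \sum
p_i^2)$; nucleotide diversity is mean pairwise differences per usable
site. Tajima's $D$ uses the standard 1989 constants and is undefined for
$S = 0$ or $n < 4$ (the variance constants degenerate at $n \le 3$).
Fu's $F_s$ computes $S' = P(K \ge k_{obs})$ exactly under the Ewens
sampling formula at $\hat\theta = k$, via unsigned Stirling numbers of
the first kind evaluated in log space, then $F_s = \ln(S'/(1-S'))$.
$R_2$ contrasts per-sequence singleton load with $k/2$; at $n = 2$ both
alleles of a polymorphic site are singletons and the carrier of the
alphabetically later state is charged, so that exactly one singleton is
counted per site.

Significance of $D$, $F_s$ and $R_2$ comes from neutral constant-size
coalescent simulations conditioned on the observed number of segregating
sites (mutations placed on branches proportional to length), the DNAsp
convention, rather than on $\hat\theta$; the choice matters for small
samples and is stated here because the two conventions coexist in the
literature. $F_s$ and $R_2$ are one-tailed (small values significant),
$D$ two-tailed on $|D|$; all p-values carry the add-one correction
$(b+1)/(m+1)$.

Pairwise $\Phi_{ST}$ is a two-level AMOVA on the matrix of pairwise
differences, with the standard unequal-sample-size coefficient, and a
label-permutation test ($\Phi \ge \Phi_{obs}$, add-one corrected).
Distances are uncorrected Hamming counts by default — on infinite-sites
synthetic data a substitution-model correction is vacuous — with
Jukes–Cantor available by flag for real alignments. When every sequence
is identical, $\Phi_{ST}$ is defined as 0 with $p = 1$.

## Recombination screening

The pairwise homoplasy index test (`phi_test()`) simplifies the refined
incompatibility score to a binary four-gamete indicator over biallelic
parsimony-informative sites — the study's loci are overwhelmingly
biallelic per site, and the binary score preserves the test's logic of
asking whether incompatibility is concentrated among distant site pairs.
$\Phi_w$ is the mean indicator over informative pairs within `window_w`
(default 100) alignment positions; significance permutes the assignment
of site columns to physical positions and counts permutations with
$\Phi_w$ at or below the observed value. This deviates from the
Splitstree implementation in the score refinement and the windowing
details, which are not standardized across implementations.

`filter_recombinant_sites()` replaces the joint sequence-and-site
optimization of IMgc with a deterministic greedy loop: remove the site in
the most remaining four-gamete violations (leftmost on ties), recompute,
stop at zero violations. The output provably passes the four-gamete test
and infinite-sites input passes through untouched.

## Haplotype networks

`build_msn()` builds the $\epsilon = 0$ minimum spanning network (the
union of all minimum spanning trees, PopART's minimum-spanning default):
edges enter in ascending Hamming weight, and within a weight class every
edge joining two components — as the components stood before the class —
is kept, so ties are never broken arbitrarily. Median-joining inference
of unsampled nodes is deliberately out of scope. Exports are GraphML and
TSV with per-region counts on nodes.

## The ABC engine

**Summary statistics.** Per locus group — mtDNA alone, nuclear loci
averaged — the vector holds $\{H, S, k, \mathrm{var}\,k, D\}$ per
population and $\{$pooled $S$, between-population mean pairwise
differences, $\Phi_{ST}\}$ per population pair: 196 statistics for the
seven-population, four-locus design. Statistics undefined on a
realization are encoded as 0, identically for observed and simulated
data. Averaging the nuclear loci (rather than concatenating per-locus
blocks) respects inheritance differences while keeping the vector
length independent of locus count.

**Reference table and rejection.** `build_reference_table()` simulates
$n$ datasets per scenario with per-row seeds derived from one master seed
(`derive_seed()`), so any row can be regenerated in isolation. Distances
are Euclidean on MAD-normalized statistics (a constant column's MAD is
replaced by 1, with a warning); `abc_reject()` retains the closest rows,
ties broken by row index.

**Scenario choice.** `model_choice()` fits a multinomial logistic
regression of the scenario label on the normalized deviations
(statistics − observed) of the retained rows, weighting observations
with an Epanechnikov kernel on rejection distance (bandwidth = largest
retained distance), and reads posterior scenario probabilities at the
observed point. Two deliberate numerical choices: the fit always carries
a small fixed ridge penalty (glmnet, $\lambda = 0.01$, unstandardized),
because retained sets of hundreds of rows against ~190 statistics are
near-separable essentially always and an unpenalized fit is undefined
there; and confidence intervals come from a nonparametric bootstrap of
the retained rows rather than asymptotic covariances. At the default
validation scale the regression's leverage is limited — see the
calibration section below.

**Error rates.** For a focal scenario, the false-negative rate is the
share of pods simulated under it for which another scenario is chosen;
the false-positive rate is the share of pods simulated under the
alternatives for which the focal scenario is chosen. `run_pods()`
supports prior-drawn, fixed (e.g. posterior-modal) or resampled pod
parameters.

**Parameter estimation.** `estimate_parameters()` keeps the closest 1%
of the selected scenario's rows (floored at 20), maps each parameter to
the real line by a logit transform onto its prior bounds (clamped
$10^{-8}$ of the range off each bound), and adjusts by a weighted
local-linear regression on the statistic deviations,
$\varphi^* = \varphi - (s - s_{obs})^\top\hat\beta$. Two safeguards
determine how much adjusting actually happens:

* If the retained design is singular — fewer retained rows than
  statistics, which is the case at the default desk scale (1% of
  $10^4$ = 100 rows against ~190 statistics) — the adjustment is skipped
  and the posterior is the weighted rejection sample, flagged
  `adjusted = FALSE`. Calibration experiments (below) motivated making
  this the hard rule rather than forcing a penalized fit: an ordinary
  solve interpolates and collapses the posterior to a point.
* Otherwise the regression is ridge-stabilized, with the penalty chosen
  by 5-fold cross-validation under the one-SE rule, so a barely
  informative design shrinks the adjustment toward zero instead of
  inventing precision.

Modes come from a Gaussian kernel density (Silverman bandwidth, kernel
weights); credible intervals are 0.025/0.975 weighted quantiles.
`scale_units()` converts $\theta$ to individuals
($N = \theta/(4 u c)$), generations to years, and mutation-scaled times
to years under the divergence-rate configuration.

## Validation design and what it shows

The validation experiments (in `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R`) use a reference table of $10^4$ simulations per
scenario, 500 retained rows for model choice, 500 pods per error-rate
experiment and 100 pods for coverage — sizes chosen as the package's
validation design; the original full-scale analysis of this system ran
$10^6$ simulations per scenario and retained 50,000.

Three results characterize this scale:

* **Coalescent calibration.** At $n = 20$, $\theta = 5$, 1,000
  replicates: $E[S] = \theta a_1$, $E[k] = \theta$ and mean Tajima's
  $D \approx 0$ within Monte-Carlo error.
* **Parameter recovery.** 95% credible intervals cover prior-drawn true
  values within the 85–99-of-100 band for all 13 scenario-1 parameters.
* **Scenario identifiability is the binding constraint.** Scenarios 1
  and 3 differ only in which lineage's size parameter the merged
  NEP+PET ancestral branch takes; under the broad default priors this
  makes them nearly likelihood-equivalent, and separating them is the
  hard part of the model choice. At this table size the true scenario
  still wins the modal-parameter pod experiment by a majority, but the
  pod-based error rates remain several-fold larger than the published
  full-scale values, which condition on 100× more simulations per
  scenario, 100× more retained rows, and narrower priors informed by
  pairwise isolation-with-migration fits. The error-rate comparison in the
  validation suite records this gap rather than hiding it.

## Known limitations

* No migration, growth, or recombination in the simulator; the ABC
  machinery is only as good as that model for real data.
* The PHI test's windowing and score refinement differ in detail from
  Splitstree; p-values on real loci will not match it digit-for-digit.
* The four-gamete filter removes sites only; IMgc can retain more data
  by also dropping sequences.
* Full-likelihood isolation-with-migration inference (IMa-style MCMC)
  is out of scope.
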