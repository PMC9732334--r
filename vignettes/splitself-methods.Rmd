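---
title: "Models and methods behind splitself"
author: "splitself authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind splitself}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splitself)
```

# The scientific problem

When a species expands its range behind a retreating ice sheet, serial
founder events favour a shift from outcrossing to self-fertilization,
and selfing in turn restricts gene flow, builds up genome-wide linkage
disequilibrium, and changes how deleterious mutations are exposed to
selection. Under the right circumstances this chain of events can seed
parapatric speciation at the range edge: a selfing peripheral lineage
buds off, keeps expanding, and becomes reproductively isolated from its
parental species. North American *Arabidopsis* — selfing
*A. arenicola* budding from *A. lyrata* around northwestern Lake
Superior after the Last Glacial Maximum — is the motivating example.

Testing that scenario requires a chain of inferences: when and from
where did the lineage split (SFS-based demographic model selection)?
Is there residual gene flow (Patterson's D)? How selfing is the new
lineage (F_IS, progeny arrays)? Did selfing and expansion leave the
expected LD footprint (correlation of zygosity)? Did mutational load
accumulate along the route (impact-annotated variant counts vs geodesic
distance)? `splitself` implements each step together with synthetic
generators that produce inputs with known truth, so every estimator can
be validated by parameter recovery before it touches real data.

# The structured coalescent engine

A `demographic_model()` lists populations with diploid effective sizes
$N_e$ and selfing rates $s \in [0,1]$, backward-in-time split events
(the derived population's lineages are pooled into the ancestral one),
a constant backward migration matrix $m_{ij}$ (the per-generation
probability that a lineage in $i$ traces back to $j$, applied while
both populations exist), a per-site mutation rate $\mu$, and a locus
length $L$. Time is in generations before sampling; conversion to
years happens only at reporting (`generations_to_years()`), with the
generation time for these perennials taken as 1–2 years.

Genealogies follow the standard structured coalescent: within a
population carrying $k$ lineages, pairwise coalescence occurs at rate
$k(k-1)/2 \cdot 1/(2N_e)$ per generation; migration moves single
lineages between coexisting populations; splits pool lineages.
Mutations are Poisson on branches at rate $\mu L$ under infinite
sites, with exact polarization (allele 0 ancestral) and uniform
positions along the locus. Loci are independent and non-recombining.

**Selfing.** Partial selfing uses the equilibrium identity-by-descent
shortcut: at sampling, an individual's two haploid lineages coalesce
immediately with probability $F = s/(2-s)$. This matches the
equilibrium expectations the mating-system analyses rely on and keeps
the simulator simple and checkable, at the cost of ignoring the
secondary effect of selfing on within-population $N_e$ and the
correlation of selfing events across loci. Full gametic bookkeeping is
out of scope.

**Implementation.** The engine is C++ (Rcpp), because the ECM fit
evaluates thousands of Monte-Carlo likelihoods; it draws all randomness
from R's RNG, so a single `seed` argument makes every simulation
bit-reproducible. Up to 64 haploid samples are supported (branch leaf
sets are machine words) — ample for pooled super-populations of a few
fully sequenced individuals each.

The engine is validated against closed forms: mean segregating sites
per locus $\theta \sum_{i<n} 1/i$ (Watterson), the neutral unfolded SFS
$E[\xi_i] = \theta/i$, the selfing heterozygote deficit
$F = s/(2-s)$, and monotonicity of $F_{ST}$ in split time.

# SFS construction and filters

`compute_joint_sfs()` tallies, per site, the tuple of derived-allele
counts across pooled super-populations into an array of dimension
$\prod_p (n_p + 1)$ ($n_p$ = haploid size). Polarization is required;
in real-data mode it must come from an outgroup-based ancestral
assignment upstream. Sites with missing genotypes among the pooled
samples are dropped and counted — the fit samples are
complete-genotype individuals, and SFS projection is deliberately not
implemented. Fixed cells are stored but flagged; all likelihood work
conditions on polymorphism.

The conventional filters are separate, composable steps:
`filter_biallelic_mac()` (minor allele count strictly greater than 3,
the filter used for structure/tree site sets — *not* applied before SFS
fitting, which it would distort) and `thin_by_distance()` (greedy
left-to-right 20 kb thinning, first site per chromosome always kept,
spacing inclusive). Each filter logs read/kept/skipped counts.

# Composite-likelihood fitting

`expected_sfs()` approximates the probability $p_c$ that a segregating
site falls in polymorphic SFS cell $c$, conditioned on polymorphism.
Rather than placing Poisson mutations and counting, each simulated
branch contributes its *length* to the cell determined by the leaves it
subtends: under infinite sites the two estimators share the estimand
($p_c \propto E[L_c]$, the expected branch length subtending
configuration $c$), and branch-length weighting has substantially lower
Monte-Carlo variance per simulation. Cells never hit by simulation are
floored at $0.5/n_{\mathrm{sims}}$ and the vector renormalized, so any
observed cell keeps a finite likelihood.

`composite_loglik()` is the multinomial composite log-likelihood
$\ln CL = \sum_c m_c \ln p_c$ over polymorphic cells (natural log
throughout; $AIC = 2k - 2\ln CL$ — AIC ranking is invariant to the log
base as long as it is uniform, which the implementation enforces by
construction). Conditioning on polymorphism removes any dependence on
unknowable monomorphic-site totals and keeps all compared models on
identical data.

`fit_model()` maximizes $\ln CL$ by expectation conditional
maximization: free parameters are partitioned into blocks — split
times, then sizes, then migration rates, then selfing — and each block
is maximized conditionally by bounded one-dimensional golden-section
search, cycling until the relative $\ln CL$ improvement drops below
`tol` (0.001) or `max_cycles` is reached. The exact block partition is
a documented choice; with the small free-parameter sets used here each
block is a single parameter. Two numerical choices matter on a noisy
Monte-Carlo objective:

- **Common random numbers**: all likelihood evaluations within one ECM
  cycle reuse one simulation seed, so line searches see a smooth
  deterministic surface; without this the search dithers in Monte-Carlo
  noise and fails to converge.
- **Log-scale search**: a parameter whose bounds span more than one
  order of magnitude is initialized log-uniformly and optimized in
  log space.

Starts are initialized independently within bounds and the best of
`n_starts` final likelihoods (re-evaluated under one shared fresh seed
so they are comparable) is returned; a start exhausting `max_cycles` is
flagged non-converged rather than raising an error.

**Desk-scale defaults.** The package defaults are
`n_sims = 2000`, `n_starts = 10`, `max_cycles = 20`; the corresponding
full-scale values used for published analyses of this kind (100,000
simulations, 100 starts, 100 cycles) are plain arguments. The test
suite and the acceptance script run the desk scale: split-time recovery
uses 5,000 loci, model-selection consistency 500-locus replicates,
and the null calibration of D 500-locus quartets. These sizes are the
package's reference configuration for validation; all scale up by
argument.

`compare_models_aic()` ranks concurrent fits by AIC with deterministic
tie-breaking (smaller $k$, then model id) and refuses fits whose
observed data differ. `hierarchical_selection()` chains scenario sets:
the winner of each step carries `provides` tags forward, and any later
candidate whose `requires` tags are not established fails loudly —
this encodes the sequential topology-then-placement-then-timing-then-
gene-flow style of comparison as an explicit, auditable contract, and
emits a per-step decision trace.

`bootstrap_ci()` is a parametric bootstrap: the fitted cell
probabilities generate multinomial pseudo-data of the observed
polymorphic-site total, each replicate is refit with reduced starts,
and percentile intervals are returned. Whether published intervals for
this kind of fit are parametric-bootstrap or profile-based is typically
not stated; this implementation is labelled as what it is.

# Patterson's D

`patterson_d()` uses the allele-frequency form over a quartet
(P1, P2, P3, outgroup): with derived frequencies $p_1..p_4$ per site,
$ABBA = (1-p_1)p_2p_3(1-p_4)$, $BABA = p_1(1-p_2)p_3(1-p_4)$, and
$D = \sum(ABBA-BABA)/\sum(ABBA+BABA)$. Unpolarized input is polarized
by the outgroup major allele (outgroup frequency exactly 0.5 drops the
site). Standard errors come from a delete-one block jackknife over
contiguous blocks of `block_size_bp` per chromosome; fewer than three
non-empty blocks refuses the jackknife (flag, not error), a zero
denominator flags D undefined. The significance convention is the
field's $|Z| \ge 3$. The null calibration in the test suite verifies
that under a no-gene-flow topology, $|Z| < 3$ in at least 95% of
simulated quartets.

# Mating system

`fis_multilocus()` uses $H_{obs}$ = fraction heterozygous and the
sample-size-corrected $H_{exp} = 2\hat p\hat q \, n/(n-1)$ per
polymorphic locus, combined as
$F_{IS} = 1 - \sum H_{obs} / \sum H_{exp}$; an all-monomorphic input
returns an explicitly flagged undefined estimate (the realistic
failure mode for a highly selfing population at few markers).

The equilibrium identities $F = s/(2-s)$, $s = 2F/(1+F)$,
$t = 1 - s$ are built in (`mating_system_conversions()`). Note a
documented discrepancy: the equilibrium identity maps $F = 0.48$ to
$t = 0.35$, whereas empirical $F_{IS}$-to-outcrossing curves
calibrated by progeny arrays in related taxa give $t < 0.2$ at such
$F$ — equilibrium assumptions (no selection, inbreeding equilibrium,
error-free markers) are optimistic. `fis_to_outcrossing()` therefore
accepts a user-supplied calibration table and interpolates linearly
through it when one is available.

`outcrossing_progeny_array()` estimates the multilocus outcrossing
rate from maternal-offspring arrays with an explicit detection
correction: an offspring is *detected* outcrossed iff it carries an
allele absent from its mother at some locus; given outcrossing, the
detection probability is
$P_{det} = 1 - \prod_\ell P(\text{pollen allele} \in \text{maternal
alleles at } \ell)$, and $\hat t_m = \overline{\text{detected}} /
\overline{P_{det}}$, truncated to $[0,1]$, with a family bootstrap SD.
Pollen-pool frequencies default to frequencies among maternal plants
when not supplied (standard practice). Offspring carrying no maternal
allele at some locus are genotyping-error records: excluded and
logged, never silently absorbed. Under complete selfing the estimator
returns exactly 0.0 with SD 0.0 — the bootstrap resamples families
whose detected fractions are all zero — reproducing the degenerate
published case rather than approximating it.

# Correlation of zygosity

For one genome, $z(x) = 1$ if heterozygous at site $x$;
$\theta = \bar z$ is genome-wide heterozygosity, and for each distance
bin $\Delta$ is the Pearson correlation of $(z(x), z(y))$ over ordered
within-region site pairs with $|y - x|$ in the bin. Pairs never span
region boundaries; regions default to chromosomes and can be set to
genic intervals via the `regions` argument, since published profiles of
this kind are computed across genic regions. The pair sums use an
$O(n)$-per-bin sliding window in C++, checked against brute-force
enumeration. Pairing is over assayed (variant or indicator) sites;
restricting to other site sets is the caller's choice of input.

Two scalings are reported side by side, because "scaled by $\theta$"
is ambiguous in the literature: `delta` (the correlation, already
dimensionless) and `delta_cov` (pair covariance divided by
$\theta(1-\theta)$). `ld_extent()` rescales the profile to its
shortest-distance bin and reports the distance at which the scaled
profile first reaches a threshold (default 0.1), interpolating
linearly in $\log_{10}$ distance between bins; a profile that never
decays is right-censored, flagged, not extrapolated.

`simulate_zygosity_tracts()` is the generative counterpart: a
stationary two-state Markov chain with stationary het probability
$\theta$ and lag-1 autocorrelation $\rho$, so the lag-$d$
autocorrelation is $\rho^d$ and the analytic extent is
$\ln(0.1)/\ln \rho$. This emulates the tract-length *statistics* the
analysis assumes — it does not emulate recombination-rate variation,
gene conversion, clustered heterozygosity from structural variation, or
callability gaps in real genomes, so passing tests show estimator
correctness, not robustness to those artifacts.

# Mutational load and geography

`count_load()` counts, per sample, variants homozygous for the
alternate allele with SnpEff impact MODERATE (missense-class) or HIGH
(start/stop-class). "Homozygous" means homozygous *alternate* — never
merely non-heterozygous — and only the first ANN annotation per variant
is used (SnpEff orders most-severe first), avoiding multi-transcript
double counting. MODIFIER and LOW never count. The counting rule is
verified exactly against the annotated-VCF generator's ground truth.

Expansion distance is the summed great-circle length along an ordered
waypoint route (`expansion_route()`, YAML-configurable): haversine on a
sphere of mean radius 6371.0088 km. Projecting a population tree onto
the map to obtain those waypoints is upstream of this package — routes
are inputs. `load_distance_regression()` is OLS of load on
$\log_{10}$(distance) with a two-sided t-test on the slope; zero
distances are offset by +1 km (logged), and a degenerate
all-equal-distance input is refused. The serial-founder generator
(`simulate_expansion_load()`) reproduces the qualitative expectation —
load increasing along the route — by binomial founder resampling of
deleterious allele frequencies at each colonization step.

# Reference configuration for validation

The split-time recovery check uses a two-population
split-with-gene-flow model at the scale inferred for this system
(`reference_split_model()`): split at 6007 generations; parental
population $N_e = 50{,}000$, outcrossing; derived population
$N_e = 5{,}000$ with selfing rate 0.95 (a selfing lineage with
strongly reduced diversity); symmetric migration $10^{-6}$ per
generation (gene flow low in both directions); $\mu = 0.355 \times
10^{-8}$ per bp per generation; 5 kb loci; three diploid samples per
side (one sequenced individual from each of three pooled nearby
populations, 6 haploids). The sizes and migration rate are the
package's own field-realistic choices for this kind of system, fixed
once when the model was defined. Refitting the split time from data simulated
under this model recovers it with median relative error well under
25% at 5,000 loci, and the parametric-bootstrap 95% interval covers
the generating value.

# Known limitations

- No recombination within loci and no LD in the coalescent engine; LD
  structure comes from the separate tract model, mirroring the split
  between SFS-based and zygosity-based analyses.
- No population growth curves; sizes are constant per epoch, migration
  constant between coexisting populations.
- Selfing enters only through the identity-by-descent shortcut (above).
- At most 64 haploid samples per simulation.
- SFS fitting conditions on polymorphism; monomorphic totals and
  projection are not modelled.
- The empirical $F_{IS}$-to-$t$ calibration curve is not bundled; the
  equilibrium identity is the default and the calibration-table
  pathway exists for users who have such a curve.
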