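---
title: "Modelling lipoxygenase inhibition of thiazolidine-2,4-diones: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling lipoxygenase inhibition of thiazolidine-2,4-diones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

tzdqsar models the soybean lipoxygenase (LOX) inhibition of nineteen
(Z)-5-arylidene-thiazolidine-2,4-diones with a three-descriptor ordinary
least-squares regression, and ships every stage of that analysis as a tested,
reusable component: descriptor computation from structure, descriptor
prefiltering, genetic-algorithm subset selection, a full internal-validation
statistic suite, and a leverage-based applicability domain. This vignette
explains the model, the numerical choices, and what the accompanying tests do
and do not establish.

## The modelling problem

Each compound carries a measured percent inhibition of soybean LOX at 100 uM.
Modelling happens on the decimal logarithm of that percentage (`log_lox`),
which compresses the 7.3-76.3 range onto roughly 0.86-1.88 and is the scale
on which a linear descriptor model is plausible. The regression form is

$$\log(\%\,\mathrm{LOX\ inh.}) = b_0 + b_1\,Mor29m + b_2\,G2u + b_3\,MAXDP$$

with at most three descriptors for nineteen compounds - deliberately small to
respect the n/p ratio. The three descriptors probe complementary aspects of
structure:

* **Mor29m** - a 3D-MoRSE electron-diffraction signal,
  $\sum_{i<j} w_i w_j \sin(s r_{ij})/(s r_{ij})$ over all atom pairs at
  scattering parameter $s = 28\ \mathrm{\AA^{-1}}$, with relative atomic mass
  weights scaled by carbon. At this large $s$ the sinc term oscillates with a
  period of about 0.22 A in $r_{ij}$, so the descriptor is a fine-grained,
  geometry-sensitive fingerprint of heavy-atom packing.
* **G2u** - the WHIM directional symmetry along the second principal axis of
  the unit-weighted atom cloud: the fraction-entropy score
  $\gamma_2 = 1/(1+S_2)$ built from the number of atoms that have a mirror
  partner across the plane orthogonal to axis 2.
* **MAXDP** - the maximal positive Kier-Hall electrotopological perturbation
  $\max_i \Delta I_i$, a purely topological (2D) measure related to the
  molecule's electrophilicity.

The analysis path mirrors the published study: fit on all 19 compounds,
inspect the Williams plot (leverage vs standardized residual, warning
leverage $h^* = 3p'/n$), remove response outliers
($|\text{std. residual}| > 2$), and refit on the remaining compounds.
`qsar_reproduce()` runs this end to end.

## Intrinsic-state conventions (MAXDP)

The intrinsic state is $I = ((2/L)^2 \delta_v + 1)/\delta$ on the
hydrogen-suppressed graph, with perturbations
$\Delta I_i = \sum_j (I_i - I_j)/(d_{ij}+1)^2$ over topological distances.
Descriptor packages differ silently in the valence delta $\delta_v$ for
third-row-and-beyond atoms: the classic count $Z_v - h$ versus the screened
general form $(Z_v - h)/(Z - Z_v - 1)$. The two coincide for C, N, O and F
and differ only at sulfur here. We benchmarked both (plus H-inclusive
graphs, distance cutoffs and bond-order degrees) against the published MAXDP
of the trimethoxy compound **1g** (4.65): the screened form lands closest
(4.59, about 1.4% low), the classic form gives 4.51, and no documented
convention reproduces 4.65 exactly - a catalogue-specific detail of the
original descriptor software. The package therefore defaults to the screened
form and exposes `delta_v = "classic"` as a switch; the acceptance test for
this value is asserted at the printed two-decimal precision and records the
residual discrepancy rather than hiding it.

## Geometry: a deterministic force-field surrogate

The study optimised structures with a molecular-mechanics force field
followed by a semi-empirical quantum method. Neither a licensed modelling
suite nor a semi-empirical code is a reasonable dependency for a desk-scale
package, and the obvious substitute - OpenBabel's conformer-searching 3D
builder - is *nondeterministic*, which breaks reproducibility of every 3D
descriptor. `embed_mol()` instead uses a chain that is deterministic by
construction:

1. a 2D structure layout (OpenBabel `--gen2D`, deterministic and aware of
   the fixed Z-configuration of the benzylidene double bond);
2. scaling of the layout toward covalent bond lengths and a *seeded*
   Gaussian out-of-plane perturbation (sd 0.3 A) to break planarity;
3. MMFF94 steepest-descent minimisation (3000 steps), which is
   deterministic from a fixed start.

The same molecule and seed always give identical coordinates; embeddings
failing a covalent-geometry sanity gate (all bonded distances within
0.7-2.0 A) are retried from the next seeded perturbation.

Consequences, measured rather than assumed: geometry-robust quantities
(G2u of all spot-checked compounds; Mor29m of compounds **1c**, **1s**)
reproduce the published values within their stated tolerances, while the
published Mor29m of **1g** (-0.9) is *not* reachable - our chain gives about
+0.2, and independent ETKDG/MMFF conformers from a different toolkit give
0.17-0.21 across seeds. That value appears specific to the original
semi-empirical geometry. Bit-faithful reproduction of the published model
coefficients therefore requires the study's own supplementary descriptor
table, which `qsar_reproduce(descriptors = ...)` accepts as a CSV; with
computed descriptors the pipeline runs identically but lands on different
numbers, and the acceptance suite reports those comparisons honestly as
failures rather than relaxing them.

Hydrogens are explicit and participate in both 3D descriptor families, as
in the descriptor software family the study used; mass weights are scaled
by carbon so unit- and mass-weighted schemes coincide on pure-carbon
skeletons. The WHIM symmetry tolerance defaults to 0.15 A (the reference
software's value is undocumented; 0.15 A is of the order of the coordinate
noise a force-field refinement leaves between chemically equivalent atoms).
Degenerate principal axes are ordered lexicographically and sign-fixed so
G2u is reproducible; null-variance axes are reported fully symmetric.

## Model search

`prefilter_descriptors()` applies the standard reduction: constant columns
out, then pairs with $|r| > 0.85$ broken by dropping the member less
correlated with the response, scanning columns left to right. The scan
order matters to the survivor set, which is why it is fixed and documented.

`ga_select()` evolves fixed-length index-set chromosomes (subset size capped
at 3 for paper-style runs) with tournament selection (size 3), uniform
crossover (probability 0.8), per-gene mutation (0.05) and elitism (2), over
a population of 100 for up to 300 generations with a 50-generation stall
stop. Fitness is $Q^2_{LOO}$ of the subset's OLS fit, the cross-validated
orientation used when the original models were generated; fitness values
are memoised per subset, so on the pool sizes this package targets the GA
costs little more than the exhaustive enumeration `exhaustive_select()`
that serves as its oracle in the tests. None of these hyperparameters are
published values - they are this package's defaults, checked by the
property that the GA's optimum equals the exhaustive optimum on
12-descriptor pools.

## Validation statistics

`validate_model()` assembles the full statistic set: $R^2$, adjusted $R^2$,
regression standard deviation $s$ (denominator $n-p-1$), Fisher $F$,
training RMSE/MAE (denominator $n$; the two conventions are kept side by
side deliberately), Lin's concordance correlation (population 1/n variance
form), $Q^2_{LOO}$ with PRESS via the exact deleted-residual shortcut
$e_i/(1-h_{ii})$, leave-more-out $Q^2$ (default 30% out, 1000 iterations,
pooled over iterations so the singleton-group limit approaches
$Q^2_{LOO}$), Todeschini's K correlation indices on autoscaled columns,
Y-scrambling averages (default 2000 permutations; the null level of the
scrambled $R^2$ is $p/(n-1) \approx 0.17$ at $n = 19, p = 3$), and Roy's
$r^2_m$, computed on the LOO predictions by default (`rm2_on = "fitted"`
switches; the study does not say which it used).

`check_thresholds()` encodes the acceptance rules quoted for these models:
$R^2 \ge 0.7$, $R^2 - R^2_{adj} < 0.3$, $RMSE_{tr} < 0.3$,
$CCC_{tr} > 0.85$, $Q^2_{LOO} \ge 0.5$, $Q^2_{LMO} \ge 0.6$,
$RMSE_{tr} < RMSE_{cv}$, $r^2_m \ge 0.6$, $CCC_{cv} > 0.85$,
$R^2_{Yscr} < 0.2$, $Q^2_{Yscr} < 0.2$, and $\Delta K$ at or above 0.05.
The $\Delta K$ boundary is deliberately inclusive: published tables quote
0.05 at two decimals for a model described as passing, so the strict
reading would misclassify reports quoted at printed precision.

## Applicability domain

`williams_domain()` reports leverages (hat-matrix diagonal of the
intercept-augmented design), $h^* = 3p'/n$, and standardized residuals.
Standardization divides by the training RMSE by default; the
leverage-adjusted studentized form is a switch, since the original
software's choice is not documented. Both the raw and standardized
residuals are kept in the report because the published "greatest residual"
for the flagged compound is quoted on the raw scale.

## Synthetic data: what it emulates, what it does not

`synth_generate()` draws an equicorrelated Gaussian descriptor pool
($\rho$ default 0.2, configurable covariance accepted) and a linear
response $y = b_0 + X\beta + \varepsilon$. Defaults mirror the study's
shape: $n = 19$, three true descriptors among a pool of twelve, noise
sd 0.1 and a response centred near 1.35 so draws span roughly the 0.8-1.9
log-activity range. The equicorrelated structure is the simplest one that
exercises the prefilter and the K indices; it does not emulate the heavy
tails, blockwise redundancy, or descriptor-specific scaling of real
descriptor matrices, so passing recovery tests demonstrate correctness of
the pipeline, not field performance on real descriptor blocks.
`recovery_experiment()` (100 repetitions in the acceptance suite, about
two minutes) measures true-subset selection rate and coefficient bias; the
coefficient summary refits on the true subset every repetition so that
estimation error is assessed independently of selection.

## Numerical and degenerate-input choices

* OLS via QR; rank deficiency is an error naming the collinear columns,
  never a silent drop.
* The LOO shortcut refuses leverages numerically at 1 (a left-out refit
  would be singular) and names the offending row.
* A perfect fit (zero residuals) standardizes to all-zero residuals in the
  Williams report instead of 0/0.
* Y-scrambling reuses one QR of the fixed design for all permutations;
  permutations, LMO splits and the GA all consume explicitly passed seeds,
  and every stochastic stage records its seed in the run manifest.
* Problem sizes in the test suite are chosen for a desk machine: the
  heaviest single stages are the 19-compound descriptor computation
  (about 15 s, dominated by force-field minimisation) and the 100-rep
  recovery experiment (about 2 min).

## Known limitations

* 3D descriptor values depend on the geometry surrogate; they are suitable
  for method development and trend work, not for bit-faithful comparison
  with values from semi-empirically optimised structures (supply the
  original descriptor table for that).
* The intrinsic-state convention question above caps agreement of MAXDP
  with the published value at about 1.4%.
* No external validation statistics or training/test splitting are
  implemented: the study kept all compounds in training, and the package
  follows that scope.
* SMILES interpretation, 2D layout and force-field minimisation are
  delegated to OpenBabel; the package requires `obabel` on the PATH.
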