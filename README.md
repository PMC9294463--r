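# tzdqsar

QSAR modelling of thiazolidine-2,4-dione lipoxygenase inhibitors in R.

Nineteen (Z)-5-arylidene-thiazolidine-2,4-diones were screened for
inhibition of soybean lipoxygenase (LOX) at 100 uM; their activity spans
7.3-76.3% inhibition. tzdqsar packages that compound set and implements the
complete modelling chain around it, for QSAR practitioners and method
developers who want every stage scripted, seeded and tested:

* **Descriptors from structure** - Kier-Hall electrotopological `MAXDP`
  (topological), the 3D-MoRSE signals `Mor01u`-`Mor32m` (with `Mor29m`, the
  mass-weighted signal at s = 28 1/A), and the WHIM directional symmetries
  `G1u`/`G2u`/`G3u`/`Gu`, computed after a deterministic, seeded 3D
  embedding (OpenBabel 2D layout + seeded out-of-plane lift + MMFF94
  minimisation).
* **Model search** - descriptor prefiltering (constant columns out,
  pairwise |r| > 0.85 broken in favour of the stronger response correlate)
  and genetic-algorithm subset selection capped at three descriptors, with
  `Q2_LOO` fitness and an exhaustive-search oracle.
* **Validation** - the full internal statistic suite: R2, adjusted R2, s,
  F, RMSE/MAE (training and cross-validated), Lin's CCC, `Q2_LOO`/PRESS,
  leave-more-out `Q2`, Todeschini's Kxx/dK, Y-scrambling, Roy's r2m, and
  the published acceptance thresholds via `check_thresholds()`.
* **Applicability domain** - leverages, warning leverage h* = 3p'/n,
  standardized residuals and the Williams plot (`williams_domain()`,
  `autoplot()`).
* **Synthetic data** - `synth_generate()` / `recovery_experiment()` draw
  descriptor/activity sets with known ground truth so the whole pipeline is
  testable without any download.

The central model form is an ordinary least-squares regression on the
decimal-log activity,

    log(% LOX inh.) = b0 + b1*Mor29m + b2*G2u + b3*MAXDP

fit on all 19 compounds, screened for outliers on the Williams plot, and
refit after exclusion.

## Worked example

```r
library(tzdqsar)

cmp <- tzd_compounds()
cmp[1:4, c("id", "lox_inh_pct", "log_lox")]
#>   id    lox_inh_pct log_lox
#> 1 1a           13.8   1.14
#> 2 1b            8.5   0.929
#> 3 1c           76.3   1.88
#> 4 1d           27.2   1.43

# the least active compound: 5-(3,4,5-trimethoxybenzylidene)thiazolidine-2,4-dione
mol <- mol_from_smiles(cmp$smiles[cmp$id == "1g"], id = "1g")
mol
#> <mol_graph 1g: 33 atoms (20 heavy), 34 bonds, no coordinates>
maxdp(mol)           # topological, no geometry needed
#> [1] 4.59
emb <- embed_mol(mol, seed = 1)
morse_signal(emb, 28, "mass"); g2u(emb)
#> [1] 0.243
#> [1] 0.165
```

`maxdp` is highest for this compound across the whole set, and it is the
least active - the descriptor enters the model with a negative coefficient.

Model search and validation on a synthetic set with known truth (three
active descriptors planted in a pool of twelve):

```r
dat    <- synth_generate(synth_spec(seed = 42))
filt   <- prefilter_descriptors(dat$descriptors, dat$y)
ranked <- ga_select(filt, dat$y, max_size = 3, seed = 42)
fit    <- fit_mlr(dat$data, "y", ranked$subset[[1]])
fit
#> <mlr_model: y = 1.339 +0.259*D01 +0.202*D02 -0.227*D03  (n = 19)>
```

The GA recovered exactly the planted subset (D01-D03, true coefficients
1.35, 0.25, 0.20, -0.20). Validation and domain analysis:

```r
v <- validate_model(fit, seed = 1)
v[v$statistic %in% c("R2", "Q2_LOO", "R2_Yscr"), ]
#>   statistic value
#> 1 R2        0.938
#> 2 Q2_LOO    0.907
#> 3 R2_Yscr   0.168     # chance level ~ p/(n-1) = 0.17
attr(check_thresholds(v), "verdict")
#> [1] TRUE
ad <- williams_domain(fit)
attr(ad, "h_star")
#> [1] 0.632             # 3 * 4 / 19
autoplot(ad)            # Williams plot
```

The published analysis path on the real compounds is one call -
`qsar_reproduce()` - which fits the full-set model, flags Williams-plot
outliers, refits without them, and returns both validation reports plus the
run manifest. Supply the study's supplementary descriptor table as a CSV
(`qsar_reproduce(descriptors = "path.csv")`) for bit-faithful coefficients;
with package-computed descriptors the same pipeline runs on the
force-field-surrogate geometries (see the vignette for what does and does
not transfer).

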