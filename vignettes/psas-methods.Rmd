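---
title: "Solubility-ratio slopes as pairwise amino-acid interaction indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Solubility-ratio slopes as pairwise amino-acid interaction indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psas)
```

## The measurement and the model

Classical amino-acid scales are one-body properties: how a residue behaves
in water or inside a fold. Phase behavior of proteins — droplets via
liquid–liquid phase separation, aggregates via liquid–solid separation —
is instead governed by two-body interactions between side chains. The
assay modeled here probes one such pair directly: an aromatic amino acid
(Tyr, Trp or Phe) is dissolved to saturation in buffer containing a second
free amino acid (the *solvent*) at a series of molar concentrations, and
the saturation solubility is read spectrophotometrically (260–280 nm)
through a per-solute standard curve.

Writing $s(c)$ for the saturation solubility at solvent concentration $c$
and $s_0 = s(0)$ for the plain-buffer baseline, the interaction index of
the (solute, solvent) pair is the slope of the solubility ratio:

$$\mathrm{PSAS} \;=\; \frac{\Delta\,(s/s_0)}{\Delta c}
\qquad [\mathrm{M}^{-1}],$$

i.e. the fractional change in solubility produced by 1 M of the solvent
amino acid. Positive slopes are *soluble* interactions (the solvent
amino acid recruits the aromatic into solution — the microscopic analogue
of the water-mediated contacts inside a droplet); negative slopes are
*insoluble* interactions (co-precipitation or charge repulsion — the
analogue of aggregate contacts); slopes near zero mean the pair interacts
about as weakly as with water.

The estimator treats the ratio curve as linear over the whole usable
concentration range. Real curves can bend at the extremes; the simulator
can generate such curvature (see below) but the estimator deliberately
does not model it, fitting one slope to all points.

## Estimation choices

**Fixed versus free intercept.** The ratio at $c = 0$ is 1 *by
definition*, so the default fit (`mode = "fixed"`) pins the intercept at 1
and estimates the through-origin least-squares slope of $(r_i - 1)$ on
$c_i$, in closed form $\sum_i c_i (r_i - 1) / \sum_i c_i^2$. A free
intercept (`mode = "free"`, ordinary least squares) is offered as a
robustness check for cases where the baseline measurement itself is
suspect. Standard errors use the usual linear-model formulas; the fixed
mode reports the uncentered $R^2$ customary for through-origin
regressions.

**Aggregation.** Replicates are averaged per concentration before
fitting, unweighted. This is the simplest defensible choice; weighting by
replicate count or inverse variance would only matter for strongly
unbalanced designs, which the simulator does not produce.

**Classification threshold.** "Near zero" needs a cutoff to become a
class. `classify_interaction()` uses a symmetric neutral band
$|\mathrm{PSAS}| \le \tau$ with $\tau = 0.05\,\mathrm{M}^{-1}$ by default
(a 5% solubility change per molar — roughly the smallest effect a bench
assay with a few replicates can distinguish from baseline noise). The
threshold is a reporting convention, not a fitted quantity; every function
that uses it takes it as an argument.

**Degenerate inputs.** A curve needs two distinct concentrations to have
a slope; all-baseline curves are flagged `unfittable` and refuse to fit.
A non-positive baseline mean is an error (the ratio is undefined), as is a
missing baseline unless an external water solubility is supplied. Rank
correlations of constant vectors are reported as errors, never silently
zero; `consistency_report()` downgrades them to `NA` with a note so one
flat profile cannot sink a whole report. Ranking ties break by the fixed
canonical row order of the bundled table, and tied solutes in ordering
strings render alphabetically (`"Phe=Trp=Tyr"`), so all outputs are
deterministic.

## What the simulator emulates — and what it does not

`simulate_assay()` draws records from

$$s = s_0\,\bigl(1 + \beta c + \gamma c^2\bigr) + \varepsilon,
\qquad \varepsilon \sim N\!\bigl(0, (\sigma s_0)^2\bigr),$$

truncated at zero (flagged when truncation fires), where $\beta$ is the
scenario's true slope matrix, $\gamma$ an optional curvature stressor
(zero by default), and $\sigma$ the relative replicate noise.

Defaults, chosen once as a plausible bench design: 5 concentration levels
per solvent spanning $[0, c_{\max}]$ including the 0 M baseline, 3
replicates per level, $\sigma = 0.05$. Solute baselines $s_0$ are the
bundled water solubilities of Tyr, Trp and Phe. Per-solvent ceilings
$c_{\max}$ derive from each solvent's own water solubility through a
single documented constant (`solvent_cmax()`: printed value read as
g/100 mL, times 10, over a nominal 125 g/mol — i.e. $0.08 \times$ the
printed number, in M). The real ceilings vary enormously between amino
acids and that variation is the point: solvents like Tyr (sparingly
soluble) allow only millimolar ranges, and slopes fitted there are
intrinsically noisy, exactly as at the bench.

The `paper_like` scenario encodes the qualitative structure reported for
the real assay — which solvents solubilize (Tyr, Trp, Phe, Arg, His, Pro,
with the aromatic solvents strongest), which insolubilize (Glu and Asp
most strongly; Gln, Asn and the hydrophobics moderately), which are
neutral (Gly, Ser, Thr, Lys), and the within-solvent solute orderings
(Trp > Tyr > Phe in solubilizing solvents; Phe > Trp > Tyr in the
anionic/amide insolubilizers, following water solubility;
Trp > Phe > Tyr in the hydrophobic ones, following side-chain
hydrophobicity). The *magnitudes* are package defaults: the source assay
published its slope matrix only as a color map, so no numeric ground
truth exists to copy, and the package asserts only signs and orderings.
Passing tests therefore show that the pipeline recovers structure it
generated itself under a realistic noise model — not that these are the
laboratory values.

Not emulated: the thermal/centrifugation protocol (saturation is assumed
reached), solvent-effect artifacts of extremely concentrated cosolutes
(the real Pro solvent reaches molar viscosities where "solvent amino
acid" and "changed solvent" blur), pH/buffer coupling, and any
concentration-dependent change of interaction mechanism.

## Problem sizes used in the checks

The packaged checks run the full 3 × 20 grid noiselessly (agreement with
ground truth to $10^{-9}$), 100 random small curves against a brute-force
grid-search minimizer of the residual sum of squares ($10^{-6}$), $10^4$
noisy curves for estimator bias at a true slope of 0.5 M$^{-1}$ (observed
bias $\sim 10^{-3}$, bound 0.02), 100 seeded noisy grid runs for
sign-class recovery (observed ≈ 95%, bound 90%), and exhaustive
pair-counting oracles for the rank statistics on a fixed pool of short
vectors ($10^{-12}$).

## Sequence profiling

`profile_index()` applies any scale — bundled or fitted via
`add_scale()` — in the classic sliding-window manner: the score at
1-based center $i$ is the mean scale value of the $w$ residues in the
window ($w$ odd), giving $L - w + 1$ scores. Windows containing
non-canonical residues are skipped (`NA`), not imputed. This is a
convenience for exploring slope-derived scales as sequence features, not
a phase-separation predictor: free amino acids and residues in a chain
are not interchangeable (Trp carries a large positive slope yet is rare
in disordered regions; Gly and Ser are near-neutral yet abundant there),
so per-window averages of these scales must be read as hypotheses, not
predictions.

## Known limitations

* Slope magnitudes in `paper_like` are invented defaults; only the sign
  and ordering structure is anchored.
* The molar conversion inside `solvent_cmax()` uses one nominal molar
  mass for all residues; per-residue masses would shift ceilings by
  ±30%. Override `cmax` where real limits are known.
* The estimator is strictly linear; systematic curvature biases the
  fitted slope toward the average local slope over the sampled range.
* With the default design, slopes in very-low-ceiling solvent columns
  (notably Tyr) have standard errors comparable to the slopes themselves;
  classification there is unreliable at realistic noise — a property of
  the assay geometry, not of the estimator.
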