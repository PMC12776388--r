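# cellnp

Neyman–Pearson analysis of cellular decision making from single-cell
signaling responses.

## What problem this solves

Cells read noisy internal signals to decide between external conditions —
for the TNF–NF-κB pathway, whether the TNF dose at the receptor is low or
high, judged from the nuclear NF-κB concentration of a single cell.  Because
the prior probability of either dose is biologically unknowable, the natural
framework is Neyman–Pearson (NP) detection: among all decision rules with a
given false alarm probability `P_FA` (declaring "high dose" when the dose is
low), the likelihood-ratio test maximizes the detection probability `P_D`
(declaring "high dose" when it is high).  `cellnp` turns tables of per-cell
measurements into these decision metrics: optimal thresholds, `P_D` at a
chosen `P_FA`, full ROC curves, and their degradation in heterogeneous
(wild-type / knockout mixed) populations.  It is aimed at quantitative
systems biologists who want a compact, prior-free score of how well a
signaling pathway transmits dose information, and how perturbations (e.g.
loss of the A20 negative feedback) blunt it.

## The statistic at the core

Log responses are modeled as Gaussian under each hypothesis,
`Y ~ N(mu, Sigma)` under `H0` and `Y ~ N(eta, Theta)` under `H1` (one
coordinate per measurement time).  Whitening `H0` and diagonalizing the
transformed `H1` covariance (`Sigma = U D U'`,
`C = D^{-1/2} U' Theta U D^{-1/2} = V Lam V'`) reduces the pair to
`N(0, I)` vs `N(m, diag(lambda))`, where the log-likelihood ratio is
monotone in the quadratic statistic

    Z = sum_i [ x_i^2 - (x_i - m_i)^2 / lambda_i ] .

The distribution of `Z` under either hypothesis has a closed-form
characteristic function; `cellnp` inverts it numerically via the Gil-Pelaez
formula to get the CDF, solves `P_FA = 1 - F_Z(z_th; H0) = alpha` for the
threshold, and reports `P_D = 1 - F_Z(z_th; H1)`.  For mixed populations the
class-conditionals become genotype mixtures, the likelihood ratio is
thresholded directly, and error probabilities are computed by deterministic
quadrature over the decision region.  A Monte Carlo module independently
re-estimates every probability for verification, and a calibrated
synthetic-data generator (lognormal responses, Hill-type dose response,
genotype and feedback structure) stands in for unavailable experimental
data.

## Worked example

```r
library(cellnp)
cfg <- default_scenario()               # synthetic study conditions
tab <- generate_dataset(cfg)            # 14,000 cells, wide layout
rep <- cmd_detect(tab, "WT,0.0052,30/240", "WT,50,30/240", alpha = 0.1)
```

```
 variant N                m          lambda      z_th pfa       pd       pm
   30min 1          2.54927        0.884085 -0.175452 0.1 0.911214 0.088786
  240min 1          1.46355         1.08489  1.611840 0.1 0.569354 0.430646
   joint 2 0.450534/2.61169 1.12422/0.88136 -0.360911 0.1 0.927028 0.072972
```

Reading: discriminating 0.0052 from 50 ng/mL TNF in wild-type cells at
`P_FA = 0.1`, the 30-minute readout alone detects the high dose with
probability 0.91; by 4 hours negative feedback has attenuated the response
and `P_D` drops to 0.57; using both time points jointly (`N = 2`) is best,
0.93.  `m` and `lambda` are the canonical effect sizes and variance ratios;
`z_th` is the optimal threshold on `Z`.

Mixing in A20-knockout cells degrades detection monotonically — at a 50/50
mix the joint `P_D` falls from 0.93 to 0.80, and for pure knockout to 0.67:

```r
sw <- cmd_mixture_sweep(tab, doses = c(0.0052, 50), beta_grid = c(0, 0.5, 1))
subset(sw, mode == "fixed_alpha" & variant == "joint")
#>    beta variant        mode pfa        pd alpha_or_target
#> 13  0.0   joint fixed_alpha 0.1 0.9270277             0.1
#> 14  0.5   joint fixed_alpha 0.1 0.7997054             0.1
#> 15  1.0   joint fixed_alpha 0.1 0.6734327             0.1
```

See `vignettes/np-cellular-decisions.Rmd` for the model, the numerical
design of the Gil-Pelaez inversion and mixture quadrature, and what the
synthetic generator does and does not emulate.

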