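# oscifit

Automated, regularised parameter estimation for nonlinear ODE models of
biological oscillators.

## The problem

Fitting a deterministic oscillator model

$$\dot{\mathbf x} = \mathbf f(t, \mathbf x, \boldsymbol\theta), \qquad
  \mathbf y = \mathbf g(\mathbf x, t, \boldsymbol\theta), \qquad
  \mathbf x(t_0) = \mathbf x_0$$

to noisy time courses by weighted nonlinear least squares,

$$Q_{NLS}(\boldsymbol\theta) = \sum_{k}\sum_{j}\sum_{i}
  \left(\frac{y_{kji} - \tilde y_{kji}}{\sigma_{kji}}\right)^2
  = \mathbf r^\top \mathbf r,$$

is notoriously treacherous: the bounds are huge when prior knowledge is
scarce, the cost surface of an oscillating model is highly multimodal (a
local solver — even multi-started — converges to whichever local optimum is
nearest), the flexible dynamics fit the noise instead of the signal, and
parameters compensate one another. `oscifit` is for modellers who want a
hands-off workflow that confronts all four pitfalls:

1. **Phase 1** — global minimisation of $Q_{NLS}$ with an enhanced scatter
   search (Latin-hypercube diversification, reference-set recombination,
   sensitivity-fed trust-region local refinement), archiving every
   evaluated parameter vector with its cost;
2. **bounding** — per-parameter cost cut-offs from the archive (knee of
   the spread-versus-cost curve) tighten the search box;
3. **regularisation tuning** — a Tikhonov penalty
   $\Gamma(\boldsymbol\theta) = (\boldsymbol\theta -
   \boldsymbol\theta^{ref})^\top W^\top W (\boldsymbol\theta -
   \boldsymbol\theta^{ref})$ with $W = \mathrm{diag}(1/\theta^{ref}_i)$ is
   configured automatically from the archive ($\theta^{ref}$ = consensus of
   the good-fit samples, $\alpha$ = acceptable cost degradation divided by
   the penalty span);
4. **Phase 2** — global minimisation of $Q_R = Q_{NLS} + \alpha\Gamma$
   inside the reduced box;
5. **post-fit** — FIM-based confidence intervals and correlations, NRMSE /
   $R^2$ / $\chi^2$, cross-validation of both estimates on held-out
   experiments, and a collinearity-based practical-identifiability report.

Four classic case studies ship ready to run (`caseStudy()`):
FitzHugh-Nagumo, the Goodwin oscillator, the Repressilator and an
enzymatic oscillator, together with a synthetic-data generator that
reproduces their published measurement protocol (10% signal noise,
detection threshold 0.1, 10 fitting + 10 cross-validation replicates).
Custom models are declared in a small plain-text format
(`parseModelText()`).

## A worked example

Recover the FitzHugh-Nagumo parameters $\{a, b, g\} = \{0.2, 0.2, 3\}$
from a noisy synthetic experiment, with no prior knowledge beyond the
bounds $[10^{-5}, 10^5]$:

```r
library(oscifit)

fhn <- caseStudy("fhn")
cfg <- dataGenConfig(fhn, seed = 101)       # 6 points, 10% noise
fits <- generateFittingData(fhn, cfg)       # 10 replicate experiments
cv   <- generateCrossvalData(fhn, cfg)      # 10 held-out experiments

res <- oscifit(fhn, fits[[1]], crossval = cv,
               control = oscifitControl(phase1_evals = 6000,
                                        phase2_evals = 3000, seed = 42))
res
```

```
<oscifit_result> model 'fhn'
   phase1 regularised     ref
a 0.74036     0.74036 0.74036
b 0.25381     0.25381 0.25381
g 1.61250     1.61250 1.61250
  Q_NLS: phase1 124.02 | regularised 124.02
  alpha = 0
  fit NRMSE: phase1 0.2621 | regularised 0.2621
  crossval NRMSE: phase1 0.2310 | regularised 0.2310
  collinearity: 2 flagged subset(s) at threshold 20
```

Reading the output: a single experiment of six noisy points, with
sub-threshold values reported at the detection limit, is deliberately
meagre — the estimate lands in a well-fitting basin that is not the
generating one (fitting NRMSE 0.26; this mirrors the reference study,
whose regularised single-experiment estimate also sits away from the
nominal values at a comparable fitting NRMSE), and the cross-validation
NRMSE shows it still predicts the ten held-out experiments decently. In
this run the accepted archive samples collapsed onto one point, so the
tuner set `alpha = 0` and phase 2 changed nothing — with richer data the
penalty becomes active (see the test suite). `res$reduced_bounds` holds
the tightened box the archive analysis produced, `res$fit_stats_R` the
confidence intervals and coefficients of variation, and
`res$collinearity` the practical-identifiability report, which here flags
two compensating parameter pairs at the biased estimate. On noise-free
data (30 points, censoring off) the same pipeline recovers `a` and `g`
essentially exactly.

A thin command-line wrapper over these functions is installed at
`inst/cli/oscifit-cli.R` (`generate`, `fit`, `simulate`, `report`
subcommands).

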