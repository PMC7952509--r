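# icrgmm — residual-based class enumeration for growth mixture models

Growth mixture models ask whether a population measured repeatedly over
time (symptom scores, substance use, learning outcomes, biomarkers) hides
subgroups that follow distinct developmental trajectories, and how many.
Conventional practice fits mixtures at several class counts and lets the
analyst adjudicate among AIC/BIC/likelihood-ratio indices that routinely
disagree. `icrgmm` implements the alternative, fully algorithmic route:
classes are discovered by clustering *individual case residuals* (ICRs),
and the number of classes is decided directly from the residual structure.

For a two-factor latent growth curve model with loading matrix Λ, factor
means η, factor covariance Ψ and diagonal residual covariance Θ,

    μ = Λη,    Σ = ΛΨΛ′ + Θ,

the package fits the model by normal-theory maximum likelihood, scores
individuals with Bartlett factor scores
η̂ᵢ = η̄ + (Λ′Θ⁻¹Λ)⁻¹Λ′Θ⁻¹(yᵢ − μ), and forms per-factor ICRs ε as the
residuals of each occasion regressed on each factor score within a class.
The closeness of individual *i* to class *k* is

    CM_ik = A_ik / ( Σᵢ A_ik / (N − 2) ),
    A_ik  = Σⱼ Σₜ ε²_itjk / com(η_jk, y_tj),

with communalities `com` (squared score–occasion correlations) as weights;
every column of the CM matrix sums to N − 2. Individuals are iteratively
reassigned to their smallest CM_ik until fewer than 5% move, and candidate
class counts proposed by Ward clustering of the global-model ICRs are
accepted while they reduce the mean within-class closeness by more than a
calibrated relative threshold. A Monte Carlo engine generates K-class
mixtures of linear trajectories with controlled Mahalanobis class
separation, and a study harness estimates correct-enumeration rates over a
design grid. The methods vignette
(`vignettes/residual-based-enumeration.Rmd`) documents the model, the
calibration of the selection threshold, and the identifiability limits of
the severe low-separation design the harness targets.

## Worked example

```r
library(icrgmm)

# two latent classes, 540 individuals, well separated (MD = 5)
sim <- simulate_growth_mixture(
  simulation_design(model = 1, K = 2, N = 540, md = 5), seed = 7)
res <- enumerate_classes(sim$y, growth_spec(4), K_max = 5)
res
#> Residual-based class enumeration
#>   selected number of classes: 2
#>  K          W      drop converged effective_K accepted
#>  1 131.384353        NA      TRUE           1     TRUE
#>  2  11.419812 0.9130809      TRUE           2     TRUE
#>  3   9.144944 0.1992036      TRUE           3    FALSE

res$partition$models[[1]]
#> Fitted latent growth curve model (linear, T = 4, N = 268)
#>   logLik -1016.223   discrepancy F = 0.00879784   converged: TRUE
#>   eta: intercept 1.0172  slope 0.3114
#>   psi: var(i) 0.2474  var(s) 0.0300  cov -0.0023
#>   theta: 0.1333 0.2195 0.2308 0.3205
```

The diagnostics table shows the scan over candidate class counts: the
two-class partition cuts the mean within-class closeness `W` by 91% and is
accepted; a third class would improve it by only 20%, below the acceptance
threshold, so scanning stops and `k_hat = 2`. The first local model
recovers the generating parameters of its class (intercept mean 1.0, slope
0.3, Ψ ≈ diag(0.25, 0.04), Θ ≈ (0.15, 0.20, 0.20, 0.35)) from the 268
individuals assigned to it.

A command-line front end wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","icrgmm.R",package="icrgmm"))')" \
  simulate --model 1 --k 2 --n 180 --md 5 --seed 7 --out data.csv
Rscript "$(Rscript -e 'cat(system.file("cli","icrgmm.R",package="icrgmm"))')" \
  enumerate --input data.csv --loading linear --kmax 5 --out result.json
```

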