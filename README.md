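# contactmix

Unsupervised Bayesian classification of molecular conformational states
from binary contact features.

## The problem

Molecular simulations produce thousands of structure snapshots, and the
question "how many distinct conformational states are here, and which
frame belongs to which?" has no labels to learn from.  `contactmix`
answers it from a single statistical hypothesis: a conformational state is
defined by the set of point-to-point contacts it forms.  Frames are
reduced to bit vectors of pairwise contacts (for proteins, C-alpha pairs
within 5 Å) and modelled as a **Bernoulli mixture** with an unknown number
of categories `K`:

```
P(x, z | θ) = Π_k π_k^{N_k} Π_j μ_kj^{N_kj} (1 − μ_kj)^{N_k − N_kj},
θ = (K, π, μ)
```

Each category `k` is a prototype vector `μ_k` of contact probabilities.  A
symmetric `Dirichlet(α)` prior with `α = M + 1` (`M` = number of
informative contacts) makes the inferred `K` insensitive to the level of
structural detail, and a uniqueness prior `Π_{k<l} (1 − B(μ_k, μ_l))` —
`B` the Bhattacharyya coefficient, equal to 1 exactly for identical
prototypes — gives zero prior mass to redundant categories.  The full
posterior over `(K, π, μ, z)` is sampled by MCMC with four move types:
Gibbs recategorization, conjugate reclassification, and reversible
category split/join moves accepted through ratios of the analytically
collapsed marginal likelihood.  See the vignette
(`vignettes/conformational-states.Rmd`) for the complete model and
sampler description.

Intended users: anyone with an ensemble of structures — molecular
dynamics trajectories, geometric toy systems, or any time series that can
be binarized into slowly varying features — who wants state assignments,
state prototypes, and a posterior over the number of states.

## Worked example

The built-in `chomp` benchmark is a closing 2D hinge of 18 points whose
cross-arm contacts switch on in order of distance from the hinge; because
the motion is monotone in time, classification quality can be scored by
how well categories form contiguous runs of frames.

```r
library(contactmix)

spec <- system_spec("chomp", P = 18, N = 1000, noise_sigma = 0.1, seed = 7)
sys  <- gen_system(spec)           # trajectory + pruned contact features
sys$features
#> <feature_matrix> 1000 frames x 46 contacts (cutoff 2, pruned)

post <- run_ensemble(sys$features, sampler_config(seed = 42))
post
#> <cmix_posterior> 250 samples from 5 chains; occupied K in [4, 4] (mode 4);
#>   split/join acceptance 0.3%

acc <- accuracy_summary(post)
sprintf("mean left %.1f%%, mean right %.1f%%", acc$mean_left, acc$mean_right)
#> "mean left 90.8%, mean right 100.0%"

k_histogram(post)
#>   4
#> 250

best <- best_theta_per_k(post)
representative_frames(sys$features, best[[1]]$theta)
#> [1] 970  86 774 886
```

Reading the output: the sampler settles on 4 occupied categories for all
250 pooled draws; the *left* accuracy (100 minus the percent of frames
whose label differs from the previous frame, after crediting the `K − 1`
required transitions) is 90.8%, and the *right* accuracy (which also
excuses oscillation between categories adjacent on the dominant category
path) is 100% — the categories are contiguous time blocks up to boundary
flicker.  `representative_frames()` names one frame per category with the
highest membership probability; here the four representatives sit in four
different stretches of the motion.  At `P = 222` the same protocol
reaches a mean left accuracy of about 98%.

## Command-line workflow

```sh
exec/contactmix simulate  --system glob --points 222 --frames 1000 --sigma 0.1 \
                          --seed 7 --out glob.rds --xyz glob.xyz
exec/contactmix featurize --input structure.pdb,traj.dcd --ca-only --cutoff 5.0 \
                          --out features.rds --pairs pairs.txt
exec/contactmix fit       --features glob.rds --chains 5 --steps 1000 \
                          --burn-in 500 --thin 10 --eta 0.9 --seed 42 \
                          --out posterior.rds
exec/contactmix evaluate  --posterior posterior.rds --features glob.rds \
                          --report report.json
```

Every command writes a `<output>.manifest.json` with the fully resolved
configuration, package version and seeds; rerunning a manifest's flags
reproduces its outputs bit-identically.

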