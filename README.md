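# mitoscaling

Mitochondria arrange into networks of clusters that continuously fragment
and fuse. A long-standing hypothesis holds that cells tune fission-fusion
rates so the network sits near the critical point of a percolation phase
transition. If that is true, network observables must show *finite-size
scaling*: their peak values must grow as power laws of system size, with
critical exponents that identify a universality class.

`mitoscaling` implements the full toolchain for testing that hypothesis:

* **Two stochastic models of mitochondrial dynamics.** An agent-based
  (AB) mean-field model — `Ne` indivisible edge-units whose endpoints form
  junctions of degree k ∈ {1,2,3}, evolving by Gillespie dynamics over the
  mass-action reactions `2X1 <-> X2` (tip-to-tip, rates a1/b1) and
  `X1 + X2 <-> X3` (tip-to-side, rates a2/b2, b2 = (3/2)b1, controls
  ci = ai/bi) — and a spatially-explicit (SE) model: an L×L periodic
  lattice with anisotropic bond updates (a random node's left *and* right
  bonds set jointly with probability p1, its column bond with p2). Both
  simulators are compiled (Rcpp).
* **Percolation observables** from cluster censuses: order parameter
  ⟨Ng/N⟩, second-largest cluster ⟨N2⟩, mean cluster size
  ⟨s⟩ = Σ′s²nₛ / Σ′s·nₛ (susceptibility proxy; primed sums exclude the
  largest cluster), fluctuation susceptibility
  χ = ⟨N⟩[⟨(Ng/N)²⟩ − ⟨Ng/N⟩²], and the cluster-size CCDF
  Nc(s) = Σ′ₛ′≥ₛ nₛ(s′).
* **Finite-size scaling machinery**: control-parameter sweeps,
  pseudo-critical point location (argmax of ⟨s⟩ with quadratic
  refinement), the scaling-law fits ⟨s⟩|max ∼ N^(γ/νd) and
  ⟨N2⟩|max ∼ N^(d_f/d), a calibrated estimator of the Fisher exponent τ
  from Nc(s) ∼ s^−(τ−1) e^(−s/s\*) (with an optional small-size cutoff
  s0), and universality-class assignment against the mean-field
  (5/2, 1/3, 2/3), 3D (2.15, 0.67, 0.84) and 2D (187/91, 43/48, 91/96)
  reference triples.
* **An image pipeline** for fluorescence mask images: global thresholding,
  8-connectivity pixel-mass censuses (no skeletonization), multi-threshold
  error propagation, mass-ranked group CCDFs, and sliding-window scaling
  fits ⟨N2⟩ ∼ N^ω1, ⟨s⟩ ∼ N^ω2, χ ∼ N^ω3 with mass as the system-size
  proxy.
* **Synthetic generators** that give every stage a ground truth: power-law
  censuses with exponential cutoffs, critical random graphs (the exact
  τ = 5/2 mean-field oracle), and rendered mask images with known
  cluster masses.

## Worked example

A reduced finite-size scaling study of the SE model (four lattice sizes,
ten realizations per grid point; about ten seconds):

```r
library(mitoscaling)

run <- se_simulate(64, p1 = 0.25, p2 = 0.7, seed = 1)
run
#> <se_run> L=64 (N=4096), 10 samples, p1=0.25 p2=0.7, <Ng/N>=0.509

study <- se_fss_study(L_values = c(24, 32, 48, 64),
                      grid = seq(0.14, 0.38, by = 0.03),
                      p2 = 0.7, n_realizations = 10, seed = 7, n_boot = 20)
study$sizes
#>    L    N p1_star  s_max N2_max unbracketed
#> 1 24  576  0.1849  32.77  82.99       FALSE
#> 2 32 1024  0.2073  53.39 141.07       FALSE
#> 3 48 2304  0.2262  88.29 255.36       FALSE
#> 4 64 4096  0.2322 155.88 469.15       FALSE

study$fit_g_nu_d
#> <scaling_fit> [gamma/(nu d) (peak <s> ~ N)] exponent = 0.7696 +/- 0.0476 (n=4, R2=0.992, range [576, 4096])
study$fit_df_d
#> <scaling_fit> [d_f/d (peak <N2> ~ N)] exponent = 0.8610 +/- 0.0420 (n=4, R2=0.995, range [576, 4096])
study$fit_tau
#> <ccdf_fit> tau = 1.850 +/- 0.006 (slope -0.850), s0 = 1, s* = 235, 101114 clusters
round(study$classification$distances, 3)
#> Mean-Field Percolation         3D Percolation         2D Percolation
#>                  0.807                  0.317                  0.256
study$classification$class
#> [1] "2D Percolation"
```

Reading the output: the pseudo-critical point `p1_star` drifts upward and
the peaks of ⟨s⟩ and ⟨N2⟩ grow with lattice size — the finite-size
signature of criticality. The fitted exponent triple
(τ = 1.85, γ/νd = 0.77, d_f/d = 0.86) sits nearest the 2D-percolation
reference (2.055, 0.896, 0.948); at these very small lattices the
exponents still carry visible finite-size bias, which shrinks as sizes
grow (see the full-size study below). A measured triple can be classified
directly, e.g. `classify_universality(2.01, 0.82, 1.01)` for an
image-derived (τ′, ω1, ω2/ω3) triple, which also lands on 2D percolation.

## Analysis workflow

The `analysis/` directory holds the study as numbered, self-contained
stages, each writing its tables under `results/`:

1. `01_phase_transition.R` — locate the transition in both models (sweep
   curves for ⟨Ng/N⟩, ⟨N2⟩, ⟨s⟩, χ).
2. `02_se_fss.R` — SE-model finite-size scaling at
   N ∈ {1024, 4096, 16384, 50176}: peak scaling fits, pooled critical
   CCDF, universality assignment.
3. `03_ab_fss.R` — AB-model scaling (scaled-down design): c2\*(Ne) drift,
   two-cutoff CCDF fits, cutoff scaling with Ne.
4. `04_image_scaling.R` — the image pipeline on a synthetic mass-ranked
   ensemble: group CCDFs, sliding-window ω exponents.

Run any stage from the repository root, e.g.
`Rscript analysis/02_se_fss.R`.

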