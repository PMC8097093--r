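# coadapt

Simulation of user–interface co-adaptation in body-machine interfaces.

A body-machine interface (BoMI) maps a high-dimensional stream of body
signals — e.g. eight inertial-sensor orientation channels at 50 Hz — to a
low-dimensional device command such as a 2-D cursor position through a linear
orthonormal-row map *B* (m = 2 < n = 8). A first-time user must discover
which directions of their own variability the interface transmits; an
adaptive interface can meet them halfway by re-estimating its map from the
statistics of the user's behavior. `coadapt` simulates this two-learner
system without any task model, for researchers studying sensorimotor
learning, interface calibration and co-adaptive decoding policies.

## The model in brief

**User** — a non-stationary Gaussian generative process
q<sub>k</sub> ~ N(μ<sub>k</sub>, Σ<sub>k</sub>), smoothed into dependent
trajectories s<sub>k</sub> = α s<sub>k−1</sub> + β q<sub>k</sub>
(α = 0.99, β = 0.15). Each action earns the reward
r<sub>k</sub> = ‖B s<sub>k</sub>‖² / ‖s<sub>k</sub>‖² ∈ [0, 1] — the fraction
of signal power transmitted through the map — and the covariance
eigenstructure is updated by reward-weighted candid covariance-free
incremental PCA (CCIPCA) with effective rate η<sub>k</sub> = η·r<sub>k</sub>
(use-dependent learning). A variance-regularization step keeps the task-dimension
vigor constant and the model genuinely two-dimensional, preventing the
vanishing-variance and line-collapse degeneracies of pure recursive updating.

**Interface** — the same incremental PCA, unsupervised (rate γ, no reward),
tracking the top-m subspace of the observed user signals; the exposed map is
re-orthonormalized after every update. With γ = 0 the loop reduces exactly
to user-only learning against a static map.

**Metrics** — Planarity (λ₍₁₎+λ₍₂₎)/tr(Σ); Subspace Angle (largest principal
angle between the map and the user's top-2 covariance subspace, 0° = aligned);
VAF = tr(BΣBᵀ)/tr(Σ)·100 (equal to 100× the expected reward for a centered
model); and the time constant of the best-fitting exponential relaxation of
the angle trace (R² ≥ 0.40 inclusion gate).

## Worked example

```r
library(coadapt)

set.seed(42)
ref <- make_reference_init()   # synthetic reference: planarity 0.65, 60 deg misalignment
cfg <- simulation_config(mode = "coadapt", eta = 1.3e-3, gamma = 1.3e-3)

set.seed(1)
run <- run_coadaptation(cfg, ref$map, ref$state)
run
#> <coadapt_run> mode = coadapt , K = 40000 , eta = 0.0013 , gamma = 0.0013
#> final (last 200 iters): planarity 0.900, angle 2.45 deg, VAF 89.9%, reward 0.819

fit_convergence(run$series$angle_deg, run$series$iteration)
#> <convergence_fit> tau = 1925.1, theta0 = 78.73, theta_inf = 1.91, R^2 = 0.925
```

Starting 60° apart, the equal-rate dyad converges to a shared subspace
(final angle 2.45°) with ~90% of the user's variance transmitted; the
exponential fit puts the convergence time constant near 1,900 iterations.
The same user learning alone against a static map stays far away:

```r
set.seed(1)
run_user_learning(simulation_config(mode = "dependent", eta = 1.3e-3),
                  ref$map, ref$state)
#> <coadapt_run> mode = dependent , K = 40000 , eta = 0.0013 , gamma = 0
#> final (last 200 iters): planarity 0.893, angle 34.67 deg, VAF 71.3%, reward 0.609
```

`run_grid()` sweeps (η, γ) learning-rate grids with deterministic per-cell
seeds; `run_playback()` drives the model with a recorded (or synthetic)
sequence; `make_covariance()` / `make_interface()` / `generate_sequence()`
construct initial conditions and IMU-like autocorrelated sequences with known
ground truth.

## Command line

A thin `Rscript` front end (`exec/coadapt`) mirrors the library:

```sh
coadapt simulate --mode coadapt --eta 1.3e-3 --gamma 1.3e-3 --K 40000 \
        --n_runs 10 --seed 7 --out results/
coadapt grid --eta-log 6 1e-4 1e-1 --gamma-log 6 1e-4 1e-1 --out grid/
coadapt metrics --sequence seq.csv --map map.txt --window 3000 --out met/
coadapt make-data --seed 5 --length 40000 --out data/
```

Outputs are tidy CSVs plus a JSON manifest; re-running a manifest's
configuration reproduces every file byte-identically. Exit codes: 0 success,
2 configuration error, 3 I/O error.

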