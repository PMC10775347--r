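# vistamrf

Simulation, reconstruction and quantification toolkit for **3D ViSTa-MRF**
— myelin-water fraction (MWF) plus T1/T2/PD mapping from a double-inversion
prepared MR fingerprinting acquisition. The package implements the whole
chain end-to-end on synthetic data, so no scanner data is required.

## The problem and the method

Myelin water — the short-T1/short-T2 pool trapped in myelin sheaths — is a
specific marker of myelination, but conventional MWF mapping needs
ill-conditioned multi-compartment fits of multi-echo data. The ViSTa
preparation sidesteps the fitting: two inversion pulses (TI1 = 560 ms
between inversions, TI2 = 220 ms to the readout) are timed so that, from a
saturation-recovery steady state (TD = 380 ms), the longitudinal
magnetization of white and gray matter crosses zero at the readout while
myelin water (T1/T2 = 120/20 ms) retains ≈ 0.68 of its equilibrium
magnetization. The first time point of each block — the *ViSTa signal* —
is therefore directly proportional to the myelin-water magnetization:

```
I_ViSTa = MWF · PD · S_myelin(B1+),   MWF = I_ViSTa / (I_PD · S_myelin)
```

where `S_myelin` is the EPG-simulated myelin-water signal in units where a
90° tip of fully recovered Mz equals 1.

ViSTa-MRF embeds this preparation in a fingerprinting sequence: 8 ViSTa
blocks of 20 gradient-spoiled readouts plus a 500-point FISP-MRF block
(660 time points, TR/TE = 12/1.8 ms, flip-angle train optimized by
Cramér–Rao lower bounds), sampled by a variable-density spiral rotated
with tiny-golden-angle shuffling (TGAS) over three axes. Reconstruction is
the temporal-subspace problem

```
min_c || W^(1/2) (M F S Φ c − k) ||²  +  λ ||c||_LLR
```

with Φ the first 14 singular vectors of the EPG dictionary (≥ 99% of the
signal energy), solved by FISTA with a Toeplitz-embedded normal operator,
Pipe–Menon density compensation, basis balancing, optional Chebyshev
polynomial preconditioning, and locally-low-rank (LLR) regularization.
Per-voxel T1/T2/PD come from B1-restricted dictionary matching of the
reconstructed series (with the package's myelin-pool correction, see the
methods vignette), and synthetic T1w/T2w/MPRAGE/FLAIR/DIR contrasts are
generated from the quantitative maps.

## Worked example

```r
library(vistamrf)

p <- vista_protocol()          # 660-point protocol, packaged CRLB-optimized train
p$fa_train[1]                  # first flip angle of the optimized train
#> [1] 39.82712                # (the reference protocol uses 38 degrees)

standard_vista_slice_seconds(p)   # standard ViSTa: 48 preps x 1.16 s
#> [1] 55.68                      # rounds to the reference 56 s/slice
scan_time_minutes(16)             # 1 mm protocol
#> [1] 5.066667
scan_time_minutes(48)             # 0.66 mm protocol
#> [1] 15.2

# signal evolutions: myelin water survives the double inversion
s_my <- simulate_evolution(p, reference_tissue("myelin"))
s_wm <- simulate_evolution(p, reference_tissue("wm"))
abs(s_my$values[1]); abs(s_wm$values[1])
#> [1] 0.3999008               # myelin-water ViSTa signal
#> [1] 0.00149525              # white matter: nulled

# dictionary and temporal subspace
dict  <- build_dictionary(dict_grid(), p)     # ~95,000 atoms, well under a minute
basis <- compute_basis(dict, 14)
basis$energy_fraction
#> [1] 0.9997597               # >= 0.99, the basis-selection criterion
```

The full closed loop (32³ two-compartment phantom, 16 acquisition groups,
8 coils, SNR 30, subspace reconstruction, matching, MWF) runs in about
10 minutes on one CPU:

```r
demo <- vista_demo(seed = 1, dict = dict, basis = basis)
demo$metrics
```

which reports the white-matter median relative T1/T2 errors, the voxelwise
MWF regression slope and Pearson r against the ground-truth phantom, and
the ViSTa-point signals of myelin vs suppressed tissues. The same loop is
available from the shell: `inst/cli/vistamrf demo --seed 1`.

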