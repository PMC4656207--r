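# phasex

Crystallographic phase extension from a low-resolution cryo-EM map when
non-crystallographic symmetry (NCS) is low — two copies or fewer in the
asymmetric unit.

## The problem

X-ray diffraction measures only structure-factor amplitudes |F(h)|; the
phases needed to compute an electron-density map
ρ(x) = (1/V) Σ_h F(h) e^(−2πi h·x) must come from elsewhere. A
single-particle cryo-EM reconstruction of the same assembly can supply
them — but only to the EM resolution (here ~4.9 Å), and classic
density-modification phase extension to the diffraction limit (~2.3 Å)
traditionally relies on averaging over many NCS copies. With only a
two-fold NCS, plain density modification stalls. `phasex` implements the
alternative: an iterative loop that alternates

1. **DM** — prime-and-switch density modification (solvent flattening,
   histogram matching, two-fold NCS averaging), where the current phases
   only *seed* the map and every new phase is taken from the modified map
   alone, removing model bias;
2. **AMB** — automatic model building: peak picking and greedy tracing of
   pseudo-Cα chains (3.8 ± 0.7 Å spacing) in the current map;
3. **PHSCMB** — σA-weighted phase combination of the DM phases with the
   phases of the auto-built model, using per-shell
   σA⁴ = corr(E_obs², E_calc²), FOM m = I₁(X)/I₀(X) with
   X = 2σA·E_o·E_c/(1−σA²), and unimodal von-Mises addition of the two
   phase sources.

A transient *increase* of the phase error after PHSCMB is expected and
tolerated — it acts like the heating step of simulated annealing — and the
next DM cycle more than recovers it. Upstream of the loop, the package
prepares the EM map (B-factor sharpening exp(+B s²/4), FSC-based FOM
weighting √(2·FSC/(1+FSC)), magnification correction, placement in a
padded P1 box) and orients/positions it against the observed amplitudes
by an exhaustive rotation/translation search scored by amplitude
correlation, with a translation-function Z-score.

Phase quality is audited per cycle with the FOM-weighted mean phase error
wMPE = Σ m_i·|Δφ_i| / Σ m_i (degrees, against reference phases), map
correlation coefficients split by main-/side-chain region, and the
fraction of built pseudo-Cα atoms within 1.5 Å of a true position.

## Worked example

The package ships a synthetic-scenario generator that emulates the
intended use case end to end: a two-copy NCS dimer of pseudo-atom chains
in a cubic P1 cell, 2.3 Å "observed" amplitudes with 5% noise, and a
4.87 Å blurred, phase-perturbed "EM" map with exact NCS operators.

```r
library(phasex)

sc  <- standard_scenario(seed = 1)
weighted_mean_phase_error(sc$start_phases, sc$truth_phases)
#> [1] 35.1935          # EM-derived start phases, 4.9 A only

fit <- phase_extend(sc$obs, sc$start_phases, sc$config,
                    reference_hist = sc$reference_hist,
                    truth_phases = sc$truth_phases,
                    truth_model  = sc$truth_model,
                    n_cycles = 4, early_exit_tol = 0)
summary(fit)
#> Phase extension audit trail
#>  cycle  stage d_min mean_fom wmpe map_cc_all map_cc_main map_cc_side ca_frac
#>      1     DM   2.3    0.976 25.1      0.944       0.951       0.936      NA
#>      1    AMB   2.3    0.737 42.1         NA          NA          NA   0.904
#>      1 PHSCMB   2.3    0.977 25.1         NA          NA          NA      NA
#>      2     DM   2.3    0.982 20.4      0.960       0.966       0.953      NA
#>      2    AMB   2.3    0.768 37.7         NA          NA          NA   0.925
#>      2 PHSCMB   2.3    0.982 20.4         NA          NA          NA      NA
#>      3     DM   2.3    0.985 17.4      0.970       0.974       0.964      NA
#>      3    AMB   2.3    0.779 36.6         NA          NA          NA   0.947
#>      3 PHSCMB   2.3    0.985 17.4         NA          NA          NA      NA
#>      4     DM   2.3    0.986 16.1      0.974       0.978       0.968      NA
#>      4    AMB   2.3    0.792 35.3         NA          NA          NA   0.933
#>      4 PHSCMB   2.3    0.986 16.2         NA          NA          NA      NA
```

Reading the trail: starting from 4.9 Å phases with a 35° weighted mean
phase error, the first DM pass extends them to 2.3 Å at ~25° wMPE; the
auto-built model recovers ~90% of the Cα positions; four cycles of
DM/AMB/PHSCMB bring the final 2.3 Å phase set to ~16° wMPE with map
correlations ≈ 0.98 (main chain) — a directly interpretable map.
`plot(fit)` draws the wMPE trajectory across stages.

A thin command-line front end over the same functions is installed at
`inst/scripts/phasex` (verbs `simulate`, `prep`, `mr`, `dm`, `build`,
`combine`, `score`, `run`, `config`).

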