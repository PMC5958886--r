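# sshelix

Helix unfolding kinetics from per-residue secondary-structure label
trajectories.

Molecular-dynamics studies of helical peptides — the motivating system
is a 20-residue fully protonated poly-glutamic acid, a classical
helix–coil model peptide — are usually analyzed through DSSP: every
recorded snapshot is reduced to one secondary-structure symbol per
residue over the eight classes `H G I E B T S` and blank (spelled `O`
here). sshelix is an R package for turning many such label trajectories
into the statistics that characterize alpha-helix unfolding:

* **Unfolding time** — `t_u`, the time of the first snapshot with no
  `H` residue in the chain.
* **Region-ordered unfolding** — ranks the N-terminal (residues 2–7),
  middle (8–13) and C-terminal (14–19) regions by mean `H` content up
  to `t_u`: the lowest-content region unfolded first.
* **Transition kinetics** — residue-resolved probabilities
  `P(y, x; i)` of moving from class `x` to `y` between successive
  snapshots (20 ps apart by default), in the full alphabet or the
  reduced classing `H / G / T / other`, plus flux ratios through
  kinetic intermediates (turn, 3_10-helix).
* **Triad statistics** — elongation and unwinding propensities of
  helix *ends*, from three-residue `H`/`–` patterns (`HH–`, `–HH`,
  `H– –`, …) and the probability that the center residue is helical
  one frame later; the impossible `–H–` pattern is tracked as a
  data-integrity anomaly.
* **Chain geometry** — end-to-end distance and radius of gyration from
  multi-model PDB coordinate trajectories.
* **Synthetic data** — a kinetic Zimm–Bragg Monte-Carlo generator
  (energy `E = -Σ h_i ln s_i - runs·ln σ`, single-flip Metropolis
  dynamics, DSSP-style emission with a minimum `H` run length of 4)
  so the whole pipeline is testable, and parameter recovery
  demonstrable, without running molecular dynamics.

See `vignette("helix-unfolding-kinetics")` for the model, the design
choices, and what synthetic-data tests do and do not certify.

## Worked example

Aggregate the bundled published per-run reference table (28 runs):

```r
library(sshelix)
ref <- reference_run_summary()
st  <- ensemble_stats(ref)
sprintf("median t_u = %.2f ns over %d runs", st$t_u_median_ns, st$n_runs)
#> "median t_u = 36.02 ns over 28 runs"
ide <- ensemble_stats(reference_run_summary("Ide"))
ide$first_region_counts
#>  N  M  C
#>  7  0 13
ide$n_terminus_to_terminus
#> 3
```

Thirteen of the twenty ideal-helix-start runs unfolded from the
C-terminal region first, and only three followed a pure
terminus-to-opposite-terminus order — unfolding typically starts at a
terminus (usually C) and then proceeds from both ends toward the
middle.

Simulate a 28-run synthetic ensemble with the default C-destabilized
generator and analyze it with the same machinery:

```r
p   <- helix_params(n_frames = 1500)          # 30 ns per run at 20 ps/frame
ens <- make_synthetic_ensemble(28, p, seed = 1)
summarize_runs(ens)
#> unfolding summary: 28 runs (0 never unfolded)
#>   t_u  mean 0.53 ns, median 0.43 ns, SD 0.36 ns
#>   order patterns: C,M,N x9  C,N,M x10  N,C,M x8  N,M,C x1
#>   terminus-to-opposite-terminus runs: 10

transition_table(ens, 19)
#> transition_table (residue 19, reduced classing, lag 1 frame)
#>           H     G     T other
#> H     0.581 0.076 0.149 0.194
#> G     0.172 0.099 0.237 0.492
#> T     0.166 0.110 0.258 0.467
#> other 0.012 0.011 0.023 0.954

rec <- recover_parameters(ens, p)
sprintf("P(H,H;2) = %.2f   P(H,H;19) = %.2f",
        rec$retention$p_HH[2], rec$retention$p_HH[19])
#> "P(H,H;2) = 0.68   P(H,H;19) = 0.58"
```

The generator's C-terminal destabilization is visible exactly where
the analysis should see it: a C-first unfolding majority (19 of 28
runs) and weaker one-frame helix retention at residue 19 than at
residue 2. (The generator compresses absolute time scales — median
`t_u` of ≈ 0.4 ns rather than tens of ns — by design; see the
vignette.)

File-based workflows mirror the in-memory ones: `read_ss_trajectory()`
/ `load_manifest()` read frames-as-lines, tidy-table, or concatenated
DSSP output; `run_simulation()` and `run_analysis()` drive the
pipeline end to end, writing per-run summary, per-residue content,
transition, and triad TSV tables; `plot_ss_raster()` draws the
standard residue × time secondary-structure raster. A thin
command-line wrapper (verbs `analyze`, `simulate`, `raster`,
`recover`) is installed at `inst/cli/sshelix`.

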