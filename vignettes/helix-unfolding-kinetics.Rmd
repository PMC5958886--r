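---
title: "Helix unfolding kinetics from secondary-structure label trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Helix unfolding kinetics from secondary-structure label trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sshelix)
```

## The problem

All-atom molecular-dynamics simulations of short helical peptides — the
motivating system is a 20-residue, fully protonated poly-glutamic acid,
a classical helix–coil model peptide — produce, after secondary-structure
assignment with DSSP, a *label trajectory*: one symbol per residue per
recorded snapshot, drawn from the eight classes `H` (alpha-helix), `G`
(3_10-helix), `I` (pi-helix), `E` (strand), `B` (bridge), `T` (turn),
`S` (bend), and the blank "other" class, which this package spells `O`.
sshelix turns a collection of such trajectories into the quantities that
characterize helix unfolding:

* the **unfolding time** $t_u$ of each run — the time of the first
  snapshot with no `H` residue anywhere in the chain;
* the **region-ordered unfolding** classification — which third of the
  chain (N-terminal, middle, C-terminal) lost its helix first;
* **residue-resolved transition probabilities** $P(y, x; i)$ — the
  probability that residue $i$, in class $x$ at time $t$, is in class
  $y$ one recorded frame (20 ps by default) later;
* **triad statistics** — elongation and unwinding propensities of helix
  *ends*, measured on three-residue windows classed by their `H`/`–`
  pattern.

A kinetic Zimm–Bragg Monte-Carlo generator produces synthetic label
trajectories with the same statistical structure, so the entire pipeline
is testable, and parameter recovery demonstrable, without running any
molecular dynamics.

## Data model and conventions

An `ss_trajectory` is a frames × residues character matrix plus timing
metadata. Residue positions are 1-based; capping groups are not
residues. The time of frame $k$ (1-based) is
$t_0 + (k-1)\,\Delta t$ with $\Delta t = 20$ ps and $t_0 = \Delta t$ by
default — the first stored frame is the snapshot recorded one interval
after the initial structure. $t_0$ is configurable because deposited
data sets do not always state their convention; every $t_u$ value is by
construction an integer multiple of the recording interval.

Readers accept three text dialects (frames-as-lines, tidy
frame/residue/label tables, and concatenated standard DSSP output
blocks) with explicit sniffing in the order table → DSSP → lines, and
fail loudly on anything ambiguous, ragged, or containing a symbol
outside the alphabet. On input, ` `, `-` and `C` are accepted as
synonyms of the blank class and normalized to `O`.

A `run_ensemble` groups runs that are analyzed together. Truncation
(e.g. restricting 3-µs runs to their first 400 ns so all members are
commensurate) is applied at construction, which makes the invariant
"no downstream operation sees a frame beyond the limit" structural
rather than something every operation must re-check.

The default `region_partition()` splits the 20-residue chain into
N = residues 2–7, M = 8–13, C = 14–19 and excludes the two terminal
residues, whose assignment is distorted by chain truncation (the first
residue cannot even have a defined main-chain hydrogen-bond pattern on
its N-side).

## Unfolding-order metric

For one run the regions are ranked by their mean alpha-helix content
over the window from the start of the run **up to and including** the
first helix-free frame; the lowest-content region unfolded first. Two
choices here were genuinely open:

* **`H`-only content.** Since $t_u$ itself is defined on the
  alpha-helix class only, the ranking also uses `H` by default
  (`G` can be included via the `labels` argument).
* **Closed window.** The window includes the $t_u$ frame itself; since
  that frame contains no `H` anywhere it shifts all three region
  contents equally and cannot change the ranking, so the choice is
  cosmetic — but it is fixed and documented.

Ties are broken by the earlier time at which a region first becomes
completely helix-free, then by the partition's declared region order.
With the published per-run table bundled in
`reference_run_summary()`, `ensemble_stats()` reproduces the reported
aggregate statistics (median $t_u$ = 36.02 ns; 13 of 20 ideal-start
runs unfolding C-first; 3 runs with terminus-to-opposite-terminus
order). The reported ensemble *mean* of those 28 printed values is
78.11 ns; runs that never unfold are excluded from $t_u$ statistics
and counted separately, since no published rule covers them.

## Transition kinetics

`transition_table()` counts, at one residue, all (frame $t$, frame
$t+1$) label pairs pooled over every member of the ensemble — the last
frame of a member is never a source — and row-normalizes the pooled
counts. Pooling before normalizing yields one estimator per ensemble
(per-run tables remain available by passing single-member ensembles).
Two representations are supported: the full eight-class alphabet, and
the reduced classing `H`, `G`, `T`, `other` with `other` exactly
\{`I`, `E`, `S`, `B`, `O`\}; collapsing a full table reproduces the
reduced counts identically. Rows whose source class was never observed
report `NA`, deliberately distinct from "observed but never left".

`flux_ratio()` expresses kinetic intermediacy: of all transitions that
*leave* class $x$, the fraction arriving at $y$,
$P(y,x)\,/\,\sum_{z \ne x} P(z,x)$. In the motivating data most
departures from `H` pass through `T`, which is why the reduced classing
singles out the turn and 3_10 classes.

Triad statistics restrict attention to three-residue windows. Each
(frame, center) pair with a successor frame is classed by the `H`/`–`
pattern of the center and its two neighbors; the reported probability
is that the center is `H` one frame later. Since DSSP requires at least
four consecutive residues for `H`, the pattern `–H–` is impossible in
valid data; occurrences are counted as anomalies and excluded from the
seven admissible classes, giving a built-in data-integrity check.
Centers run over positions 2..19 ("All" scope) or a region's positions;
for the default partition the three regions exactly tile the All scope,
which the tests verify by brute-force pooling.

## The synthetic generator

The generator evolves a binary helix(h)/coil(c) state under the
Zimm–Bragg energy

$$E(h) = -\sum_i h_i \ln s_i \;-\; R(h)\,\ln\sigma,$$

where $R(h)$ is the number of maximal helical runs, via single-residue
Metropolis flips (uniformly random residue, accept with probability
$\min(1, e^{-\Delta E})$); one frame is recorded per sweep of
`n_residues` proposed moves. Detailed balance w.r.t. the Boltzmann
distribution holds exactly, and is verified by exhaustive enumeration
on an 8-residue chain (256 states; total-variation distance between the
empirical state distribution over $10^5$ sweeps and the exact
distribution below 0.02, using $s$ linear in $[0.8, 1.2]$ and
$\sigma = 0.2$ — a configuration chosen to mix fast and concentrate
mass, since with 256 cells and $10^5$ correlated samples even a perfect
sampler's finite-sample TV is close to that bound).

Default parameters (chosen once, as the conditions the analyses
assume):

| parameter | default | meaning |
|---|---|---|
| `s` | geometric 1.1 → 0.75 | per-position helix propensity; N-terminal third marginally helix-favoring, C-terminus weakest |
| `sigma` | 0.02 | nucleation penalty; makes de-novo nucleation a rare event |
| `min_run` | 4 | shortest run emitted as `H` (the DSSP minimum) |
| `p_decorate_G`, `p_decorate_T` | 0.3, 0.5 | boundary intermediates at helix ends |
| `n_frames` | 1500 | 30 ns at 20 ps per frame |

The propensity profile deserves a comment. A Metropolis flip that
shortens a helix end is accepted with probability $\min(1, 1/s_i)$, so
any profile with $s_i \le 1$ everywhere lets *both* ends erode at the
proposal rate and produces almost no N/C asymmetry regardless of the
$s$ gradient. Raising the N-terminal third slightly above 1 pins the N
end (net growth pressure) while the C end frays, which reproduces the
qualitative structure the analyses target: a C-first unfolding
majority (fraction ≈ 0.6–0.8 over 50 runs), weaker one-frame `H`
retention at residue 19 than at residue 2, and near-flat elongation
probabilities. The generator makes no attempt to reproduce absolute
unfolding times or contents of any force field; its $t_u$ scale
(median ≈ 0.4 ns) is deliberately compressed so that 50-run ensembles
simulate in seconds.

### Minimum run length: emission, not rejection

DSSP's `H` class implies runs of ≥ 4 residues. Enforcing that in the
*state space* by rejecting violating moves has a structural defect
under single-flip dynamics: a 4-residue run can neither shrink (end
flip → 3-run, rejected) nor split (interior flip, rejected), so
complete unfolding becomes unreachable. The package therefore enforces
the constraint at the **emission layer** by default
(`min_run_mode = "relabel"`): the h/c chain is an unconstrained
Zimm–Bragg process (so the stationary distribution stays exactly
Boltzmann and unfolding completes), and helical runs shorter than
`min_run` are emitted as nascent-helix intermediates — `G` with
probability `p_decorate_G`, else `T` — never `H`. Emitted `H` runs are
therefore always ≥ 4 long and the `–H–` triad anomaly count is exactly
zero by construction. A literal rejection mode
(`min_run_mode = "reject"`) exists for studying the constrained chain
itself, with the caveat above.

Boundary decoration (coil next to an emitted helix end becomes `G` or
`T` with the stated probabilities, else `O`) is cosmetic labeling on
top of the binary state, not part of the energy: it exists to exercise
the reduced-classing analytics (`G`/`T` as boundary intermediates),
not to model turn thermodynamics.

### What the generator does and does not emulate

It emulates: position-dependent helix stability with a weak C-terminus,
rare nucleation, contiguous `H` runs of length ≥ 4, turn/3_10
enrichment at helix boundaries, and many-run unfolding study designs.
It does **not** emulate: beta structure (`E`/`B` never emitted), bends
(`S`), pi-helix, the long time-correlations of real solvent dynamics,
or realistic absolute time scales. Green tests on synthetic data
therefore certify the *counting and inference machinery*, not any
force-field-level claim about real peptides.

## Numerical choices and degenerate inputs

* Time comparisons (truncation, windows) use a `1e-9` ps epsilon so
  frame times that are exact multiples of the interval are never
  excluded by floating-point noise.
* Transition rows and triad classes with zero source counts are `NA`,
  never 0.
* The sample SD ($n-1$) is used for $t_u$; a single defined $t_u$
  yields `NA`.
* Ensembles whose members disagree on residue count or frame interval
  are constructor errors, not warnings.
* Chain-geometry metrics: end-to-end distance defaults to
  Cα(first residue)–Cα(last residue) and the radius of gyration to
  unweighted heavy atoms; both selectors are configurable since
  experimental comparisons (e.g. FRET between dye-labeled termini) do
  not fix a unique atom pair. Both metrics are rigid-motion invariant
  to 1e-8 Å by construction and by property test.

## Problem sizes used by the tests

The test suite and acceptance script run entirely on synthetic or
bundled-table inputs: brute-force equivalence on ensembles of ≤ 5 runs
× ≤ 50 frames; directional/recovery checks on 20–50 runs × 1500 frames
(a few seconds); the stationarity check on one 8-residue chain ×
$10^5$ sweeps. Reproducing the full published transition and triad
probabilities requires the deposited multi-megabyte raw label
trajectories, which are not bundled; `deposited_data_manifest()`
documents where to install them, and the corresponding acceptance test
reports their absence as a failure rather than silently passing.

## Limitations

* The deposited raw data's exact file layout is unverified; the
  dialect sniffing order (table → DSSP → frames-as-lines) fails loudly
  rather than guessing, and may need a new dialect once the archive's
  layout is known.
* Single-lag empirical probabilities only: no Markov-state-model
  construction, lag scans, or implied-timescale analysis.
* Discrete beta-sheet "formation events" are not segmented; only
  `E`/`B` content fractions are available.
* The generator's analytic retention prediction
  (`recover_parameters(..., params = )`) neglects end effects; it is a
  comparison aid, not an estimator.
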