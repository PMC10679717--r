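# ttmd

Thermal titration molecular dynamics (TTMD) analysis for nucleic-acid–ligand
complexes: rank candidate binding poses by how long they keep their native
interactions while the simulation temperature climbs a stepwise ramp.

## The problem and who this is for

Docking scores are notoriously unreliable on RNA: the surface-charge
distribution and conformational plasticity of structured RNAs (aptamers,
riboswitches, viral regulatory elements) defeat scoring functions built for
protein pockets. TTMD is a post-docking filter: instead of scoring a static
pose, it runs a chain of short MD segments at progressively increasing
temperature (300→450 K standard; 73→223 K "cold" alternative; 10 K / 10 ns
steps) and watches the native receptor–ligand interaction pattern decay.
Poses whose native contacts persist to high temperature behave like long
residence-time complexes; poses that shed their contacts early are likely
artifacts. This package is for computational chemists building or analysing
such pipelines: it implements every analysis stage — fingerprints, scoring,
termination, coefficients, replicate aggregation, pose ranking, RMSD
reports — plus a pluggable engine contract and fully synthetic generators so
the whole pipeline is testable without a GPU.

## The score and the coefficients

Per frame, receptor–ligand interactions (H-bonds both ways, π-stacking,
cation–π, ionic, hydrophobic, halogen, vdW) are detected geometrically with
RNA-aware atom typing and encoded as a binary fingerprint **f** over fixed
(residue × class) slots. The frame score is the negated cosine similarity
to the reference frame's fingerprint:

    IFP_CS = − cos(f, f_ref) ∈ [−1, 0]

(−1 = fully native, 0 = all native contacts lost). A titration stops early
after any step whose last 10 % of frames average strictly above −0.05.
Runs are summarised by

* **MS** — slope of the line joining the titration profile's endpoints,
  `MS = (mean IFP_CS(T_end) + 1) / (T_end − T_start)`, clamped to [0, 1];
  a first-step termination scores 1 by convention. Lower = more stable.
* **IFF** — RMS fluctuation of the per-frame score about the whole-run
  mean; penalises volatile traces.

Per pose, replicate coefficients are aggregated by a trimmed mean (drop one
min and one max of the non-missing replicates) with a population-SD
dispersion, and poses are ranked by ascending trimmed mean.

## Worked example

Six synthetic poses with designed stabilities (log-spaced loss rates),
five replicates each through the full protocol, aggregated and ranked:

```r
library(ttmd)

panel  <- make_pose_panel(6)                      # designed ranking 1..6
coeffs <- run_pose_panel(panel, standard_ramp(), n_replicates = 5, seed = 2024)
rank_poses(aggregate_replicates(coeffs, value = "ms"))
#> # A tibble: 6 × 6
#>    rank pose_id trim_mean trim_error n_used n_total
#>   <int> <chr>       <dbl>      <dbl>  <int>   <int>
#> 1     1 pose01    0.00661   0.000626      3       5
#> 2     2 pose02    0.00872   0.000448      3       5
#> 3     3 pose03    0.0150    0.00240       3       5
#> 4     4 pose04    0.0274    0.00967       3       5
#> 5     5 pose05    0.0815    0.371         3       5
#> 6     6 pose06    1         0             3       5
```

The recovered ranking matches the designed one: pose 1 (slowest designed
loss rate) has the lowest trimmed-mean MS, and pose 6 loses all native
contacts in its first step in every replicate (MS = 1 by convention; its
dispersion is 0 because all five replicates agree).

A coordinate-level titration with the toy Langevin engine — a ligand
particle in a 2 kcal/mol binding well escapes during step 3 of the
standard ramp:

```r
ts  <- toy_system(well_depth = 2.0)
lay <- build_layout(ts$complex, select_binding_site(ts$complex, 6.0))
res <- run_titration(toy_engine(ts), ts$complex, lay, standard_ramp(), seed = 11)
res
#> <ttmd_result> 3/16 steps, last T = 320 K (terminated early)
#>   MS = 0.048939, IFF = 0.23544
glance(res)          # broom-style one-row summary
titration_profile(res)  # per-step means + MS slope segment
autoplot(res)           # timeline: IFP_CS + ligand/backbone/site RMSD
```

`MS = 0.0489` is read as: the last completed step ran at 320 K with a
step-mean score of ≈ −0.02, i.e. the native hydrophobic contacts were
essentially gone 20 K above the ramp start — a volatile pose.

Real systems enter through `read_complex("complex.pdb", ligand = "LIG")`
and `read_trajectory()` (DCD or multi-model PDB); published per-replicate
benchmark coefficients for six RNA–ligand systems are available via
`benchmark_replicates()`.

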