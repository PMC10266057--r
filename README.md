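# xferkin

Kinetic analysis of protein–nucleic-acid direct transfer from
fluorescence-polarization (FP) plate assays, plus reaction-scheme
simulation of how direct transfer reshapes enzyme activity on chromatin.

## The scientific problem

A nucleic-acid-binding protein can leave its ligand two ways: it can
dissociate into free solution (intrinsic off-rate `k_minus1`), or it can
be handed directly to a second nucleic acid through a transient ternary
intermediate, without ever becoming free ("direct transfer", rate
constant `k_theta` in M⁻¹s⁻¹). The two mechanisms are distinguished by a
competition-chase experiment (FP competitive dissociation, FPCD): a
preformed complex between the protein and a fluorescent ligand is
challenged with increasing amounts of unlabeled competitor, and the
observed dissociation rate `k_off_obs` is measured at each competitor
concentration. Classic competition predicts `k_off_obs` saturating at
`k_minus1`; direct transfer predicts it keeps rising linearly with slope
`k_theta`. Getting this discrimination right matters: two labs measuring
the same complex at 200-fold vs 2,000-fold competitor excess will report
10-fold different "off-rates" unless the competitor-concentration
dependence is modeled explicitly.

`xferkin` provides, end to end:

* **kinetics core** — mass-action reaction networks (`build_scheme`,
  `integrate_network`, `equilibrium_state`) with conservation auditing;
* **synthetic data** — realistic FP plate generators for equilibrium
  titrations and FPCD chases (`generate_binding_plate`,
  `generate_fpcd_plate`), with noise, replicates, dead time, and a
  packaged table of reference rate constants (`table1_species`);
* **equilibrium binding** — isotherm extraction and apparent-Kd fitting
  (`isotherm_from_plate`, `fit_kd_app`), ionic-strength regression
  (`salt_dependence_regression`);
* **FPCD pipeline** — trace normalization, one-phase decay fits, and
  direct-transfer vs classic model selection by BIC
  (`normalize_traces`, `fit_decay`, `fit_transfer_models`,
  `analyze_fpcd`);
* **scheme analysis** — a histone-methyltransferase scheme in which RNA
  competes with nucleosomes for the enzyme but can also hand the enzyme
  over by direct transfer; effective-molarity sweeps, ablations, and
  initial-velocity grids (`prc2_params`, `cobinder_params`,
  `simulate_hmtase`, `relative_v0_grid`, `rbtf_occupancy`);
* **CLI** — a single `xferkin` executable with `simulate`, `analyze`,
  `fit-kd`, `salt-slope`, `grid`, and `reproduce` subcommands.

## Worked example

Recover an apparent Kd from a noisy synthetic titration, then run a full
FPCD chase analysis at the packaged dsDNA constants
(`k_minus1 = 9.1e-5 s⁻¹`, `k_theta = 260 M⁻¹s⁻¹`):

```r
library(xferkin)

# 1) affinity from an equilibrium titration (12 points, 2 mP noise)
plate_kd <- generate_binding_plate(table1_species("G4"),
                                   make_titration(1e-6, 10^(5/11), 12),
                                   noise = noise_model(2, seed = 42))
fit <- fit_kd_app(isotherm_from_plate(plate_kd))
print(fit)
#> <kd_fit> Kd_app = 2.292e-09 M (SE 2.2e-11); P_free = 49.95 mP, P_bound = 200 mP; RSS = 1.88

# 2) FPCD chase: off-rate vs competitor concentration (3 mP noise)
sp <- table1_species("ds-dN60", competitor = "ds-d(N)60")
cross <- flux_crossover(9.1e-5, 260)        # where transfer flux = intrinsic flux
series <- c(0, make_titration(100 * cross, 1000^(1/7), 8)[1:8])
plate <- generate_fpcd_plate(sp, series, noise = noise_model(3, seed = 1))
report <- analyze_fpcd(plate, Kd_app = 5.1e-9)
print(report)
#> <fpcd_report> ds-[F]d(N)60 vs ds-d(N)60
#> <transfer_fit> selected: direct (kinetic regression)
#>   k_minus1P = 0.000132 /s (SE 3.8e-05)
#>   k_thetaD  = 233 /M/s (SE 2.5)
#>   K_reb = 7.22e-05 M; BIC direct/classic = -148.28 / -93.21
```

With noise off, the pipeline returns the generating constants to within
numerical precision; with plate-realistic noise the transfer constant is
tightly identified per plate, while the (much smaller) intrinsic
off-rate is identified on replicate averages.

The same flows are available from the command line (the executable is
installed at `inst/cli/xferkin`):

```sh
xferkin simulate binding --params table1:G4 --seed 11 -o plate.csv
xferkin fit-kd plate.csv -o kd.json
xferkin simulate fpcd --params table1:ds-dN60 --competitor-top 3.5e-5 -o chase.csv
xferkin analyze fpcd chase.csv -o chase.json
xferkin salt-slope --ligand ds-dN60 -o salt.json   # slope 1.4, intercept -5.2
xferkin reproduce crossover --seed 1 -o crossover.json
```

Every artifact carries a provenance header (package version, seed,
parameter hash) and is bit-for-bit reproducible from it.

## Reproduction

The packaged reference quantities can be recomputed from scratch against
the installed package:

```sh
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```

which regenerates noiseless synthetic datasets from the fixture
constants and reports the recovered values
(`t1`/`t2`: apparent Kd in nM for the G4 RNA and 60-bp dsDNA ligands;
`t3`–`t6`: dissociation and transfer constants from the full FPCD
pipeline for the dsDNA and RNA parameter sets), e.g.

```json
{"t1":{"value":2.3,"n":13},"t2":{"value":5.1,"n":13},
 "t3":{"value":9.1e-05,"n":9},"t4":{"value":260,"n":9},
 "t5":{"value":0.0017,"n":7},"t6":{"value":170,"n":7}}
```

The full test suite (unit, property-based, and acceptance tests) runs
with:

```r
testthat::test_dir("tests/testthat", package = "xferkin",
                   load_package = "installed")
```

See `vignettes/transfer-kinetics.Rmd` for the model definitions, the
estimator-consistent fitting strategy, and the numerical methods.
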