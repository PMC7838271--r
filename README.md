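# fluorpanel

Optimal fluorophore panel design for flow cytometry and other laser-based
fluorescence instruments.

Every multicolor experiment faces the same selection problem: out of a
library of fluorophores (fluorescent proteins, dyes, conjugated antibodies),
pick *n* and assign each to one detector of the machine at hand so that each
detector sees a strong signal from its own fluorophore and as little
spectral bleed-through (spillover) from the others as possible. The space of
possible panels is `C(F, n) · D!/(D−n)!` for `F` fluorophores and `D`
detectors — over 3 million 4-color panels for 8 fluorophores on 16
detectors, and ~4 × 10²⁷ 10-color panels for a 188-fluorophore catalog on 19
detectors — so ad hoc selection does not scale. `fluorpanel` is for bench
scientists and facility staff who want that choice computed.

## What it computes

**Signal model.** From excitation/emission spectra on a common 1-nm grid
(300–900 nm), the predicted signal of fluorophore *f* in detector *d* is

    S_fd = ex_f(laser line of d) × (emission of f inside d's bandpass) /
           (total emission of f)  [× normalized brightness, optional]

Autofluorescence, when supplied per detector, is added as bleed-through.
A panel is **valid** if every detector has strictly positive signal for its
own fluorophore.

**Ranking.** Panels are compared lexicographically on three tiers:
(1) number of detectors whose total bleed-through is within a threshold η of
their signal (default η = 0.10); (2) geometric mean of the signals;
(3) arithmetic mean of the per-detector bleed-through. Equal on all three =
equivalent.

**Search.** `exhaustive_search()` ranks the full space (with exact
solution-space counting via `count_panels()` and a valid-panel census via
`count_valid_panels()`); `simulated_annealing()` / `multistart_sa()` handle
spaces where enumeration is intractable, using a 9,206-iteration geometric
cooling schedule by default and always re-ranking candidates with the exact
comparator.

**Validation.** `signals_match()` and `within_tolerance()` compare
per-detector-normalized predictions against measured matrices at the
0.05/0.10/0.20 tolerances; `agreement_summary()` tabulates percentages over
panel sets. `generate_library()` / `generate_instrument()` /
`simulate_measurements()` provide synthetic Gaussian-spectrum data so
everything runs without downloads.

## Worked example

```r
library(fluorpanel)
lib  <- read_fluorophore_library(
          system.file("extdata", "example_library.csv", package = "fluorpanel"))
inst <- read_instrument_config(
          system.file("extdata", "example_instrument.json", package = "fluorpanel"))

count_panels(length(lib), length(inst$detectors), 2)
#> <panel_count> F=3 D=5 n=2: 60 (60) panels

res <- exhaustive_search(lib, inst, n = 2)
res
#> <panel_search> n=2: 60 panels, 10 valid (16.7%), eta=0.1
#>   rank   fluorophores       detectors within_eta_count geomean_signal mean_bleedthrough
#> 1    1 mAzure/mGarnet L445-D1/L561-D1                2     0.55983246                 0
#> 2    2 mAzure/mGarnet L445-D1/L561-D2                2     0.34623106                 0
#> ...

bleedthrough_report(best_panel(res)$panel, build_signal_matrix(lib, inst))
#>   detector fluorophore    signal bleedthrough bleed_ratio within_eta
#> 1  L445-D1      mAzure 0.5633398            0           0       TRUE
#> 2  L561-D1     mGarnet 0.5563470            0           0       TRUE
```

Only 10 of the 60 2-color panels are valid (both detectors must see their
own fluorophore), and the best one pairs the cyan protein on the blue
laser's first window with the red-shifted protein on the yellow-green
laser's first window: both signals ≈ 0.56 of the emitted light, with no
predicted cross-talk, so both detectors sit within η. Multistart annealing
returns the same panel:

```r
multistart_sa(lib, inst, n = 2, params = sa_params(restarts = 4, seed = 1))
#> <sa_result> 9206 iterations (seed 1)
#> <panel> n=2
#>   mAzure -> L445-D1
#>   mGarnet -> L561-D1
#> <panel_score> within-eta 2/2  geomean signal 0.5598  mean bleed 0.0000 (eta=0.1)
```

## Command line

`inst/cli/fluorpanel.R` wraps the same functions:

```sh
Rscript inst/cli/fluorpanel.R count --fluorophores 8 --detectors 19 --n 5
# 78,140,160 panels (7.81402e+07) for n=5 from F=8 fluorophores, D=19 detectors

Rscript inst/cli/fluorpanel.R select --library lib.csv --instrument cyto.json \
    --n 4 --algorithm sa --restarts 50 --seed 1 --out results/
```

Subcommands: `count`, `select`, `score`, `validate`, `simulate`. Exit codes:
0 success, 2 no valid panel, 3 input error.

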