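# her4switch

Mechanistic modeling of the time-dependent antagonist/agonist switch in
HER4-JAK2-STAT5 signaling, with variance-based global sensitivity analysis.

## The problem

HER4/ErbB4 is the ErbB receptor whose ligand Neuregulin (NRG) triggers an
anti-proliferative JAK2-STAT5 program: phospho-STAT5 dimers enter the
nucleus and transcribe differentiation genes such as beta-casein. In
differentiating HC11 mammary epithelial cells this response reverses sign
over time — over 0-12 h after stimulation, raising the NRG dose *lowers*
beta-casein mRNA, while over 24-48 h it *raises* it. Canonical JAK-STAT
models cannot produce this switch.

`her4switch` implements a two-compartment mass-action ODE model of the
pathway (concentrations in nM, time in h) with two additional mechanisms
that jointly generate the switch:

* **Competitive heterodimerization** — ligand-stimulated HER4 pairs with a
  lumped HER2/HER3 partner pool, draining free HER4 away from HER4-JAK2
  binding with a capture flux that grows with dose (early antagonism);
* **a slower JAK2-independent branch** — the cleaved HER4 s80/4ICD fragment
  phosphorylates STAT5 directly at a ten-fold lower rate
  (`kR39 = 0.1 kR06`), escaping SOCS negative feedback (late agonism).

On top of the simulator the package provides the three dynamical readouts
used to characterize the switch (interval-integrated beta-casein mRNA over
0-12/12-24/24-48 h; the early/late switch ratio; the STAT5-to-mRNA
transcription peak delay), Latin-hypercube parameter ensembles for
uncertainty bars, and Sobol sensitivity indices estimated with the Saltelli
design

    S_i  = [ (1/N) sum_j f(A)_j f(B_A^i)_j − f0^2 ] / V(Y)
    S_Ti = 1 − [ (1/N) sum_j f(A)_j f(A_B^i)_j − f0^2 ] / V(Y)

over quasi-random Sobol' sequences generated in-package. It is aimed at
systems biologists studying receptor-level competition and parallel
pathway timing, and at anyone needing a self-contained, oracle-tested
Saltelli GSA stack in R.

## Worked example

```r
library(her4switch)

net <- build_full_network()          # canonical core + both branches
trajs <- run_dose_series(net, dose_protocol(c(0, 10, 20, 50),
                                            output_step = 0.02))
readout_table(trajs)
```

```
        dose_nM integral_0_12 integral_12_24 integral_24_48 switch_ratio delay_h
dose_0        0        0.0479          0.050          0.100       0.3194      NA
dose_10      10        4.9806          1.866          0.186       2.4277  0.5602
dose_20      20        4.8426          1.803          0.361       2.2380  0.5585
dose_50      50        4.2385          1.480          0.733       1.9150  0.5521
```

Reading the table: the 0-12 h integral *falls* with dose (4.98 → 4.24 nM·h,
the early antagonism) while the 24-48 h integral *rises* (0.186 → 0.733
nM·h, the late agonism); `dose_trend()` condenses these columns to the
signs −1 and +1. The dose-0 row is the hydrocortisone-only control (basal
transcription), the normalization reference for fold changes. The ~0.56 h
`delay_h` is the baseline STAT5-to-mRNA peak gap; reducing the mRNA export
rate `kR45` ten-fold stretches it to ~2.8 h:

```r
slow <- set_parameters(net, params = c(kR45 = net$parameters[["kR45"]] * 0.1))
transcription_delay(run_timecourse(slow, dose = 20))
#> [1] 2.803
```

Ablations show both branches are necessary: without heterodimerization the
early trend is no longer −1, without the s80 branch the late trend is no
longer +1 (`add_heterodimerization()` / `add_jak_independent_branch()`
applied separately to `build_canonical_network()`).

Sensitivity screening over the twelve flagged parameters:

```r
space <- default_parameter_space(net,
  parameters = c("n_transc", "V_transc", "K_transc", "kR45", "kR15",
                 "kfR41", "kfR42", "kfR43", "kfR36", "kR37", "kR39",
                 "SOCS_Binding_Rate"))
rank_top(sobol_gsa(net, space, output = "integrated_casein", dose = 20,
                   N = 128))
```

Report drivers (`cmd_simulate()`, `cmd_switch()`, `cmd_delay_sweep()`,
`cmd_gsa()`, `cmd_bench()`) take a YAML-compatible configuration and write
CSV tables plus SVG figures; a thin command-line wrapper ships in
`inst/cli/her4switch.R`. Networks round-trip through SBML
(`write_sbml()` / `read_sbml()`) and a YAML config format.

See the methods vignette (`vignettes/her4-switch-model.Rmd`) for the model
assumptions, parameter choices, numerical policy and limitations.

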