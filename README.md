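# MethanoSIP

Isotope mass-balance accounting for dual-label (¹³CH₄ + ¹⁵N₂) stable
isotope probing of root-associated microbiomes.

## The scientific problem

Methane-oxidizing communities on rice roots burn CH₄ for carbon and
energy, and in nitrogen-poor rhizospheres they can pay for that growth by
fixing N₂. Quantifying this coupling requires tracking *two* isotope
labels through a closed microcosm: ¹³C from the methane into root tissue
and respired CO₂, and ¹⁵N from the dinitrogen headspace into biomass and
dissolved inorganic nitrogen. The questions the accounting must answer:

- How much CH₄ was consumed, and with what carbon-use efficiency (CUE)?
- How much N₂ was fixed, and what fraction of the fixed N was mineralized
  to plant-available ammonium?
- How strongly does methane oxidation stimulate fixation relative to a
  CH₄-free control, and what does that imply at field scale?
- Which taxa carry the label (density-gradient shifts, differential
  abundance) and what roles do they play in the co-occurrence network?

## The core model

All quantities are per gram of dry root mass. With `E(pool)` the
atom-percent excess of a pool over natural background (1.08 atom % ¹³C,
0.369 atom % ¹⁵N):

```
T_CH4 = E(TOC)·C_TOC·1e6/M13C            (solid ¹³C, µmol g⁻¹)
      + E(CO2)·[CO2]·V_gas/m             (headspace ¹³CO₂)

CUE   = biomass ¹³C / T_CH4

T_N2  = E(TON)·C_TON·1e6/M15N            (solid ¹⁵N)
      + Σ_species E(X)·[X]·V_liq·1e3/(M15N·m)   (NH4⁺, NO3⁻, NO2⁻)

mineralized fraction = inorganic ¹⁵N / T_N2
field budget: gross CH4 = net emission/(1−f_ox); N fixed =
  gross·f_ox/M_CH4 · (T_N2/T_CH4) · M_N
```

Pools flagged below detection contribute zero and are reported as
skipped. Small negative excesses (≤0.05 atom %) are clamped with a typed
warning; larger ones error. Everything downstream — fold stimulation,
pool partitioning, gradient labeling calls, volcano classification, Zi–Pi
network roles — is built on these primitives. A seed-controlled synthetic
microcosm generator inverts the same balances from planted truths, so the
whole pipeline can be validated end to end against known answers.

## Worked example

Simulate the three-treatment study design (CH₄-free control, ¹³CH₄,
¹³CH₄ + nitrate) without noise and run the flux accounting:

```r
library(MethanoSIP)
sim <- simulateBottles(simulationConfig(seed = 1, noiseCv = 0))
f   <- computeFluxes(sim$measurements, sim$geometry)
s   <- fluxSummary(f)
s[s$treatment == "13CH4", c("variable", "mean")]
#>              variable      mean
#>                 t_ch4 1.238e+03
#>           biomass_13C 6.561e+02
#>               co2_13C 5.819e+02
#>                   cue 5.300e-01
#>                  t_n2 4.330e+01
#>           biomass_15N 2.490e+01
#>         inorganic_15N 1.840e+01
#>  mineralized_fraction 4.249e-01
```

So the ¹³CH₄ treatment consumed 1238 µmol CH₄ g⁻¹ at a CUE of 0.53 and
fixed 43.3 µmol N g⁻¹, of which 42.5 % was mineralized. Compare against
the control and extrapolate:

```r
tn2 <- function(tr) s$mean[s$treatment == tr & s$variable == "t_n2"]
foldStimulation(tn2("13CH4"), tn2("NoCH4"))
#> [1] 164.0152
atomPercentExcess(4.65, 1.08)        # ¹³C excess in root organic carbon
#> [1] 3.57
unlabeledBySubtraction(15.5, 0.55)   # NH4-N from unlabeled organic N, µmol
#> [1] 14.95
fieldNitrogenBudget(150, 0.9, nfixEfficiency(tn2("13CH4"), 1238))
#> [1] 41.22499                       # kg N ha⁻¹ yr⁻¹
```

Gradient labeling calls work on qPCR density profiles:

```r
g <- simulateGradient(labeled = TRUE, shift = 0.03, seed = 2)
detectLabeling(g$sample, g$control)[c("call", "shift")]
#> $call
#> [1] "labeled"
#> $shift
#> [1] 0.03
```

Community-level tools (`volcanoAnalysis`, `inferNetwork`,
`detectModules`, `nodeRoles`, `runReport`) are covered in the vignette
`vignettes/dual-label-sip-accounting.Rmd`.

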