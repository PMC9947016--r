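# cardiotd

Cellular toxicodynamic (TD) modelling of doxorubicin (DOX)-induced
cardiotoxicity and its attenuation by dexrazoxane (DEX), with in
vitro-to-clinical translation.

DOX is a highly effective anthracycline whose cumulative, dose-limiting
cardiotoxicity restricts its clinical use; DEX is the only approved
cardioprotectant. `cardiotd` is aimed at pharmacometricians and
quantitative systems pharmacologists who want to (i) fit a mechanistic
cell-level TD model to viability time courses of human cardiomyocytes
(AC16) exposed to DOX, DEX and their combination, and (ii) use clinical
plasma pharmacokinetics (PK) of both drugs to drive that cell model and
rank dosing regimens — DEX:DOX dose ratios and DOX dose fractionation —
by an integrated toxicity metric, the area under the viability-time
curve (AUEC).

## The model

Drug concentrations in culture medium decay by first-order degradation,

$$C_i(t) = C_{i,0}\, e^{-k_{deg,i} t}, \qquad i \in \{DOX, DEX\}.$$

Untreated cells grow exponentially, $dR/dt = k_g R$, with $R$ the %
viability. DOX inhibits growth linearly ($1 - S_{DOX} C_{DOX}$) and
stimulates death through a saturable Hill function
$K_{DOX} = K_{max}\,C_{DOX}/(KC_{50} + C_{DOX})$ whose effect is
delayed by a chain of three transit compartments with rate constant
$k_{tr} = 1/\tau$:

$$\frac{dK1}{dt} = k_{tr}\,(K_{DOX} - K1), \quad
  \frac{dK2}{dt} = k_{tr}\,(K1 - K2), \quad
  \frac{dK3}{dt} = k_{tr}\,(K2 - K3),$$

$$\frac{dR}{dt} = \bigl(1 - (S_{DOX} C_{DOX} + S_{DEX} C_{DEX})\bigr)
  k_g R - K3\,R.$$

DEX alone inhibits growth linearly ($1 - S_{DEX} C_{DEX}$); in
combination it additionally blunts the DOX death signal entering the
transit chain through a second Hill function,
$K_{DEXi} = I_{max}\,C_{DEX}/(IC_{50} + C_{DEX})$, so the chain input
becomes $K_{DOX} - K_{DEXi}$ (optionally floored at zero for clinical
extrapolation, where plasma DEX far exceeds the in vitro range).

For translation, DOX plasma PK follows a linear three-compartment
mammillary model (CL 53.3 L/h, V 17.7 L for a 1.8 m² adult) and DEX a
two-compartment model (kel = k12 = k21 = 1 h⁻¹, V 14.6 L); 15-min
infusions are the default. Plasma mg/L are converted to the µM scale of
the cell model via molar masses (DOX 543.52, DEX 268.27 g/mol).

## Worked example

```r
library(cardiotd)

## 1. simulate an in vitro viability study (240 records, triplicates)
design <- default_design()
data <- generate_viability(design, td_params_ac16(),
                           default_degradation_params(),
                           noise_spec(cv = 0.075, seed = 42))

## 2. refit all nine TD parameters by pooled weighted least squares
fit <- fit_td_simultaneous(data, default_degradation_params())
print(fit)
#> Model fit (converged, 4 iterations)
#>            estimate rse_percent
#> kg          0.01183      2.2480
#> r0        101.81797      0.7656
#> s_dox       0.15230      7.9943
#> s_dex       0.01140      9.7157
#> kmax_dox    0.07102      1.9538
#> kc50_dox    0.10852      7.1780
#> ktr_dox     0.12655      2.8918
#> imax_dexi   0.07911     15.6225
#> ic50_dexi  56.33741     25.8543
#> objective (weighted SSR): 1.11114
```

The refit recovers the generating parameters: the growth rate (0.0118
vs 0.0115 h⁻¹), maximal kill rate (0.0710 vs 0.0697 h⁻¹) and transit
rate (0.127 vs 0.126 h⁻¹, a mean transit time of ~8 h) come back within
a few percent, while the interaction IC50 (56 vs 39 µM) is the least
precise parameter (%RSE ≈ 26), as expected for a half-saturation
constant probed by only five combination levels.

```r
## 3. translate to the clinic: DEX:DOX dose-ratio scan
scan <- scan_dose_ratios(dox_dose_per_m2 = 50,
                         ratios = c(0, 1, 5, 10, 20, 50), cycles = 3)
print(scan)
#> DEX:DOX dose-ratio scan (typical mode, window 0-1512 h, clamp_net_kill = TRUE)
#>  ratio dex_dose_per_m2        auec auec_ratio auec_ratio_literal
#>      0               0 11931336576    1.00000            1.00000
#>      1              50 13018894939    1.09115            1.09115
#>      5             250 16031843307    1.34368            1.34368
#>     10             500 18039749727    1.51196            1.55201
#>     20            1000 18902549924    1.58428            1.81244
#>     50            2500 17019340341    1.42644            2.07858
#> optimum (smallest ratio within 1% of the maximum): 20:1
```

`auec_ratio` is AUEC(DOX+DEX)/AUEC(DOX) over three Q3W cycles
(1512 h): larger means more viability preserved, i.e. more
cardioprotection. Protection rises steeply up to 10:1, gains little
from 10:1 to 20:1, and *declines* at 50:1, where the linear DEX
growth-inhibition term dominates at very high plasma concentrations —
so the clinically attractive region is the 10:1-20:1 plateau. The
`auec_ratio_literal` column shows the same metric without flooring the
net kill signal at zero.

Configuration-driven entry points (`run_generate()`, `run_fit()`,
`run_translate()`) wrap these steps for scripted pipelines, and
`inst/cli/cardiotd.R` exposes them as a command line.

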