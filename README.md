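# actopore

Active-gel pore dynamics and image quantification for adherent liposomes.

Cell-sized lipid vesicles (giant unilamellar vesicles) adhering to a
poly-L-lysine substrate spread, build membrane tension, and rupture through
a pore that expands across the basal surface. When the inner leaflet carries
a membrane-nucleated actin layer — passive, or contractile with myosin —
that membrane–cortex composite sets the rupture kinetics, and the vesicle
becomes a minimal mechanical model of the cell cortex. `actopore` is for
biophysicists working with such reconstituted systems: it implements the
active-gel theory of pore expansion, the length-scale arguments that
discriminate candidate mechanisms of peripheral actin assembly, the trace
and image quantifications used to measure these systems, and seeded
synthetic-data generators with ground truth for validating every estimator.

## The model

The pore radius in the membrane–cortex layer follows, during the early
phase of opening,

$$\frac{dR}{dt} \approx \frac{(\sigma_0 + 2 f_{adh} R_L/3)\,R - 2\gamma}
  {\eta_{eff}(R)},
\qquad
\eta_{eff}(R) = \eta + (\eta - 2\rho_0\tau_a\zeta)\,\frac{R^2}{R_L^2},$$

with contractile active stress $\sigma_0$, adhesive force density
$f_{adh}$, membrane tension $\gamma$, layer viscosity $\eta$, actin
turnover time $\tau_a$, and $\zeta = \partial(\sigma_a - P)/\partial\rho$
at the reference density. Pores above the critical radius
$R_c = 6\gamma/(3\sigma_0 + 2 f_{adh} R_L)$ expand to the contact radius
$R_L$; below it they reseal. A passive actin layer ($\zeta<0$) raises the
effective viscosity and slows rupture; myosin ($\zeta>0$) fluidizes the
layer. A moving-boundary radial solver for the coupled density/velocity
fields (continuity with first-order turnover plus a quasi-static force
balance against substrate friction) predicts the density pile-up at the
retracting edge and the friction-screened flow profiles. Companion
calculators give the bendo-capillary length $\sqrt{k_b/\gamma}$, the Thiele
length $\sqrt{D/k}$, and myosin thick-filament tension estimates.

## Worked example

```r
library(actopore)

p <- liposome_params("actin")      # calibrated defaults per condition
critical_radius(p) * 1e6           # 0.3 (um): spontaneous pores expand

for (cond in c("bare", "actin", "actomyosin"))
  cat(cond, pore_timescale(liposome_params(cond))$tau, "\n")
#> bare 20.0
#> actin 80.0
#> actomyosin 20.0
```

Integrating the opening law and fitting the saturating exponential gives
the pore-opening timescale per condition: the passive actin layer slows
rupture fourfold relative to a bare liposome (normalized
$\tau/\tau_{BL} = 4$), and myosin restores the bare-liposome kinetics —
the fluidization signature.

```r
bendocapillary_length(4e-18, c(0.3e-3, 5.0e-3)) * 1e9
#> 28.3 115.5     # nm; rounds to the 30-100 nm bracket

td <- thiele_defaults()
thiele_length(td$D, td$k) * 1e6
#> 1 10           # um

hypothesis_report(L_b = 115e-9, L_Th = c(1e-6, 1e-5), L_obs = 2e-6)
#> mechanosensing_supported: FALSE
#> reaction_diffusion_supported: TRUE
```

Membrane bending acts over tens of nanometres — far short of the ~2 um band
where peripheral actin assembles — while the ATP reaction–diffusion length
brackets it: assembly is diffusion-limited, not mechanosensed.

```r
g <- gen_traction_map(1.4e-4, R_contact = 1.1e-5, noise_sd_pa = 0.2,
                      seed = 1)
rim_tension(g$tmap) * 1e3
#> 0.141          # mN/m recovered from a noisy rim-localized stress map
```

The pipeline wrappers (`run_simulate`, `run_fields`, `run_fit`,
`run_lengths`, `run_quantify`, `run_synth`) tie the stages together from a
YAML or list configuration and write a JSON manifest per run; a thin
command-line wrapper lives at `inst/cli/actopore.R`. The methods vignette
(`vignettes/active-gel-pore-dynamics.Rmd`) documents the model assumptions,
numerical choices, estimator conventions and known limitations.

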