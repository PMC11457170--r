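---
title: "Valuing avoided methane from salt marsh restoration: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Valuing avoided methane from salt marsh restoration: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Freshening salt marshes emit methane. When a tidal restriction (an undersized
culvert, a tide gate, a dike) limits seawater flushing, marsh porewater
salinity drops and methanogenesis switches on; above roughly 18 psu, sulfate
reduction outcompetes it and methane production effectively ceases. Restoring
tidal flow therefore has a quantifiable greenhouse-gas co-benefit, and
salinity — cheap to measure — serves as the proxy for it. This package turns
pre/post-restoration salinity monitoring into (i) avoided methane estimates,
(ii) Verified Carbon Units (VCUs) priced at a market rate, and (iii) a social
benefit in dollars under the social cost of methane, then scales the
per-hectare rates to a regional tidal-restriction inventory.

## The accounting model

A site enters abatement accounting only if its restoration succeeded on the
salinity criterion: the pooled pre-restoration mean salinity was strictly
below 18 psu (the marsh was impaired) and the pooled post-restoration mean
strictly surpassed 18 psu. Equality resolves away from success in both
comparisons — a site whose pre-restoration mean already sat at 18.3 psu was
never impaired, and a post mean of exactly 18 has not "surpassed" the
threshold. `classify_site()` implements this three-way outcome
(`SUCCESS`, `FAILED_BELOW_THRESHOLD`, `NOT_IMPAIRED`).

For a successful site with area $A$ (m²), annual avoided emissions are

$$E_{\mathrm{avoided}} = (E_0 - E_1)\,A / 10^6 \quad [\text{t CH}_4\,\text{yr}^{-1}],$$

where $E_0$ and $E_1$ are areal emission factors (g m⁻² yr⁻¹) assigned by
salinity regime: pre-restoration either 19.4 (a cross-study geometric mean)
or 41.6 (the true mean) for impaired marsh, and post-restoration 0.46 for
marsh above 18 psu. The VM0033 crediting methodology's more conservative
tiered post-restoration factors (1.1 g CH₄ m⁻² yr⁻¹ for 18–20 psu, 0.56
above 20 psu) are available through `select_post_ef(..., scheme = "vm0033")`.

Credits convert avoided methane to CO₂-equivalents with the methane global
warming potential, here the IPCC AR6 100-year value for non-fossil methane:

$$\mathrm{VCU} = (E_0 - E_1)\,A \cdot \mathrm{GWP}_{\mathrm{CH_4}} + (C_0 - C_1),$$

with $\mathrm{GWP}_{\mathrm{CH_4}} = 27.2$ and one VCU per metric ton CO₂e.
The $C$ terms accept additional CO₂e flows (soil carbon, N₂O) already
expressed in t CO₂e yr⁻¹; they default to zero and are an interface, not a
model — this package does not derive sequestration factors. Credits
accumulate over each site's *qualifying years*: post-restoration years whose
annual mean salinity surpassed 18 psu. Restored marshes can show a lag phase
of one or more post-restoration years still below threshold; those years are
excluded because methane production was still possible. Credit revenue is
whole credits × $20/t CO₂e and is deliberately not discounted, matching
registry practice.

The social benefit applies an annual social-cost-of-methane (SCM) schedule
$Y_{i,a\%}$ (dollars per ton emitted in year $i$, discounted at rate $a$):

$$\mathrm{SCM}_{2050} = \sum_{i=2021}^{2050} (E_0 - E_1)\,A \cdot Y_{i,a\%}.$$

The annual abatement rate is held constant across the window, and the window
is fixed at 2021–2050 regardless of when the restoration happened: the SCM
schedules begin in 2021, so the valuation expresses *future* value from
already-completed restorations rather than value since completion. The 3%
discount rate is the default reported value; 2.5% and 5% schedules are
packaged for sensitivity, and a higher rate always yields a lower cumulative
benefit.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| salinity threshold | 18 | psu | methanogenesis cutoff in the salinity–methane literature |
| pre-restoration EF | 19.4 or 41.6 | g m⁻² yr⁻¹ | geometric vs true mean of published impaired-marsh fluxes |
| post-restoration EF | 0.46 | g m⁻² yr⁻¹ | published factor for marsh above 18 psu |
| GWP (CH₄, non-fossil) | 27.2 | — | IPCC AR6, 100-year horizon; AR4/AR5 and 20-year entries packaged |
| credit price | 20 | $/t CO₂e | prevailing voluntary-market assumption |
| discount rate | 3 | % | default in the SCC/SCM technical documents |
| valuation window | 2021–2050 | years | span of the published SCM schedules |
| inventory area | 2,304 | acres | regional marshes with restriction effect > 0.5 |

## Numerical conventions

Every computation carries full precision; rounding exists only in report
rendering, and the two report functions encode the printed conventions of
the source accounting exactly:

* `table3_report()` shows per-site annual emissions at 2 d.p. and computes
  the displayed annual VCUs from those *rounded* emissions (0.21 × 27.2 =
  5.712 → 5.7). Totals are sums of the rounded site columns (0.21 + 3.07 =
  3.28, although the unrounded total rounds to 3.27). Accumulation functions
  never do this: cumulative VCUs are unrounded per-site annual VCUs × years
  (which is what reproduces the published 985 and 2,140; using the displayed
  5.7/83.5 would give 987).
* Revenue is whole credits × price: registries issue integral credits, and
  the published $19,700 and $53,420 are 985 × 20 and 2,671 × 20.
* Cumulative social benefits are rounded per column; a combined total is the
  sum of the rounded per-site totals.
* Mass basis: the published factors are reported as grams of *carbon*
  (gC m⁻² yr⁻¹) while the accounting treats the resulting tonnage directly
  as methane mass. Replication mode (the default) keeps that convention,
  which is the only way to reproduce the published tables;
  `stoichiometric_correction = TRUE` multiplies carbon-basis factors by
  16/12 (the CH₄:C mass ratio) for a chemically explicit alternative, and
  mixing carbon-basis with methane-basis factors without the correction is
  an error.
* "Mt" in the source accounting denotes metric tons, never megatons; all
  interfaces here say metric tons.
* Statewide area: the inventory's acre figure is authoritative and is
  converted at 1 acre = 4,047 m² (0.4047 ha), the rounded conversion used in
  the source accounting — 2,304 acres = 932.4288 ha. This, and only this,
  reproduces the statewide dollar figures to the dollar at both emission
  factors ($264,903 / $12,044,257 and $575,402 / $26,161,602). One published
  figure is not reconcilable from any of the stated inputs — the statewide
  per-year crediting revenue range printed alongside the scaling results —
  while the companion per-acre figures ($96,072 yr⁻¹, $42 acre⁻¹ yr⁻¹, and
  the 20-year-GWP variant $285,389 yr⁻¹) match this package's
  `statewide` output exactly; we report the computed values.

## The SCM schedule is data, and part of it is reconstructed

The package applies Interagency Working Group SCM values; it never
re-derives damage estimates. The published record prints only the 2021–2030
values of the 3% schedule (1500, 1600, 1600, 1700, 1700, 1800, 1800, 1900,
1900, 2000 $/t). The packaged file
`inst/extdata/scm_schedule_synthetic.csv` is a *synthetic reconstruction*
of the full 2021–2050 schedules at 2.5%, 3% and 5%: annual values linearly
interpolated between the IWG five-year anchors and rounded to $100. For the
3% schedule the reconstruction reproduces all ten printed 2021–2030 values;
one interpolated year (2046) was set a step lower (2800 rather than 2900,
still monotone) so that the 2021–2050 sum equals $68,200/t — the sum implied,
to the dollar, by the published per-site and statewide 2021–2050 totals
divided by their abatement rates. Users with the authoritative annual
schedules should load them with `read_scm_schedule()`; every valuation
function accepts any schedule covering the window, and a gap inside the
window is an error naming the missing years.

## What the synthetic generator emulates — and what it does not

`generate_site()` emulates the structure of schoolyard-style salinity
monitoring: multiple transects, three soil depth classes (shallow 5–20 cm,
medium 35–50 cm, deep 65–80 cm), several sampling dates per year over a
multi-year window spanning a restoration date. Observations are drawn as
true mean + per-depth offset + optional seasonal sinusoid + independent
normal noise, truncated at 0 psu; lag years replace the generating mean with
a below-threshold value. The normal observation model is the minimal
structure supporting standard-error-based recovery tests — the monitored
sites are summarized only as means ± SE, which conflate transect, depth and
seasonal variance, and the generator does not attempt to decompose them
further. It also does not simulate methane flux (the method never observes
methane directly), autocorrelated within-year salinity dynamics, tidal
stage, or temperature. Passing recovery tests therefore shows the
*accounting* is faithful to its inputs, not that salinity monitoring of this
design identifies methane abatement in real marshes.

Seeds are explicit arguments everywhere, generation is byte-identical under
(scenario, seed), and the generator saves and restores the caller's RNG
state. `generate_inventory()` draws marsh areas from a lognormal (median
~2 ha with a long right tail, the familiar skew of marsh-size distributions)
and restriction-effect scores from a beta distribution, and records its own
filtered totals as attributes so downstream filtering can be checked
exactly.

Problem sizes in the shipped tests are deliberately modest — 200 seeded
replicates for the classification-recovery property, 250 synthetic marshes
for inventory recovery — chosen so Monte-Carlo error is far from the
asserted bounds while the whole suite stays fast.

## Design choices where the design was open

* **Duplicate same-day, same-depth measurements** are treated as independent
  observations; the pooled mean ignores transect, depth and season by
  design ("average of all values"), with depth- and year-stratified modes as
  opt-in variants (`stratify_by`). The depth-stratified mode is provided
  without asserting that the emission-factor framework is valid
  stratum-by-stratum — that remains an open scientific question.
* **Window attribution:** an observation dated on the restoration date
  belongs to the post window; calendar years (Jan–Dec) define annual means,
  and the restoration year is post from the restoration date onward.
* **Qualifying-year source:** when raw observations exist,
  `qualifying_years()` recomputes the counts; when only summary metadata is
  available, the recorded post-restoration monitoring-year counts (12 and
  11 for the two successful sites) are used directly.
* **ppt and psu** are treated as the same unit.
* **No interpolation of emission factors:** a site 1 psu below threshold and
  a site 10 psu below receive the same pre-restoration factor; the salinity
  proxy supports only regime assignment, not a dose–response.
* **GWP uncertainty bands** (±11 at AR6 100-yr) are stored and reported but
  not propagated by default; low/high runs can pass `value ± uncertainty`
  directly as the `gwp` argument.
* **Credits are kept real-valued** internally and rendered whole at
  reporting time.

## Known limitations

The statewide estimate is an extreme upper bound: it assumes every
restricted marsh is successfully restored, while only a third to two-thirds
of the monitored projects achieved the qualifying salinity change —
`success_adjusted()` exposes that scaling. Marsh extent is assumed fixed;
boundary migration, sea-level rise and within-marsh spatial heterogeneity of
methane flux are out of scope, as is any GIS processing of the restriction
inventory (it is consumed as a table). The salinity proxy itself bounds the
credibility of every downstream dollar figure; nothing here substitutes for
direct flux measurement.
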