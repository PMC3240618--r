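---
title: "A kinetic model of glutamatergic signaling in a CA1 dendritic spine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A kinetic model of glutamatergic signaling in a CA1 dendritic spine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinesim)
```

## The model

`spinesim` simulates the biochemistry of glutamatergic transmission at a
single CA1 dendritic spine. The spine is divided into four well-mixed
compartments — synaptic cleft (0.0015 µm³), postsynaptic density
(PSD, 0.002 µm³), cytosol (0.02 µm³) and endoplasmic reticulum
(ER, 0.002 µm³). All species are described by deterministic mass-action (or
Michaelis–Menten/Hill) ordinary differential equations; concentrations are
uniform within a compartment, and cross-compartment transport is carried by
explicit channels, pumps and diffusive exchange terms whose rates are
expressed as amounts so that mass balances exactly between compartments of
different volume.

The signalling network has five interacting parts.

**Glutamate in the cleft.** A presynaptic release event deposits ~3000
glutamate molecules as a point source. The cleft plus perisynaptic space is
treated as a thin disc (effective height ≈ 14.6 nm) in which glutamate
spreads radially with an effective diffusion coefficient D = 330 µm²/s and
an initial Gaussian spread of 200 nm, giving the closed form
C(r,t) = N exp(−r²/4D(t+t₀)) / (4πD(t+t₀)h). Generic transporters at
0.5 mM, excluded from the central 200 nm, remove glutamate as a
pseudo-first-order sink (the 0.5 mM transporter pool is never approached by
the ≤ 40 µM glutamate transients beyond the exclusion zone, so the two-step
binding/translocation scheme collapses to its binding step). With uptake the
radial problem is solved once on a log-spaced finite-volume grid and
superposed per release — the sink is linear, so superposition is exact. The
disc height is set so a single release peaks at 40 µM at 1000 nm without
uptake; the binding rate is set so the same peak is 32 µM with transporters.
The peak concentration of the free kernel is independent of D (it equals
N e⁻¹/πr²h), so these two calibrations do not constrain the diffusion time
scale.

**mGluRI activation.** Group-I metabotropic receptors (5 receptors ≈ 8 µM)
follow a cubic ternary-complex scheme: eight states spanning
{ligand-free/bound} × {inactive/active} × {G-protein-free/coupled}, with all
edge constants derived from multiplicative state weights so every
thermodynamic loop is exactly consistent. Receptor-coupled Gq binds
glutamate with high affinity; nucleotide exchange on coupled active
receptors releases GαGTP + Gβγ. Two assay conditions matter for the
calibration and are reproduced as the experiments define them:

* the *glutamate binding* curve (10-s applications) is computed in the
  nucleotide-free condition — exchange disabled — because high-affinity
  agonist binding in membrane preparations is measured without GTP, where
  the agonist–receptor–G ternary complex is stable. This yields an EC50 of
  ~0.56 µM.
* the *functional* GαGTP concentration–response (140-min stimulations) runs
  with full GTP turnover; sustained exchange keeps receptors mostly
  uncoupled, so the response tracks the low-affinity uncoupled occupancy and
  the branch probability that a captured G protein is activated before it
  unbinds. This yields an EC50 of ~5.6 µM, tenfold higher than the binding
  potency, as in the underlying GTPγS accumulation data.

**PLC/IP3 branch.** GαGTP binds PLC in a calcium-dependent manner
(Hill factor with K = 0.3 µM); PLC-bound Gα hydrolyses its GTP quickly (the
GAP effect) and active PLC hydrolyses PIP2 into IP3 + DAG. The small PLC
pool (0.5 µM) saturates during strong transients, which compresses the top
of the transient dose–response and places the 1-s square-pulse potencies
(IP3 ~1.0 µM, Ca ~1.5 µM) between the high- and low-affinity receptor
regimes. Resting IP3 (100 nM) is maintained by a constitutive PLC background
that carries the same calcium dependence, normalised to its basal value —
this term is derived at assembly so that resting IP3 production exactly
balances degradation. IP3 is degraded by a calcium-dependent 3-kinase
(Hill n = 2, K = 0.4 µM, to IP4) and a 5-phosphatase (to IP2); the calcium
sensitivity of the 3-kinase is what makes strong ionotropic calcium influx
*suppress* net IP3 at high stimulation frequency.

**IP3 receptor and ER calcium.** IP3R gating follows the De Young–Keizer
scheme: each of four identical subunits carries an IP3 site, an activating
Ca site and an inhibitory Ca site (eight states; dissociation constants
d2 = 1.049, d4 = 0.1445, d5 = 0.08234 µM follow the canonical set, the IP3
affinity d1 = 0.2 µM sits within the experimental 0.1–1 µM range and is the
calibration anchor for the calcium pulse potency, and d3 is derived from the
thermodynamic cycle d1·d2 = d3·d4 so detailed balance is exact).
The channel conducts when 3 of 4 subunits are in the IP3-bound,
activation-bound, inhibition-free state, P_open = x₁₁₀³ (the 4-of-4 variant
is configuration-exposed). At saturating IP3 the equilibrium open
probability is bell-shaped in calcium with its maximum near 0.3 µM. ER
release (IP3R flux and a passive leak, both proportional to the ER–cytosol
gradient) is balanced by SERCA (Hill n = 2, K = 0.2 µM); the leak
coefficient is derived at assembly so the 0.5 mM ER baseline is an exact
fixed point.

**Ionotropic receptors and calcium homeostasis.** 80 AMPA and 20 NMDA
receptors sit at 20 nm from the release site, each described by a five-state
Markov scheme (two sequential binding steps, one open state, one
desensitised state) with fast/low-affinity AMPA and slow/high-affinity NMDA
constants. The NMDA open fraction drives calcium into the PSD through a
fixed-driving-force coefficient jointly calibrated against the full model's
single-release (~516 nM) and 1-s tetanic (~3.3 µM) cytosolic calcium peaks; AMPA is calcium-
impermeable by default (GluA2-containing assumption, configuration flag to
change). There is no membrane potential and no Mg²⁺ block — the model
describes biochemistry only, which is a stated limitation. Cytosolic calcium
is cleared by PMCA (Hill n = 2) and NCX (n = 1) against a derived
plasma-membrane leak from the clamped 2 mM cleft reservoir, buffered by
calmodulin, calcineurin and PKC (pure 1:1 buffers, no downstream enzymatic
action) in both cytosol and PSD, and exchanged between PSD and cytosol by
amount-conserving first-order diffusion (as is IP3).

## Derived-at-assembly constants

Three constants are solved when the model is assembled so that the stated
resting state is an exact fixed point, mirroring the usual
"leak balances pump" construction: the plasma-membrane leak (balances
PMCA + NCX at 60 nM cytosolic Ca against 2 mM cleft Ca), the ER leak
(balances SERCA minus the basal IP3R flux at 0.5 mM ER Ca), and the
constitutive IP3 production (balances IP3 degradation at 100 nM IP3). The
receptor cube and G-protein pools are initialised from the separately
equilibrated cascade. Equilibration (`equilibrate()`) therefore converges in
seconds of CPU time with residuals near machine precision, and perturbed
initial states relax back to the same baseline.

## Stimulation protocols and analysis

`make_protocol()` builds deterministic release-event lists: `single`,
`burst4` (4 pulses at 100 Hz), `tbs5`/`tbs9` (5 or 9 bursts with 200 ms
between burst onsets; the 9-burst pattern is read as one train of 9 bursts
spanning 1.64 s), `tetanus` (f Hz for a fixed duration) and generic
`pulses`. Simulations restart the stiff solver (lsoda, rtol 1e-8,
atol 1e-12 µM) at every release so the millisecond glutamate transients
cannot be stepped over; output is interpolated onto a uniform grid
(default 1 ms).

The analysis layer quantifies transients exactly as the figures do:
above-baseline area under the curve by left-endpoint Riemann sum on the
uniform grid; EC50s by least-squares four-parameter logistic fits on
log-dose; decay kinetics by mono-exponential fits from the post-stimulus
peak. The transient *duration* is reported as the time the trace spends
above baseline plus 5 % of the peak elevation — a bandwidth chosen to match
what is visually resolvable on a published trace. Receptor contributions are
decomposed by running the identical protocol on the mGluRI-only,
AMPA/NMDA-only and all-receptor model variants (they share the same
baseline, since closed iGluRs carry no flux) and comparing AUCs; the
additivity index AUC(all)/(AUC(mGluRI)+AUC(iGluR)) exceeds 1 for calcium
(supra-additive interaction through calcium-stimulated PLC and IP3R
activation) while total IP3 falls below the mGluRI-only response at high
frequency (calcium-stimulated 3-kinase degradation).

## Parameter provenance and calibration targets

Affinities and rate constants originate from the literature for each
component scheme (ternary-complex GPCR activation, De Young–Keizer IP3R,
SERCA/PMCA/NCX pump forms, Jonas-type AMPA and Lester/Jahr-type NMDA
kinetics) and are then jointly calibrated against a fixed set of anchors:
EC50s of 5.6 µM (functional), 0.56 µM (binding), 1.5 µM (calcium, 1-s
pulses) and 1.0 µM (IP3, 1-s pulses); resting concentrations 60 nM Ca /
100 nM IP3 / 2 mM cleft / 0.5 mM ER; a ~200 nM calcium transient with 800 ms
mono-exponential decay for five releases at 50 Hz; 40/32 µM glutamate peaks
at 1000 nm; and a ~516 nM single-release calcium peak for the full model.
The shipped configuration (`inst/extdata/spine_model.yaml`) is this
package's own transcription of that calibrated set; every value is
configuration-exposed and the derived constants adapt automatically when a
parameter is changed.

Numerical choices worth noting: the IP3R activating-site on-rate is twice
the canonical value (equilibrium constants unchanged) so channel closure
does not rate-limit the calcium decay; the canonical d3 is adjusted by
4 × 10⁻⁴ to make detailed balance exact rather than approximate; inside the
adaptive integrator, transiently negative trial states are clamped to zero
for rate evaluation while reported trajectories are clipped at zero; the
radial glutamate grid uses 260 log-spaced finite volumes out to 60 µm, which
conserves released mass to better than 1 %.

## What the simulated conditions do and do not show

All results are deterministic ODE outputs: there is no trial-to-trial
variability, no stochastic channel gating, no vesicle-release failure, and
no spatial gradient within a compartment. Receptor counts in a real spine
are small (5 mGluRI, 20 NMDAR), so the deterministic fractions computed here
are ensemble means over many trials of a strongly fluctuating system.
Glutamate spillover from neighbouring synapses, membrane-voltage dynamics,
Mg²⁺ block of NMDARs, receptor desensitisation-independent plasticity and
downstream calmodulin/calcineurin/PKC enzymatic signalling are outside the
model's scope. Passing the packaged tests shows the implementation
reproduces the calibration anchors and structural invariants of this
biochemical model, not that the model captures any particular experimental
preparation beyond those anchors.

Two geometric limitations of the thin-disc cleft are worth knowing. The
free-diffusion solution in a sheet decays only as 1/t, so low-micromolar
glutamate persists near the release site for tens of milliseconds. The slow,
high-affinity NMDA scheme integrates that tail, which (i) leaves a residual
~8 % transporter sensitivity in the NMDA peak open fraction where an
idealised synapse shows essentially none, and (ii) inflates the
single-release responses that form the denominators of the
frequency-facilitation AUC ratios, which come out roughly half the
calibrated model family's nominal factors while preserving their ordering
(1000 nm > 100 nm; full-model location ratio ~1.18). A three-dimensional
porous far field would remove the tail but cannot reach the 40 µM
single-release peak at 1000 nm that anchors the geometry, so the sheet is
kept and the discrepancy documented. Similarly, the single NMDA
desensitised state cannot make the sustained (tetanic) and transient
(single-release) calcium influx ratios match both of their anchors exactly;
the shipped constants split the difference (both within ~11 %).

## Problem sizes

The packaged experiments use the sizes at which the results are stable:
12-point log-spaced dose grids for the receptor-level curves, 7-point grids
for the 1-s pulse curves (each point a 12-s simulation), 8-s records for the
50-Hz calibration transient, and ~22-s records (protocol span plus a 20-s
tail) for the theta-burst AUC experiments. Halving the solver tolerances
changes every reported peak and AUC by well under 0.5 %.

## A worked run

```{r example, eval = FALSE}
cfg <- spine_config()
cfg$simulation$receptors <- "mglur"
model <- assemble_spine_model(cfg)
base <- equilibrate(model)
round(attr(base, "baselines"), 4)

res <- run_protocol(model, make_protocol("pulses", frequency = 50,
                                         n_pulses = 5),
                    duration = 8, baseline = base)
max(res$series$Ca_cyt)                       # 0.200 uM peak
fit_mono_exponential_decay(res$series$time, res$series$Ca_cyt,
                           from = 0.08)      # tau = 0.76 s
```
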