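---
title: "Modelling translation under tRNA synthetase depletion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling translation under tRNA synthetase depletion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribocharge)
```

## The problem

Charged (aminoacylated) tRNAs feed translating ribosomes; aminoacyl-tRNA
synthetases recharge them. When one synthetase is depleted — by a tet-off
promoter and doxycycline in yeast, or by loss-of-function mutation in human
disease — intuition says its cognate uncharged tRNA should accumulate, stall
ribosomes at the cognate codons, and trigger the Gcn2 kinase / *GCN4*
amino-acid-starvation response. Experimentally the starvation response does
fire, yet bulk charging levels of the affected tRNA barely move and
polysomes show no queues. `ribocharge` implements the two stochastic models
that dissect this: a whole-cell exclusion-process model of ribosome traffic
coupled to charging kinetics (GTM), and a three-state sequestration model of
the uncharged pool (SSM).

## The global translation model

mRNAs are 1D codon lattices; ribosomes are extended particles with a
footprint of `W = 9` codons. The *tracked position* of a ribosome is the
codon it is translating; a ribosome at tracked position `p` covers sites
`p .. p+W-1`, so two tracked positions on one lattice always differ by at
least `W`, and a hop from `i` to `i+1` requires the next ribosome to sit at
`i+1+W` or beyond. Initiation places a ribosome at site 1 and needs sites
`1..W` free. This convention (rather than letting the footprint trail the
tracked site) makes "the next codon" of a blocked ribosome the codon
`i + W`, and makes the entry region exactly one footprint.

The state of the cell is one coupled continuous-time Markov jump process:

* **Initiation** on an mRNA of category *m* at rate
  $\alpha_m(R_\mathrm{free}) = \alpha_{0,m}\,\min(R_\mathrm{free}/R^*, 1)$ —
  a stepwise-linear function of the free ribosome pool with a single
  breakpoint $R^*$. Related models in the literature sometimes use several
  linear pieces; one breakpoint is the minimal
  stepwise-linear form, and all observables here depend on it only through
  the realized rate at the steady-state pool size, to which $R^*$ is set
  self-consistently during calibration. Every initiation takes a ribosome
  from the shared pool; termination and drop-off return it. The total
  ribosome number is strictly conserved.
* **Elongation** out of codon $i$ at rate
  $k(i) = \lambda \, w(i) \, T^c_{c(i)}$, proportional to the instantaneous
  count of cognate charged tRNA, with a wobble-pairing efficiency $w \le 1$
  for codons read through non-Watson–Crick third-position pairing. Each hop
  consumes one charged tRNA **of the codon being left**: the hop *is* the
  translation of codon $i$, so its cognate tRNA is the one delivered and
  used. The wobble factor defaults to 0.64 for wobble-decoded codons (a
  fixture convention, configurable per codon in the map).
* **Termination** at the stop codon at constant, non-limiting rate $\beta$
  (default 10/s), identical for all mRNAs; it increments the per-category
  protein counter. The stop codon is factor-mediated: it consumes no tRNA
  and contributes no tRNA demand.
* **Drop-off** at rate $\gamma$ (default $5\times10^{-4}$/s) for every
  ribosome not at a stop codon, uniformly along the lattice (no site
  dependence is modelled); it frees the ribosome without producing protein,
  and consumes no tRNA.
* **Recharging** of species $i$ at rate
  $\chi_i = V_{max,i}\, T_i^u / (K_{m,i} + \sum_j T_j^u)$, the
  Michaelis–Menten law with competitive inhibition, the sum running over
  the isoacceptors sharing the amino acid (they compete for one synthetase).
  $V_{max,i} = d\,E_0\,k_{cat}$, so the synthetase protein ratio $d$ scales
  the maximum charging rate of the depleted enzyme only. Recharging is a
  stochastic event (one molecule per event), which keeps the whole system a
  single exact jump process whose mean obeys the balance
  "recharging − usage".
* **Feedback** (optional): slowed growth feeds back on initiation-factor
  and ribosome production, modelled minimally as
  $\tilde\alpha_0 = d\,\alpha_0$.

### Event engine

The engine (`src/gtm_engine.cpp`) is Gillespie's direct method over the five
event classes — there is no discrete time step, hence no tie-breaking.
Propensities are recomputed by a linear scan over the active entities (all
bound ribosomes, lattices and tRNA species) at every event. At desk scale
that is a few hundred operations per event and empirically faster and safer
than incremental caching: a single tRNA-pool change reprices *every*
ribosome sitting on a cognate codon, so correct caching needs per-species
occupancy indices that buy nothing at these sizes. All randomness comes from
R's RNG, so `set.seed()` (or the `seed` argument, which seeds a local RNG
stream) reproduces trajectories bit-for-bit.

Observables are propensity-weighted time averages over the post-burn-in
window (exact for a jump process): the global current $J$ (proteins/s) and
per-category currents $J_a$, the per-site density profile of tracked
positions, per-species charging fractions $Q_i = T^c_i/T^t_i$ and their
mean $\langle Q\rangle$, the realized initiation rate
$\langle\alpha\rangle$ (the copy-weighted mean of
$\alpha_m(R_\mathrm{free}(t))$, i.e. the rate function, not thinned by
steric blocking), and the mean elongation rate, measured as hops per
ribosome-second on the lattice. Monte-Carlo standard errors come from ten
batch means. Because the model's "current" can mean either proteins/s or
the site-averaged ribosomal flux $k_j\rho_j(1-\rho_{j+1})$ — which coincide
per mRNA at steady state when drop-off is rare — both are reported
(`J` and `site_flux`).

### Calibration

Three global scale factors are fitted at wild type ($d = 1$):
`lambda_scale` to a mean elongation rate of 10 codons/s, `vmax_scale` to a
mean charging level of 80%, and `alpha_scale` to a realized initiation rate
of 0.15/s — the three physiological anchors of the model. The fit is a
damped multiplicative fixed-point iteration with three refinements that
experience with the coupled system forced:

1. *Coupling compensation.* Raising the charging level raises every charged
   pool and hence every hopping rate, so the λ-update anticipates the
   charging correction (`target/measured × Q/Q_target`); without this the
   two controls fight and the iteration limit-cycles.
2. *Saturation-aware V_max step.* At steady state usage equals
   $V_{max}\,s(T^u)$ with $s(T^u)=T^u/(K_m+T^u)$ nearly flat when
   $T^u \gg K_m$, so the naive $(1-Q)$-ratio update overshoots badly; the
   step instead inverts the Michaelis–Menten law at a typical pool size.
3. *Verification runs.* tRNA pools relax over tens of seconds, so a short
   calibration window can agree with the targets transiently while the pool
   still drifts. Iterations chain their final pool state (warm start), and
   convergence is only declared after a 3× longer confirmation window also
   meets tolerance; failing confirmations feed their (better) measurements
   back into the update.

Defaults: 80 s windows with 30 s burn-in, relative tolerance 5% (per-metric
tolerances accepted), at most 40 iterations, error with diagnostics on
non-convergence. The calibrated fixture carries its equilibrated pool state,
so downstream wild-type runs start at the steady state rather than relaxing
towards it.

## The synthetase sequestration model

Per tRNA species, the uncharged pool is split into *empty* ($e$, free, the
Gcn2-visible form) and *bound* ($b$, sequestered on the synthetase
mid-reaction); $c$ is charged, and $e + b + c = T^t$ is conserved exactly.
Mass-action rates: association $k_1(\tilde E_0 - b)\,e$ (free enzymes
$\tilde E_0 - b$, so binding saturates when every enzyme is occupied),
dissociation $k_0 b$, aminoacyl transfer $k_2 b$, and usage $f\,k_3\,c$.
Depletion rescales the enzyme count of the target amino acid only,
$\tilde E_0 = d\,E_0$; the growth-coupling factor $f = 5d$ for $d<0.2$ and
$1$ otherwise applies to the usage of **all** species, because slowed growth
slows all translation. The 20-amino-acid network (one pool per amino acid)
is the default; any species set works.

Two routes to the same answer are implemented deliberately: an exact
Gillespie simulation (`simulate_ssm()`, Rcpp) and the deterministic fixed
point (`ssm_steady_state()`), obtained by reducing the stationary conditions
to one monotone scalar equation in $c$ (flux balance gives
$b = f k_3 c / k_2$, association balance gives $e$ in terms of $b$) solved
by bisection — the oracle against which the stochastic means are tested at
$10^4$ copies.

### Choosing the rate constants

The model's biological anchors fix the functional forms and the wild-type
configuration (about 80% charged, with the uncharged remainder almost
entirely enzyme-bound) but not numeric rate constants, so the package
calibrates them in closed form from that configuration: given the usage constant $k_3$
and a dissociation/transfer ratio, the target fixed point determines $k_2$
and $k_1$ exactly (`ssm_params()`). Two desk-scale choices deserve note:

* `bound_share = 0.96`: the wild-type fixed point puts 96% of the uncharged
  pool in the bound state, so the *stochastic* steady state — which
  fluctuates around it — stays clearly above the "at least 95% sequestered"
  regime that defines the sequestration picture.
* `E0 = T^t` (enzymes comparable in number to tRNAs). Flux balance forces
  $b(d) = 5d\,k_3 c/k_2$ below the coupling threshold, which must stay
  within the enzyme capacity $d\,E_0$ for charged levels to hold roughly
  constant under depletion — that requires $E_0 \ge 5\,b_{wt}$, i.e.
  enzymes cannot be scarce relative to the wild-type bound pool. With a
  scarcer enzyme (say $E_0 = 0.2\,T^t$) the three-state model saturates its
  enzymes at small $d$ and charged levels collapse roughly five-fold,
  contradicting the depletion phenomenology the model exists to capture;
  the non-saturating choice reproduces it. The constants are fixture
  defaults, not measured values, and every one is a user-settable argument.

## The synthetic fixture

The desk-scale cell (`synthetic_fixture()`) emulates the structure of the
coarse-grained yeast system while staying small enough for exhaustive
testing: 8 category-representative mRNAs of 200 codons (each built by
largest-remainder apportionment of a random codon composition, then
shuffled), copy numbers ramping 8→1 and initiation constants on a
descending four-fold geometric ramp around 0.2/s — transcript classes in a
real cell differ several-fold in initiation rate, and the spread makes the
wild-type per-category current ranking resolvable above Monte-Carlo
counting noise — a reduced genetic
code of 18 sense codons / 16 tRNA species / 15 amino acids with two
glutamine isoacceptors (CAA and CAG) competing for one synthetase and two
wobble-decoded codon pairs, 200 ribosomes, and ~24,000 tRNAs allocated
proportionally to codon demand (floor 350) with synthetase capacities sized
so calibration starts near its fixed point. Glutamine-codon content spans
0.2–3% across categories — from nearly Gln-free to about six Gln codons per
mRNA — and is assigned in *shuffled* order so Gln content is not confounded
with the copy-number/initiation ranking (otherwise the no-feedback depletion
would reorder categories in rank order and the concordance contrast would be
invisible). Every category with a positive requested Gln fraction is
guaranteed at least one Gln codon: glutamine occurs in essentially every
real protein, and a Gln-free high-copy transcript class would keep
translating at full speed under depletion, qualitatively changing the
whole-cell response; an explicitly requested fraction of 0 still yields a
Gln-free mRNA for controlled experiments.

What the fixture does **not** emulate: the real 93-category GO-Slim
transcriptome with its measured abundances and initiation constants, the
full 61-codon code and 41 tRNA species, measured tRNA copy numbers, or
per-enzyme kinetic constants — those come from genome databases and
published model repositories, and the TSV readers accept them when
available. Passing
tests therefore demonstrate the mechanisms (competition, queueing, feedback,
sequestration) at desk scale, not quantitative agreement with any particular
strain.

`downscale()` maps a larger configuration to a smaller one: all counts
(ribosomes, tRNA totals, enzyme abundances, mRNA copies, the initiation
breakpoint) and $K_m$ are divided by a volume factor ω (counts rounded
half-up, minimum 1), unary rates are untouched, and `lambda_scale` is
multiplied by ω so the physical hop rate per ribosome — which multiplies a
*count* of charged tRNAs — stays intensive, exactly as dividing $K_m$ keeps
enzyme saturation intensive. Per-copy currents, charging levels and
densities are then scale-invariant up to rounding; integer rounding of
small copy numbers is the dominant distortion, so scale-invariance checks
use copy numbers divisible by ω.

## Numerical choices and degenerate inputs

* Time averages accumulate the state over each inter-event interval before
  the event fires (exact for a jump process); the burn-in boundary splits
  the interval it falls in. Default burn-in: the first 20% of `t_end`.
* Largest-remainder apportionment (ties broken by index order) converts
  fractional codon compositions to integer multisets deterministically and
  mass-preservingly; the same rule allocates tRNA totals.
* Counts are rounded half-up (`floor(x + 0.5)`), never banker's rounding,
  so downscaling is monotone; copy numbers and pools floor at 1 with a
  warning when a pool collapses.
* Event selection scans subtract rates from a uniform draw; the last
  eligible candidate is kept as a fallback against floating-point
  undershoot, so a selection can never fall off the end of the scan.
* Degenerate inputs fail fast with named errors: codons without a cognate
  species, duplicate synthetases, charged counts above totals, bound counts
  above enzyme capacity, `t_end <= burn_in`, zero-mass compositions,
  consuming from an empty charged pool (whose event rate is zero, so the
  engine can never attempt it — the error guards the public API).
* An event-count guard (`max_events`, default $5\times10^7$) truncates
  runaway simulations with a warning rather than hanging.
* The empty transcriptome is legal and produces zero current; a lattice
  with $\beta = 0$ jams completely and the engine terminates early when the
  total propensity reaches zero.

## Problem sizes used by the tests

The suite runs the desk fixture described above: calibration on 80 s
windows, confirmation runs of 240 s (roughly $4\times10^5$ events),
depletion runs of 400–700 s, a conservation run of 600 s (over $10^6$
events),
master-equation comparisons on lattices of up to 8 sites (a few hundred
enumerable states), and SSM runs of 20 species × $10^4$ copies (about
$3\times10^6$ events). These sizes give Monte-Carlo standard errors well
inside the tolerances being asserted while keeping the whole suite at the
scale of seconds per file.

## Known limitations

* The initiation feedback is the minimal linear form $\tilde\alpha_0 =
  d\alpha_0$; Gcn2/eIF2α signalling is not modelled mechanistically (the
  SSM's empty pool is the kinase-visible readout, not a kinase model).
* Elongation-factor (eEF1A) ternary-complex formation, amino-acid pool
  depletion, mRNA synthesis/decay and spatial effects are out of scope.
* One cognate tRNA species per codon (many-to-one wobble only); near-cognate
  competition and misreading are not represented.
* The GTM's drop-off is site-independent; real processivity failures are
  context-dependent.
* Desk-scale counts make relative fluctuations larger than in a real cell;
  quantities reported as percentages are robust to this, absolute currents
  are fixture-specific.
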