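---
title: "Models and methods behind the nmrdyn pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the nmrdyn pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrdyn)
```

# Scope

`nmrdyn` analyses the standard quantitative readouts of a solution-NMR
protein dynamics study: amide ^15^N relaxation interpreted with the
Lipari–Szabo model-free formalism, the overall rotational correlation time
from R2/R1 ratios, hydrogen/deuterium exchange protection factors,
residual dipolar couplings and their alignment tensor, chemical-shift
perturbation screening for ligand binding, and coordinate-precision
metrics over multi-model NMR ensembles. A seeded generator produces
synthetic two-state (apo / cofactor-bound) datasets with known ground
truth, so every stage is validated by parameter recovery rather than by
unavailable raw spectra.

# Spin physics and the model-free description

Relaxation of a backbone amide ^15^N nucleus is driven by the ^15^N–^1^H
dipolar interaction and the ^15^N chemical shift anisotropy, both
modulated by molecular motion. The motion enters through the spectral
density

$$J(\omega) = \frac{2}{5}\left[\frac{S^2\,\tau_c}{1+(\omega\tau_c)^2}
 + \frac{(S_f^2 - S^2)\,\tau}{1+(\omega\tau)^2}\right],
 \qquad \tau^{-1} = \tau_c^{-1} + \tau_e^{-1},$$

where $\tau_c$ is the overall (isotropic) rotational correlation time,
$S^2 \in [0,1]$ the generalized order parameter of the N–H bond
(1 = rigid), $\tau_e$ the effective correlation time of the internal
motion, and $S_f^2$ the fast-motion order parameter of the extended
two-timescale form ($S_f^2 = 1$ recovers the original single-timescale
model). The observables are

* $R_1 = \tfrac{d^2}{4}[J(\omega_H{-}\omega_N) + 3J(\omega_N) +
  6J(\omega_H{+}\omega_N)] + c^2 J(\omega_N)$
* $R_2 = \tfrac{d^2}{8}[4J(0) + J(\omega_H{-}\omega_N) + 3J(\omega_N) +
  6J(\omega_H) + 6J(\omega_H{+}\omega_N)] +
  \tfrac{c^2}{6}[4J(0)+3J(\omega_N)] + R_{ex}$
* $\mathrm{NOE} = 1 + \tfrac{d^2}{4}\,\tfrac{\gamma_H}{\gamma_N}
  [6J(\omega_H{+}\omega_N) - J(\omega_H{-}\omega_N)]/R_1$

with $d = (\mu_0/4\pi)\hbar\gamma_H\gamma_N r_{NH}^{-3}$ and
$c = \omega_N\,\Delta\sigma/\sqrt{3}$. The chemical-exchange term
$R_{ex}$, reporting on µs–ms conformational transitions, enters $R_2$
only.

**Constants.** $\gamma_H = 2.6752219\times10^8$,
$\gamma_N = -2.7126\times10^7$ rad s^-1^ T^-1^, $r_{NH} = 1.02$ Å,
$\Delta\sigma = -160$ ppm — the community-standard choices for backbone
amides; all overridable through `spin_constants()`, and every report
echoes the constants used. **Sign convention:** Larmor frequencies are
used as magnitudes inside $J(\omega)$; the negative $\gamma_N$ is
honoured only in the NOE expression, where it matters physically (this
is why flexible residues show depressed or negative NOEs). Only
isotropic overall tumbling is modelled — a single $\tau_c$ per state, no
axially symmetric diffusion tensor — because each state of the study
system is summarized by one correlation time.

# Estimating the overall correlation time

For residues without fast internal motion or exchange, the ratio
$R_2/R_1$ depends on $\tau_c$ but not on $S^2$ (the order parameter
scales both rates equally when $\tau_e \approx 0$). `estimate_tauc()`
therefore inverts the rigid-limit ratio per residue by a 1-D root search
over $\tau_c \in [0.5, 50]$ ns and averages over residues, after two
filters:

* **NOE cutoff** (default 0.65): sub-ns mobility depresses the NOE and
  biases the ratio; flexible residues are excluded.
* **Ratio trimming** (default 1.5 population SDs about the mean):
  exchange broadening inflates $R_2$, so ratio outliers are excluded.
  The population (not sample) SD makes the estimate exactly invariant
  under duplication of the record set.

The result is the trimmed mean ± SEM, with every exclusion recorded and
its reason named. The defaults are declared package choices — the
kind of exclusion rule every study of this type applies but rarely
prints — and both are exposed as arguments.

# Per-residue model-free fitting

With $\tau_c$ fixed (a two-stage procedure keeps three-observable fits
identifiable), each residue is fitted against the candidate models
M1 {S²}, M2 {S², τ~e~}, M3 {S², R~ex~}, M4 {S², τ~e~, R~ex~} and
optionally M5 {S~f~², S², τ~s~}, by minimizing
$\chi^2 = \sum[(\mathrm{obs}-\mathrm{calc})/\sigma]^2$ within bounds
($S^2 \in [0,1]$, $\tau_e \in [0, \tau_c)$, $R_{ex} \in [0, 50]$ s^-1^).

**Numerical choices.** The internal time is optimized as
$\log_{10}\tau_e$: internal motions span picoseconds to nanoseconds, and
the $\chi^2$ surface carries a well-known spurious minimum near
($S^2{=}1$, $\tau_e{\approx}\tau_c$) that linear-scale searches fall
into. A fixed 5-point-per-parameter multi-start grid (log-spaced for
$\tau_e$) precedes bounded quasi-Newton (`L-BFGS-B`) refinement from the
five best grid nodes in a fixed order, so fits are deterministic. On
noiseless data this recovers generating parameters to better than 0.01%.
M5 is parameterized as ($S_f^2$, $S_s^2$) with $S^2 = S_f^2 S_s^2$ so
the constraint $S^2 \le S_f^2$ holds by construction.

**Model selection.** Candidates are ranked by the small-sample-corrected
information score AICc $= \chi^2 + 2k + 2k(k+1)/(n-k-1)$, ties broken
toward fewer parameters. With single-field data ($n = 3$ observables)
the correction term is undefined for $k \ge 2$, so whenever any
candidate reaches that regime the ranking falls back to plain AIC
$= \chi^2 + 2k$ for all candidates — using the correction for some
models and not others would bias the comparison. Information-based
selection was chosen over stepwise F-tests because nested F-testing is
fragile with three observables per residue.

**Uncertainties.** `monte_carlo_errors()` refits synthetic datasets
drawn from Normal(obs, σ~obs~) and reports per-parameter SDs in natural
units; the generator is seeded explicitly and leaves the global RNG
state untouched, so results are bit-reproducible.

**Exchange classification.** A residue is labelled as undergoing
conformational exchange iff its fitted $R_{ex}$ strictly exceeds
2 s^-1^; a residue at exactly the threshold is not flagged. If data at
several fields are combined, $R_{ex}$ is assumed to scale as $B_0^2$.

# Hydrogen/deuterium exchange and protection factors

Peak-intensity decays are fitted as $I(t) = I_0 e^{-k t}$ with a fixed
zero baseline (fully exchanged amides vanish in D~2~O; an incomplete-
exchange baseline can be added by the caller before fitting). Three
residue fates are distinguished:

* **ok** — a quantifiable decay; $k_{obs}$ with its standard error.
* **censored** — the fitted decay over the observation window is smaller
  than twice the intensity noise; only an upper bound
  $k_{obs} \le \ln(1/0.95)/t_{max}$ (i.e. less than 5% decay over the
  run) can be stated, so the protection factor is a lower bound. The 5%
  threshold is a declared package default.
* **no signal** — the amide exchanged before the first time point (the
  fate of unprotected residues at neutral pH, where intrinsic rates are
  1–100 s^-1^); no rate can be stated at all.

Intrinsic (random-coil) rates come from the Bai–Englander framework:
$k_{int} = k_A[\mathrm{D}^+] + k_B[\mathrm{OD}^-] + k_W$, each term
corrected for the side chains flanking the amide (bundled reference
table, poly-DL-alanine basis), for terminal groups, and for temperature
via Arrhenius factors (activation energies 14/17/19 kcal mol^-1^ for the
acid-, base- and water-catalyzed paths, 293 K reference). The D~2~O ion
product is held at its 20 °C value (pK~D~ = 15.05) — a small
approximation over the 20–40 °C range of these experiments. The optional
`d2o_read` flag applies the standard pD = pH~read~ + 0.4 electrode
correction (off by default). The protection factor is
$PF = k_{int}/k_{obs}$; an observed rate more than 10× the intrinsic
rate is unphysical under EX2 exchange and triggers a warning. State
comparisons report per-residue $\Delta\log_{10} PF$ with censored bounds
propagated (a censored numerator makes the difference a lower bound, a
censored denominator an upper bound).

EX1/EX2 discrimination and conversion to opening free energies are out
of scope.

# Chemical-shift perturbation screening

The combined amide CSP is
$\Delta\delta = \sqrt{\Delta\delta_H^2 + (\alpha\,\Delta\delta_N)^2}$
with $\alpha = 0.14$ (0.20 for glycine). The binding verdict uses an
iteratively trimmed cutoff: $\mu + k\sigma$ is computed over
non-exceeding residues, exceedances are set aside, and the cycle repeats
until stable; "binding" requires at least 3 residues above the final
cutoff.

The stringency default is $k = 4$, not the 3 familiar from Gaussian
statistics. The combined CSP is positive definite — under a pure-noise
null it follows a Rayleigh-like distribution whose upper tail is heavy
relative to its own SD — and $\mu + 3\sigma$ is exceeded by chance by
roughly 0.5% of residues, one to two per protein, which makes spurious
"binding" verdicts routine (observed in ~47% of null replicates at
$k=3$). At $k = 4$ the null false-call rate drops below ~1% while
genuine binding-site perturbations (tenths of a ppm against a millippm
cutoff) remain far above threshold. All three knobs ($\alpha$, $k$, the
3-residue rule) are arguments.

Titration K~d~ fitting and peak tracking through overlap are out of
scope; the screen assumes matched residue numbering between states.

# Residual dipolar couplings

RDCs are extracted as the difference of ^15^N–^1^H splittings measured
in aligned and isotropic conditions, with uncertainties combined in
quadrature; the sign convention depends on which doublet component is
upfield, so a `flip_sign` switch is provided. The Saupe alignment tensor
is the least-squares solution of
$D_i = D_{max}\sum_{kl} S_{kl}\,u_{ik}u_{il}$ over the five independent
elements of the traceless symmetric matrix, obtained by SVD of the
orientation design matrix. $D_{max} = -21.7$ kHz (the ^15^N–^1^H value
at $r = 1.02$ Å) is folded into the scaling and echoed in the output.
Quality is reported as
$Q = \sqrt{\sum(D_{obs}-D_{calc})^2 / \sum D_{obs}^2}$; an all-zero
coupling set yields a zero tensor with $Q$ reported as NaN and a note.
A design-matrix condition number above 10^6^ is refused as a degenerate
orientation set — the failure an ideal α-helix produces, since its N–H
vectors lie on a narrow cone. Derived quantities: axial component
$D_a = D_{max}S_{zz}/2$ and rhombicity
$R = \tfrac{2}{3}(S_{xx}-S_{yy})/S_{zz}$ after ordering
$|S_{zz}| \ge |S_{yy}| \ge |S_{xx}|$ (so $0 \le R \le 2/3$).

# Ensemble precision metrics

`pairwise_rmsd()` computes
$\mathrm{RMSD}_{ab} = \sqrt{\sum_i |x_i^a - x_i^b|^2 / n}$ over a
selection for every unordered model pair and reports mean ± SD over the
$N(N{-}1)/2$ pairs. Deposited NMR families are already superposed on
their ordered core, so the default is no re-superposition; a
`superpose = "selection"` mode (pairwise Kabsch fit on the selection
itself) and a `superpose = "reference"` mode (all models fitted to the
first over a reference selection) are provided so both conventions can
be compared — useful because published fragment-precision numbers
rarely state which convention they used. "Heavy atoms" means all
non-hydrogen atoms of the selection; for the cofactor SAH the
methionine moiety is defined as atoms N, CA, CB, CG, SD, C, O (+OXT if
present) and the adenosine moiety as the remaining heavy atoms. Altlocs
resolve to the first-listed conformer (deposited files list the highest
occupancy first).

# The synthetic-data generator

`make_scenario()` builds a 244-residue single-domain protein in two
states, mirroring a ~26 kDa methyltransferase:

| segment | residues | apo S² | complex S² | τ~e~ | R~ex~ probability |
|---|---|---|---|---|---|
| N-terminal tail | 1–51 | 0.20–0.50 | 0.80–0.95 | 0.5–1.5 ns | 0.10 / 0.05 |
| core | 52–203, 229–244 | 0.85–0.95 | 0.85–0.95 | 20–80 ps | 0.10 / 0.05 |
| mobile loop | 204–228 | 0.50–0.70 | 0.50–0.70 | 0.1–0.5 ns | 0.30 / 0.30 |

τ~c~ is 12.5 ns for the apo state and 10.4 ns for the complex (cofactor
binding orders the tail and compacts the molecule, so it tumbles
faster); R~ex~ magnitudes are uniform on [2.5, 8] s^-1^; measurement
noise defaults to 2% on R1/R2 and 0.02 absolute on the NOE — typical
modern-spectrometer precision. Protection factors are log-normal per
segment, rising by ~1.5 log units in tail and core upon cofactor binding
but not in the loop. CSP scenarios are "null" (referencing noise only,
0.005/0.05 ppm ^1^H/^15^N) or "site" (five contiguous residues perturbed
by ~0.15 ppm combined). RDCs are back-calculated from a fixed Saupe
tensor over jittered helix N–H vectors. All randomness flows through one
explicit seed; the same preset + seed is bit-reproducible, and every
simulator returns the ground truth alongside the data.

**What the generator does and does not emulate.** It reproduces the
*data shapes* and noise levels of a two-state dynamics study — segment
architecture, censoring, null/positive screens — so parameter-recovery
tests demonstrate that the estimators are correct and calibrated. It
does not simulate spectra, peak overlap, anisotropic tumbling,
field-dependent exchange, or correlated noise; passing tests therefore
validate the analysis chain, not the experimental steps upstream of it.

# Problem sizes and determinism

The packaged tests and the acceptance script use: a 20-point noiseless
parameter grid for the model-free round trip; 100-residue rigid sets and
20 seeded scenario pairs for the τ~c~ estimator; 100 null and 20
planted-site CSP replicates; the full 244-residue scenario for exchange
classification, HDX recovery and state comparison; and 50–80 vector RDC
sets. These sizes give stable statistics while keeping a full run in
tens of seconds. Every stochastic step takes an explicit seed, and
seeded runs are bit-reproducible.

# Known limitations

* Isotropic tumbling only; proteins with strongly anisotropic diffusion
  need a tensor model this package deliberately omits.
* Single-field model selection runs on three observables per residue;
  M4/M5 fits are saturated ($k = n$) and flagged as such — their χ² is
  zero by construction and only the information penalty separates them.
* Intrinsic-rate prediction holds pK~D~ at its 20 °C value and uses the
  dominant ionization state of D/E/H near neutral pH.
* The CSP screen calls binding from shift changes only; exchange
  broadening (intensity loss without shift change) is not detected.
* Deposited-ensemble checks require the coordinate file; only plain PDB
  (not mmCIF) input is parsed.
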