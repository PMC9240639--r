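# nmrdyn — protein backbone dynamics and structural NMR analysis in R

Solution-NMR studies of protein dynamics produce a standard family of
quantitative readouts: per-residue ^15N relaxation rates (R1, R2,
heteronuclear NOE) interpreted with the Lipari–Szabo model-free
formalism, an overall rotational correlation time from R2/R1 ratios,
amide hydrogen/deuterium exchange protection factors, residual dipolar
couplings with their alignment tensor, chemical-shift-perturbation
ligand screens, and coordinate-precision statistics over the deposited
NMR ensemble. `nmrdyn` implements this whole analysis chain as a
reusable R package for spectroscopists and structural biologists who
have the measured tables (peak intensities, rates, shifts, couplings)
and want reproducible, testable numbers out of them.

At its core is the model-free spectral density

    J(w) = (2/5) [ S2 tc / (1 + (w tc)^2) + (Sf2 - S2) t / (1 + (w t)^2) ],
    1/t = 1/tc + 1/te

mapped to observables through the standard dipolar + CSA expressions
(Rex enters R2 only), with per-residue fits over the model hierarchy
M1 {S2} … M4 {S2, te, Rex}, M5 {Sf2, S2, ts}, AIC-based model selection
and Monte-Carlo uncertainties. Around it sit: a τc estimator with
NOE-cutoff and ratio-trimming filters; Bai–Englander intrinsic exchange
rates and protection factors PF = k_int/k_obs with explicit censoring;
combined CSPs Δδ = sqrt(ΔδH² + (α ΔδN)²) with a calibrated binding
verdict; SVD fitting of the Saupe tensor with Q-factor; pairwise-RMSD
ensemble metrics; and a seeded synthetic-data generator emulating a
two-state (apo / cofactor-bound) ~26 kDa methyltransferase so that every
stage is validated by parameter recovery. The methods vignette
(`vignettes/nmr-dynamics-methods.Rmd`) documents every model, default
and numerical choice.

## Worked example

Simulate the apo state, estimate its tumbling time, and run the
model-free analysis:

```r
library(nmrdyn)
const <- spin_constants(700)          # 16.44 T, default amide constants

scn <- make_scenario("apo", seed = 1) # 244 residues, disordered 1-51 tail
rel <- simulate_relaxation(scn)       # R1/R2/NOE table with 2% noise

est <- estimate_tauc(rel, const)
print(est)
#> tau_c = 12.40 +/- 0.04 ns  (151 residues used, 93 excluded)

mf <- fit_modelfree(rel, est$tau_c, const)
mean(mf$S2[mf$res_num <= 51])   # disordered tail
#> [1] 0.3604081
mean(mf$S2[mf$res_num %in% 52:203])  # ordered core
#> [1] 0.8923639
sum(mf$exchange == "conformational exchange", na.rm = TRUE)
#> [1] 36
```

The estimator recovers the scenario's true 12.5 ns tumbling time from
noisy data while excluding flexible and exchange-broadened residues; the
fitted order parameters separate the disordered tail (S² ≈ 0.36) from
the rigid core (S² ≈ 0.89); and exactly the 36 residues carrying a true
Rex > 2 s⁻¹ are labelled as undergoing conformational exchange. The
complex preset (`make_scenario("complex", seed = 1)`) yields
τc = 10.16 ± 0.02 ns and an ordered tail (S² ≈ 0.89) — the signature of
cofactor-induced structuring.

The numbered scripts under `analysis/` run the full study in order —
simulation, relaxation/dynamics, H/D exchange, CSP screening, RDC tensor
fitting, ensemble RMSD — each printing what it found and writing its
tables under `results/`:

```sh
for f in analysis/0*.R; do Rscript "$f"; done
```

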