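# shared fixtures, all generated in code

SC700 <- spin_constants(700)

# noiseless one-residue relaxation record from the forward model, with
# nominal fractional uncertainties attached for chi2 weighting
mk_record <- function(S2, tau_c, tau_e = 0, rex = 0, sig_frac = 0.02,
                      sig_noe = 0.02, res_num = 1, const = SC700) {
  pr <- predict_rates(dynamics_params(S2 = S2, tau_c = tau_c,
                                      tau_e = tau_e, Rex = rex), const)
  data.frame(res_num = res_num,
             R1 = pr[["R1"]], R1_err = sig_frac * pr[["R1"]],
             R2 = pr[["R2"]], R2_err = sig_frac * pr[["R2"]],
             NOE = pr[["NOE"]], NOE_err = sig_noe)
}

# rigid (S2 = 1) synthetic protein table with fractional Gaussian noise
mk_rigid_table <- function(n, tau_c, noise_frac = 0.02, seed = 1,
                           const = SC700) {
  pr <- predict_rates(dynamics_params(S2 = 1, tau_c = tau_c), const)
  set.seed(seed)
  data.frame(
    res_num = seq_len(n),
    R1 = rnorm(n, pr[["R1"]], noise_frac * pr[["R1"]]),
    R1_err = noise_frac * pr[["R1"]],
    R2 = rnorm(n, pr[["R2"]], noise_frac * pr[["R2"]]),
    R2_err = noise_frac * pr[["R2"]],
    NOE = rnorm(n, pr[["NOE"]], 0.02),
    NOE_err = 0.02)
}

# minimal multi-model PDB writer (fixed-width ATOM/HETATM records)
write_toy_pdb <- function(path, models, atoms) {
  lines <- character(0)
  for (m in seq_along(models)) {
    lines <- c(lines, sprintf("MODEL     %4d", m))
    xyz <- models[[m]]
    for (i in seq_len(nrow(atoms))) {
      nm <- atoms$name[i]
      nmf <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else nm
      lines <- c(lines, sprintf(
        "%-6s%5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        atoms$rec[i], i, nmf, atoms$resname[i], atoms$chain[i],
        atoms$resno[i], xyz[i, 1], xyz[i, 2], xyz[i, 3], 1, 0,
        atoms$elem[i]))
    }
    lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}

# atom table for a 4-atom toy residue pair (protein + SAH heteroatom)
toy_atoms <- function() {
  data.frame(rec = c("ATOM", "ATOM", "ATOM", "HETATM"),
             name = c("N", "CA", "C", "SD"),
             resname = c("ALA", "ALA", "ALA", "SAH"),
             chain = "A", resno = c(1, 1, 1, 2),
             elem = c("N", "C", "C", "S"))
}

# random 3-D rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function(seed) {
  set.seed(seed)
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
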