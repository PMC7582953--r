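# Independent oracles coded separately from the package implementation:
# different constant sources, different arrangement of the arithmetic.
# These stay independent of the code paths they check.

# --- spectral density oracle (isotropic, two-Lorentzian sum) ------------
# tau values in seconds, omega rad/s.
oracle_jw_iso <- function(s2, tau_e_s, tau_r_s, omega) {
  lor <- function(tau) tau / (1 + omega^2 * tau^2)
  second <- if (tau_e_s > 0) {
    tau_p <- tau_e_s * tau_r_s / (tau_e_s + tau_r_s)
    (1 - s2) * lor(tau_p)
  } else 0
  (2 / 5) * (s2 * lor(tau_r_s) + second)
}

# extended two-timescale oracle (fast limit of the faster motion)
oracle_jw_ext <- function(s2f, s2s, tau_s_s, tau_r_s, omega) {
  lor <- function(tau) tau / (1 + omega^2 * tau^2)
  s2 <- s2f * s2s
  tau_p <- tau_s_s * tau_r_s / (tau_s_s + tau_r_s)
  (2 / 5) * (s2 * lor(tau_r_s) + (s2f - s2) * lor(tau_p))
}

# --- brute-force relaxation oracle --------------------------------------
# Constants written from scratch (CODATA / standard NMR values), not
# shared with the package internals.
ORACLE <- list(
  gh = 267522187.44,          # rad/s/T
  gn = -27126000,
  mu0_over_4pi = 1e-7,        # T^2 J^-1 m^3
  hbar = 1.054571817e-34
)

oracle_relaxation <- function(s2, tau_e_ps, tau_r_ns, field_mhz,
                              rex_at_field = 0,
                              r_nh_m = 1.02e-10, csa = -160e-6) {
  wh <- field_mhz * 1e6 * 2 * pi
  b0 <- wh / ORACLE$gh
  wn <- abs(ORACLE$gn) * b0
  jw <- function(w) oracle_jw_iso(s2, tau_e_ps * 1e-12, tau_r_ns * 1e-9, w)
  d <- ORACLE$mu0_over_4pi * ORACLE$hbar * ORACLE$gh * abs(ORACLE$gn) /
    r_nh_m^3
  d2 <- d^2
  c2 <- (wn * csa)^2 / 3
  r1 <- d2 / 4 * (jw(wh - wn) + 3 * jw(wn) + 6 * jw(wh + wn)) + c2 * jw(wn)
  r2 <- d2 / 8 * (4 * jw(0) + jw(wh - wn) + 3 * jw(wn) + 6 * jw(wh) +
                    6 * jw(wh + wn)) +
    c2 / 6 * (4 * jw(0) + 3 * jw(wn)) + rex_at_field
  # gamma ratio is negative for 15N: gh/gn = -gh/|gn|
  noe <- 1 + (d2 / 4) * (ORACLE$gh / ORACLE$gn) *
    (6 * jw(wh + wn) - jw(wh - wn)) / r1
  list(r1 = r1, r2 = r2, noe = noe)
}

# --- entropy oracle ------------------------------------------------------
# Bond-vector (cone) relation, S = +sqrt(S2), entropy in kB units.
oracle_residue_entropy <- function(s2) {
  log(pi * (3 - sqrt(1 + 8 * sqrt(s2))))
}

# --- methanol-d4 thermometer oracle --------------------------------------
oracle_methanol_t <- function(dd) 409.0 - 36.54 * dd - 21.85 * dd^2

# --- shared tiny helpers -------------------------------------------------
# single-residue noiseless dataset from given true params at the standard
# two-field design (full triple at 800, R2 only at 600); sigma floor keeps
# the dataset valid and makes noiseless model selection sharp.
single_residue_dataset <- function(params, tau_r_ns = 4.3,
                                   temperature_k = 310.15,
                                   fields = c(600, 800),
                                   sigma = 1e-6) {
  tensor <- diffusion_tensor("isotropic", tau_r_ns)
  rows <- lapply(fields, function(f) {
    tr <- predict_relaxation(params, tensor,
                             spectrometer_field(f, temperature_k))
    full <- f == max(fields)
    data.frame(residue_id = 10L, residue_name = "ALA", field_mhz = f,
               r1 = if (full) tr$r1 else NA, r1_err = if (full) sigma else NA,
               r2 = tr$r2, r2_err = sigma,
               noe = if (full) tr$noe else NA,
               noe_err = if (full) sigma else NA,
               flags = "")
  })
  relaxation_dataset(do.call(rbind, rows), protein = "oracle",
                     temperature_k = temperature_k)
}

# Backbone template with orientationally diverse NH vectors (random walk
# of residue frames); the extended chain is degenerate for axial-tensor
# work because every amide points the same way.
random_backbone_template <- function(n_residues, seed = 1) {
  set.seed(seed)
  atoms <- data.frame(
    atom_name = rep(c("N", "CA", "C"), n_residues),
    residue_id = rep(seq_len(n_residues), each = 3L),
    residue_name = "ALA", chain = "A", stringsAsFactors = FALSE)
  xyz <- matrix(NA_real_, 3 * n_residues, 3)
  origin <- c(0, 0, 0)
  runit <- function() {
    v <- rnorm(3)
    v / sqrt(sum(v^2))
  }
  for (i in seq_len(n_residues)) {
    origin <- origin + 3.8 * runit()
    base <- (i - 1) * 3
    xyz[base + 1, ] <- origin                      # N
    xyz[base + 2, ] <- origin + 1.46 * runit()     # CA
    xyz[base + 3, ] <- origin + 2.40 * runit()     # C
  }
  list(atoms = atoms, xyz = xyz)
}

small_scheme <- function(n = 30L) {
  clip <- function(r) r[r <= n]
  region_scheme(clip(6:10), clip(12:18), clip(20:25),
                residue_ids = seq_len(n))
}
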