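## Physical constants. Units throughout the package: coordinates in Angstrom,
## energies in kcal/mol, masses in amu, temperatures in K, charges in units of
## the elementary charge.

## Coulomb constant k such that E = k q_i q_j / r is in kcal/mol for charges
## in e and r in Angstrom (the value used by the AMBER family of codes).
.COULOMB_K <- 332.0637

## Gas constant in kcal/(mol K).
.R_GAS <- 0.0019872

## Second radiation constant h*c/k_B in cm*K: converts a wavenumber (cm^-1)
## to a characteristic temperature, so h*nu/(k_B*T) = .C2 * nu_tilde / T.
.C2 <- 1.43877687750393

## Conversion from sqrt(eigenvalue of the mass-weighted Hessian) in
## sqrt(kcal/mol / (amu A^2)) to a wavenumber in cm^-1:
## nu_tilde = sqrt(lambda * 4184 J/kcal / (N_A * 1e-20 m^2 * m_u)) / (2 pi c).
.FREQ_CM1 <- local({
  NA_   <- 6.02214076e23
  amu   <- 1.66053906660e-27     # kg
  c_cm  <- 2.99792458e10         # cm/s
  sqrt(4184 / (NA_ * 1e-20 * amu)) / (2 * pi * c_cm)
})

## Run a block with a locally-set RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Derive a reproducible sub-seed (< 2^31) for a named generator from a run
## seed, so adding one generator never perturbs the streams of the others.
subSeed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  (as.integer(seed) %% 1000003L) * 1009L + (h %% 65521L)
}
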