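#' @include gradients.R
NULL

#' Energy minimization
#'
#' Local minimization of the implicit-solvent potential with analytic
#' gradients (L-BFGS with restarts until the RMS gradient criterion or the
#' step budget is met). The default term set omits the nonpolar surface
#' term: the point-count surface estimator is piecewise constant, so that
#' term carries zero force and zero curvature almost everywhere and cannot
#' move a stationary point or a normal mode; it only offsets the energy.
#'
#' @inheritParams totalEnergy
#' @param gradientTol target RMS gradient, kcal/(mol A).
#' @param maxSteps iteration budget.
#' @return list: `frame` (minimized coordinates), `energy` (kcal/mol),
#'   `gradientRms` (kcal/(mol A)), `converged` (logical), `steps` used.
#' @export
minimizeEnergy <- function(system, frame, params = energyModelParams(),
                           gradientTol = 1e-6, maxSteps = 2000L,
                           terms = c("bond", "ele", "vdw", "gb")) {
  x0 <- as.numeric(t(frame))
  asFrame <- function(x) matrix(x, ncol = 3L, byrow = TRUE)
  fn <- function(x) totalEnergy(system, asFrame(x), params, terms)
  gr <- function(x) as.numeric(t(totalGradient(system, asFrame(x), params,
                                               terms)))
  if (!is.finite(fn(x0))) stop("non-finite energy at start", call. = FALSE)
  steps <- 0L
  x <- x0
  repeat {
    budget <- maxSteps - steps
    if (budget <= 0L) break
    opt <- stats::optim(x, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = min(budget, 500L),
                                       factr = 10))
    steps <- steps + opt$counts[["function"]]
    moved <- max(abs(opt$par - x))
    x <- opt$par
    g <- gr(x)
    if (sqrt(mean(g^2)) <= gradientTol || moved < 1e-12) break
  }
  g <- gr(x)
  rms <- sqrt(mean(g^2))
  list(frame = asFrame(x), energy = fn(x), gradientRms = rms,
       converged = rms <= gradientTol, steps = steps)
}

#' Hessian of the potential energy
#'
#' Central finite differences of the analytic gradient (better conditioned
#' than double-differenced energies), symmetrized as `(H + t(H))/2`.
#'
#' @inheritParams totalEnergy
#' @param step finite-difference displacement, A.
#' @return 3n x 3n matrix, kcal/(mol A^2); coordinate order
#'   (x1, y1, z1, x2, ...)
#' @export
hessianMatrix <- function(system, frame, params = energyModelParams(),
                          step = 1e-4,
                          terms = c("bond", "ele", "vdw", "gb")) {
  x0 <- as.numeric(t(frame))
  m <- length(x0)
  asFrame <- function(x) matrix(x, ncol = 3L, byrow = TRUE)
  H <- matrix(0, m, m)
  for (k in seq_len(m)) {
    xp <- x0; xp[k] <- xp[k] + step
    xm <- x0; xm[k] <- xm[k] - step
    gp <- as.numeric(t(totalGradient(system, asFrame(xp), params, terms)))
    gm <- as.numeric(t(totalGradient(system, asFrame(xm), params, terms)))
    H[, k] <- (gp - gm) / (2 * step)
  }
  if (any(!is.finite(H))) stop("non-finite Hessian entries", call. = FALSE)
  (H + t(H)) / 2
}

#' Harmonic normal modes from a Hessian
#'
#' Eigenvalues of the mass-weighted Hessian `M^-1/2 H M^-1/2`. Modes with
#' `|nu| < zeroThreshold` are counted as rigid-body (translation/rotation:
#' 6 for a nonlinear molecule, 5 for a linear one) and removed; negative
#' eigenvalues beyond the threshold are reported as imaginary modes.
#'
#' @param hessian 3n x 3n matrix from [hessianMatrix()].
#' @param masses per-atom masses, amu (length n).
#' @param zeroThreshold rigid-body cut in cm^-1.
#' @return a [NormalModeResult]
#' @export
normalModes <- function(hessian, masses, zeroThreshold = 1) {
  stopifnot(all(masses > 0))
  w <- 1 / sqrt(rep(masses, each = 3L))
  Hm <- hessian * outer(w, w)
  ev <- eigen((Hm + t(Hm)) / 2, symmetric = TRUE, only.values = TRUE)$values
  nu <- sign(ev) * sqrt(abs(ev)) * .FREQ_CM1
  zero <- abs(nu) < zeroThreshold
  imag <- nu <= -zeroThreshold
  freq <- sort(nu[!zero & !imag])
  if (sum(zero) > 6L)
    warning(sprintf("%d near-zero modes (expected <= 6)", sum(zero)),
            call. = FALSE)
  new("NormalModeResult", frequencies = freq, nZeroModes = sum(zero),
      nImaginary = sum(imag))
}

#' Harmonic-oscillator vibrational entropy
#'
#' `S = R sum_i [ x_i/(exp(x_i)-1) - ln(1 - exp(-x_i)) ]` with
#' `x_i = h nu_i / (k_B T)`.
#'
#' @param frequencies wavenumbers, cm^-1, all `> 0`.
#' @param T temperature, K.
#' @return entropy in kcal/(mol K)
#' @export
vibrationalEntropy <- function(frequencies, T = 300) {
  if (any(frequencies <= 0))
    stop("vibrational entropy requires strictly positive frequencies",
         call. = FALSE)
  x <- .C2 * frequencies / T
  term <- ifelse(x > 500, 0, x / expm1(x)) - log1p(-exp(-pmin(x, 500)))
  .R_GAS * sum(term)
}

#' Entropy change of binding from normal modes
#'
#' For each analysed snapshot the complex, the receptor alone and the ligand
#' alone are minimized and subjected to normal-mode analysis;
#' `T dS = T (S_complex - S_receptor - S_ligand)` is averaged over snapshots
#' with standard error `sd/sqrt(n)`. Snapshots yielding imaginary modes in
#' any species are dropped with a warning.
#'
#' @inheritParams snapshotBindingComponents
#' @param frames a [Trajectory] or list of coordinate matrices.
#' @param T temperature, K.
#' @param thin analyse every `thin`-th frame (minimization dominates cost).
#' @param gradientTol,maxSteps passed to [minimizeEnergy()].
#' @param terms energy terms for minimization and the Hessian.
#' @return list: `TdS` (kcal/mol), `se`, `n`, `log` (per-snapshot
#'   data.frame: snapshot, S_complex, S_receptor, S_ligand, TdS,
#'   n_imaginary)
#' @export
entropyTerm <- function(system, frames, receptorGroup, ligandGroup, T = 300,
                        params = energyModelParams(), thin = 10L,
                        gradientTol = 1e-6, maxSteps = 2000L,
                        terms = c("bond", "ele", "vdw", "gb")) {
  if (is(frames, "Trajectory")) frames <- frames@frames
  if (is.matrix(frames)) frames <- list(frames)
  ir <- .groupIdx(system, receptorGroup)
  il <- .groupIdx(system, ligandGroup)
  if (!length(il)) stop("ligand group is empty", call. = FALSE)
  sysR <- subsetSystem(system, ir)
  sysL <- subsetSystem(system, il)
  pick <- seq(1L, length(frames), by = max(1L, as.integer(thin)))
  speciesS <- function(sys, fr) {
    mn <- minimizeEnergy(sys, fr, params, gradientTol, maxSteps, terms)
    nm <- normalModes(hessianMatrix(sys, mn$frame, params, terms = terms),
                      sys@atoms$mass)
    list(S = if (nm@nImaginary > 0L || !length(nm@frequencies)) NA_real_
         else vibrationalEntropy(nm@frequencies, T),
         nImag = nm@nImaginary)
  }
  rows <- lapply(pick, function(i) {
    fr <- frames[[i]]
    sc <- speciesS(system, fr)
    sr <- speciesS(sysR, fr[ir, , drop = FALSE])
    sl <- speciesS(sysL, fr[il, , drop = FALSE])
    data.frame(snapshot = i, S_complex = sc$S, S_receptor = sr$S,
               S_ligand = sl$S,
               TdS = T * (sc$S - sr$S - sl$S),
               n_imaginary = sc$nImag + sr$nImag + sl$nImag)
  })
  log <- do.call(rbind, rows)
  ok <- is.finite(log$TdS)
  if (any(!ok))
    warning(sprintf("%d snapshot(s) dropped (imaginary modes)", sum(!ok)),
            call. = FALSE)
  if (!any(ok)) stop("all snapshots dropped in entropy calculation",
                     call. = FALSE)
  vals <- log$TdS[ok]
  list(TdS = mean(vals),
       se = if (length(vals) > 1L) stats::sd(vals) / sqrt(length(vals))
            else NA_real_,
       n = length(vals), log = log)
}
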