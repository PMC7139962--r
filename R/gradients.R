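#' @include energy.R
NULL

## Analytic gradients of the implicit-solvent potential
##
## The total energy used for minimization and normal-mode analysis is
##   E = E_bond + E_ele(intra) + E_vdw(intra) + G_pol(GB) + G_nonpol(SASA).
## All terms except G_nonpol have analytic gradients below (the GB term
## includes the chain rule through the OBC effective radii). The
## Shrake-Rupley surface estimator is piecewise constant in the coordinates,
## so its exact gradient is zero almost everywhere and the nonpolar term
## contributes energy but no force.

## d(HCT integral)/dr, same branch structure as .hctIntegral().
.hctIntegralDeriv <- function(r, or1, sr2) {
  U <- r + sr2
  Labs <- abs(r - sr2)
  useOr <- or1 >= Labs
  L <- ifelse(useOr, or1, Labs)
  Lp <- ifelse(useOr, 0, sign(r - sr2))
  dbase <- -Lp / L^2 + 1 / U^2 +
    0.25 * ((1 + sr2^2 / r^2) * (1 / U^2 - 1 / L^2) +
            (r - sr2^2 / r) * (-2 / U^3 + 2 * Lp / L^3)) +
    0.5 * ((Lp / L - 1 / U) / r - log(L / U) / r^2)
  dcorr <- ifelse(sr2 - r > or1, 2 * Lp / L^2, 0)
  ifelse(or1 >= U, 0, 0.5 * (dbase + dcorr))
}

## Accumulate sum_j C_ij (x_i - x_j) rows into a gradient matrix.
## C must be symmetric with zero diagonal; C_ij = dE/dd_ij / d_ij.
.pairGradient <- function(C, X) {
  rowSums(C) * X - C %*% X
}

#' Total potential energy of a system in one frame
#'
#' @inheritParams bondEnergy
#' @param terms character subset of `c("bond", "ele", "vdw", "gb",
#'   "nonpol")`.
#' @return energy in kcal/mol
#' @export
totalEnergy <- function(system, frame, params = energyModelParams(),
                        terms = c("bond", "ele", "vdw", "gb", "nonpol")) {
  e <- 0
  if ("bond" %in% terms) e <- e + bondEnergy(system, frame)
  if ("ele" %in% terms)
    e <- e + coulombEnergy(system, frame, params = params, intra = TRUE)
  if ("vdw" %in% terms)
    e <- e + ljEnergy(system, frame, params = params, intra = TRUE)
  if ("gb" %in% terms) e <- e + gbPolarEnergy(system, frame, NULL, params)
  if ("nonpol" %in% terms)
    e <- e + nonpolarEnergy(sasa(system, frame, NULL, params)$total, params)
  if (!is.finite(e)) stop("non-finite energy", call. = FALSE)
  e
}

#' Analytic gradient of the total potential energy
#'
#' @inheritParams totalEnergy
#' @return n x 3 matrix, kcal/(mol A)
#' @export
totalGradient <- function(system, frame, params = energyModelParams(),
                          terms = c("bond", "ele", "vdw", "gb", "nonpol")) {
  a <- system@atoms
  n <- nrow(a)
  G <- matrix(0, n, 3L)
  idx <- seq_len(n)
  X <- frame
  D <- .crossDist(X, X); diag(D) <- 1

  if ("bond" %in% terms && nrow(system@bonds)) {
    b <- system@bonds
    dv <- X[b$i, , drop = FALSE] - X[b$j, , drop = FALSE]
    d <- sqrt(rowSums(dv^2))
    f <- b$k * (d - b$r0) / d        # dE/dd / d
    for (r in seq_len(nrow(b))) {
      G[b$i[r], ] <- G[b$i[r], ] + f[r] * dv[r, ]
      G[b$j[r], ] <- G[b$j[r], ] - f[r] * dv[r, ]
    }
  }

  needW <- any(c("ele", "vdw") %in% terms)
  if (needW && n > 1L) {
    Wele <- .intraWeights(system, idx, "ele_scale")
    Wvdw <- .intraWeights(system, idx, "vdw_scale")
    Wele <- Wele + t(Wele); Wvdw <- Wvdw + t(Wvdw)
    if ("ele" %in% terms) {
      Q <- outer(a$charge, a$charge)
      C <- -params@coulombK * Wele * Q / D^3
      diag(C) <- 0
      G <- G + .pairGradient(C, X)
    }
    if ("vdw" %in% terms) {
      Rmin <- outer(a$lj_rmin_half, a$lj_rmin_half, "+")
      EPS <- sqrt(outer(a$lj_epsilon, a$lj_epsilon))
      s6 <- (Rmin / D)^6
      C <- 12 * Wvdw * EPS * (s6 - s6 * s6) / D^2
      diag(C) <- 0
      G <- G + .pairGradient(C, X)
    }
  }

  if ("gb" %in% terms && !anyNA(a$charge)) {
    G <- G + .gbGradient(system, X, D, params)
  }
  ## "nonpol": zero gradient (piecewise-constant estimator)
  G
}

## GB-OBC gradient: direct f_GB distance dependence plus the chain rule
## through the effective Born radii.
.gbGradient <- function(system, X, D, params) {
  a <- system@atoms
  n <- nrow(a)
  q <- a$charge
  rho <- a$gb_radius; scr <- a$gb_screen
  off <- params@gbOffset
  or <- rho - off
  OR1 <- matrix(or, n, n)
  SR2 <- matrix(scr * or, n, n, byrow = TRUE)
  I <- .hctIntegral(D, OR1, SR2); diag(I) <- 0
  Ii <- rowSums(I)
  psi <- Ii * or
  h <- params@obcAlpha * psi - params@obcBeta * psi^2 +
    params@obcGamma * psi^3
  R <- 1 / (1 / or - tanh(h) / rho)
  ## dR_k/dpsi_k
  dRdpsi <- R^2 * (1 / cosh(h))^2 *
    (params@obcAlpha - 2 * params@obcBeta * psi +
     3 * params@obcGamma * psi^2) / rho

  RR <- outer(R, R)
  expo <- exp(-D^2 / (4 * RR))
  f <- sqrt(D^2 + RR * expo)
  pref <- params@coulombK *
    (1 / params@dielectricIn - 1 / params@dielectricOut)
  Q <- outer(q, q)

  ## direct channel: per unordered pair, dE/dd = pref q_i q_j f^-2 df/dd
  dfdd <- D * (1 - 0.25 * expo) / f
  Cdir <- pref * Q / f^2 * dfdd / D
  diag(Cdir) <- 0

  ## dE/dR_k: off-diagonal pairs (counted twice in the double sum) + self
  dfdR <- expo * (matrix(R, n, n, byrow = TRUE) + D^2 / (4 * matrix(R, n, n))) /
    (2 * f)                             # df_ij/dR_i (row index)
  M <- Q / f^2 * dfdR
  diag(M) <- 0
  dEdR <- pref * rowSums(M) + (pref / 2) * q^2 / R^2

  ## radii channel: dE/dd_kj += dE/dR_k dR_k/dpsi or_k dI_kj/dd
  dIdd <- .hctIntegralDeriv(D, OR1, SR2); diag(dIdd) <- 0
  A <- (dEdR * dRdpsi * or) * dIdd      # row k: contribution via R_k
  Crad <- (A + t(A)) / D
  diag(Crad) <- 0

  .pairGradient(Cdir + Crad, X)
}
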