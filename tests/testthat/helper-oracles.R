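## Shared fixtures and independent brute-force oracles. The oracles are
## deliberately written as plain double loops over atom pairs, separate from
## the package's vectorized implementations.

K_COUL <- 332.0637

beadAtoms <- function(n, charge = rep(0, n), mass = rep(12, n),
                      rminHalf = rep(1.6, n), eps = rep(0.1, n),
                      gbRadius = rep(1.59, n), gbScreen = rep(0.8, n),
                      resIndex = rep(0L, n), resName = NULL,
                      authorResid = NULL, name = NULL) {
  if (is.null(resName)) resName <- rep("BEA", n)
  if (is.null(authorResid)) authorResid <- resIndex + 1L
  if (is.null(name)) name <- paste0("B", seq_len(n))
  data.frame(name = name, element = "C", mass = mass, charge = charge,
             lj_rmin_half = rminHalf, lj_epsilon = eps,
             gb_radius = gbRadius, gb_screen = gbScreen,
             residue_index = resIndex, residue_name = resName,
             author_resid = authorResid)
}

beadSystem <- function(n, ..., bonds = NULL) {
  molecularSystem(beadAtoms(n, ...), bonds = bonds)
}

randomSystem <- function(n, seed) {
  set.seed(seed)
  X <- matrix(runif(3 * n, 0, 4 + n^(1/3) * 3), n, 3)
  ## push apart any clashing pair deterministically
  repeat {
    D <- as.matrix(dist(X))
    diag(D) <- Inf
    if (min(D) > 2.0) break
    ij <- which(D == min(D), arr.ind = TRUE)[1L, ]
    X[ij[1L], ] <- X[ij[1L], ] + runif(3, 1, 2)
  }
  sys <- beadSystem(n,
                    charge = runif(n, -0.9, 0.9),
                    rminHalf = runif(n, 1.3, 2.0),
                    eps = runif(n, 0.02, 0.25),
                    gbRadius = runif(n, 1.2, 1.9),
                    gbScreen = runif(n, 0.7, 0.9))
  list(system = sys, frame = X)
}

randomRotation <- function(seed) {
  set.seed(seed)
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

rigidMove <- function(X, seed) {
  R <- randomRotation(seed)
  set.seed(seed + 1L)
  sweep(X %*% R, 2L, runif(3, -10, 10), "+")
}

## ---- brute-force oracles ----------------------------------------------

oracleCoulombInter <- function(sys, X, ia, ib) {
  a <- atomData(sys)
  e <- 0
  for (i in ia) for (j in ib)
    e <- e + K_COUL * a$charge[i] * a$charge[j] /
      sqrt(sum((X[i, ] - X[j, ])^2))
  e
}

oracleLJInter <- function(sys, X, ia, ib) {
  a <- atomData(sys)
  e <- 0
  for (i in ia) for (j in ib) {
    r <- sqrt(sum((X[i, ] - X[j, ])^2))
    rm <- a$lj_rmin_half[i] + a$lj_rmin_half[j]
    ep <- sqrt(a$lj_epsilon[i] * a$lj_epsilon[j])
    e <- e + ep * ((rm / r)^12 - 2 * (rm / r)^6)
  }
  e
}

## pair weight under the exclusion/1-4 rules of a system
.pairWeight <- function(sys, i, j, col) {
  ex <- sys@exclusions
  if (nrow(ex))
    for (r in seq_len(nrow(ex)))
      if ((ex[r, 1] == i && ex[r, 2] == j) ||
          (ex[r, 1] == j && ex[r, 2] == i)) return(0)
  p <- sys@pairs14
  if (nrow(p))
    for (r in seq_len(nrow(p)))
      if ((p$i[r] == i && p$j[r] == j) || (p$i[r] == j && p$j[r] == i))
        return(p[[col]][r])
  1
}

oracleCoulombIntra <- function(sys, X) {
  a <- atomData(sys)
  n <- nrow(a)
  e <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    w <- .pairWeight(sys, i, j, "ele_scale")
    if (w == 0) next
    e <- e + w * K_COUL * a$charge[i] * a$charge[j] /
      sqrt(sum((X[i, ] - X[j, ])^2))
  }
  e
}

oracleLJIntra <- function(sys, X) {
  a <- atomData(sys)
  n <- nrow(a)
  e <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    w <- .pairWeight(sys, i, j, "vdw_scale")
    if (w == 0) next
    r <- sqrt(sum((X[i, ] - X[j, ])^2))
    rm <- a$lj_rmin_half[i] + a$lj_rmin_half[j]
    ep <- sqrt(a$lj_epsilon[i] * a$lj_epsilon[j])
    e <- e + w * ep * ((rm / r)^12 - 2 * (rm / r)^6)
  }
  e
}

## GB double-sum oracle: takes effective radii as given and evaluates the
## pairwise generalized-Born sum term by term.
oracleGBSum <- function(sys, X, R, epsIn = 1, epsOut = 80) {
  q <- atomData(sys)$charge
  n <- length(q)
  pref <- K_COUL * (1 / epsIn - 1 / epsOut)
  e <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    r2 <- sum((X[i, ] - X[j, ])^2)
    f <- sqrt(r2 + R[i] * R[j] * exp(-r2 / (4 * R[i] * R[j])))
    e <- e - (pref / 2) * q[i] * q[j] / f
  }
  e
}

## two-pass textbook Pearson correlation
oraclePearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

## analytic accessible area of sphere 1 occluded by sphere 2
twoSphereSasa1 <- function(r1, r2, d, probe) {
  R1 <- r1 + probe; R2 <- r2 + probe
  if (d >= R1 + R2) return(4 * pi * R1^2)
  if (d <= abs(R1 - R2)) return(if (R1 < R2) 0 else 4 * pi * R1^2)
  h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  4 * pi * R1^2 - 2 * pi * R1 * h1
}
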