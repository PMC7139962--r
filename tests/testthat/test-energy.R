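test_that("Coulomb energy matches closed forms and the brute-force oracle", {
  sys <- beadSystem(2, charge = c(1, -1))
  X <- rbind(c(0, 0, 0), c(3, 0, 0))
  expect_equal(coulombEnergy(sys, X, 1L, 2L), -332.0637 / 3,
               tolerance = 1e-12)
  zero <- beadSystem(3)
  Xz <- matrix(rnorm(9), 3)
  expect_equal(coulombEnergy(zero, Xz, params = energyModelParams(),
                             intra = TRUE), 0)
  for (seed in 1:5) {
    rs <- randomSystem(10, seed)
    ia <- 1:6; ib <- 7:10
    expect_equal(coulombEnergy(rs$system, rs$frame, ia, ib),
                 oracleCoulombInter(rs$system, rs$frame, ia, ib),
                 tolerance = 1e-10)
    expect_equal(coulombEnergy(rs$system, rs$frame, intra = TRUE),
                 oracleCoulombIntra(rs$system, rs$frame),
                 tolerance = 1e-10)
  }
  expect_error(coulombEnergy(sys, X, 1:2, 2L), "disjoint")
  expect_error(coulombEnergy(sys, rbind(c(0, 0, 0), c(1e-9, 0, 0)),
                             1L, 2L), "singularity")
})

test_that("LJ energy has its minimum at Rmin and matches the oracle", {
  sys <- beadSystem(2, rminHalf = c(1.5, 1.7), eps = c(0.1, 0.2))
  Rmin <- 1.5 + 1.7
  X <- rbind(c(0, 0, 0), c(Rmin, 0, 0))
  expect_equal(ljEnergy(sys, X, 1L, 2L), -sqrt(0.1 * 0.2),
               tolerance = 1e-12)
  far <- rbind(c(0, 0, 0), c(1e6, 0, 0))
  expect_lt(abs(ljEnergy(sys, far, 1L, 2L)), 1e-12)
  for (seed in 6:10) {
    rs <- randomSystem(10, seed)
    expect_equal(ljEnergy(rs$system, rs$frame, 1:5, 6:10),
                 oracleLJInter(rs$system, rs$frame, 1:5, 6:10),
                 tolerance = 1e-10)
    expect_equal(ljEnergy(rs$system, rs$frame, intra = TRUE),
                 oracleLJIntra(rs$system, rs$frame),
                 tolerance = 1e-10)
  }
})

test_that("exclusions and 1-4 scaling are honoured in intra sums", {
  bonds <- data.frame(i = 1:3, j = 2:4, k = 300, r0 = 1.5)
  sys <- beadSystem(4, charge = c(0.4, -0.3, 0.2, -0.3), bonds = bonds)
  set.seed(42)
  X <- matrix(cumsum(c(0, 1.5, 1.5, 1.5)), 4, 1) %*% t(c(1, 0, 0)) +
    matrix(rnorm(12, 0, 0.2), 4, 3)
  expect_equal(coulombEnergy(sys, X, intra = TRUE),
               oracleCoulombIntra(sys, X), tolerance = 1e-10)
  expect_equal(ljEnergy(sys, X, intra = TRUE), oracleLJIntra(sys, X),
               tolerance = 1e-10)
  ## the only counted pair is the scaled 1-4 pair
  d14 <- sqrt(sum((X[1, ] - X[4, ])^2))
  expect_equal(coulombEnergy(sys, X, intra = TRUE),
               (1 / 1.2) * K_COUL * 0.4 * (-0.3) / d14, tolerance = 1e-10)
})

test_that("generalized Born reproduces the Born ion and the double-sum", {
  p <- energyModelParams()
  ion <- beadSystem(1, charge = 1, gbRadius = 2 + p@gbOffset)
  X1 <- matrix(0, 1, 3)
  expect_equal(effectiveBornRadii(ion, X1, params = p), 2)
  born <- -(p@coulombK / 2) * (1 - 1 / 80) / 2
  expect_equal(gbPolarEnergy(ion, X1, params = p), born, tolerance = 1e-9)

  ## far-separated atoms keep their isolated radii
  two <- beadSystem(2, charge = c(1, -1), gbRadius = c(1.5, 1.8))
  far <- rbind(c(0, 0, 0), c(1e6, 0, 0))
  expect_equal(effectiveBornRadii(two, far, params = p),
               c(1.5, 1.8) - p@gbOffset, tolerance = 1e-9)

  ## burial inside a neighbor shell strictly increases the effective radius
  shell <- 2.2 * rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                       c(0, 0, 1), c(0, 0, -1))
  sys7 <- beadSystem(7, charge = c(1, rep(0, 6)))
  X7 <- rbind(c(0, 0, 0), shell)
  rEff <- effectiveBornRadii(sys7, X7, params = p)
  expect_gt(rEff[1], 1.59 - p@gbOffset)

  ## 3-atom system equals the pairwise double-sum oracle
  rs <- randomSystem(3, seed = 99)
  R <- effectiveBornRadii(rs$system, rs$frame, params = p)
  expect_equal(gbPolarEnergy(rs$system, rs$frame, params = p),
               oracleGBSum(rs$system, rs$frame, R), tolerance = 1e-10)

  ## all charges zero -> 0
  neutral <- beadSystem(3)
  expect_equal(gbPolarEnergy(neutral, matrix(rnorm(9), 3) * 3, params = p),
               0)
})

test_that("Shrake-Rupley surface matches sphere closed forms", {
  p <- energyModelParams()
  one <- beadSystem(1, rminHalf = 1.6)
  s <- sasa(one, matrix(0, 1, 3), params = p)
  expect_equal(s$total, 4 * pi * 3^2, tolerance = 1e-9)

  ## fully buried central atom
  big <- beadSystem(7, rminHalf = c(1.5, rep(4, 6)))
  Xb <- rbind(c(0, 0, 0),
              rbind(c(3, 0, 0), c(-3, 0, 0), c(0, 3, 0), c(0, -3, 0),
                    c(0, 0, 3), c(0, 0, -3)))
  expect_equal(sasa(big, Xb, params = p)$perAtom[1], 0)

  ## two-sphere case vs the spherical-cap formula, within 2% at 960 points
  two <- beadSystem(2, rminHalf = c(1.6, 1.9))
  d <- 3.1
  X2 <- rbind(c(0, 0, 0), c(d, 0, 0))
  got <- sasa(two, X2, params = p)$perAtom
  expect_equal(got[1], twoSphereSasa1(1.6, 1.9, d, 1.4), tolerance = 0.02)
  expect_equal(got[2], twoSphereSasa1(1.9, 1.6, d, 1.4), tolerance = 0.02)

  expect_error(sasa(beadSystem(1, rminHalf = 0), matrix(0, 1, 3),
                    params = p), "zero-radius")
})

test_that("nonpolar term is gamma * SASA + beta", {
  p <- energyModelParams()
  expect_equal(nonpolarEnergy(0, p), 0.92)
  expect_equal(nonpolarEnergy(1000, p), 6.34, tolerance = 1e-9)
  expect_equal(nonpolarEnergy(12345, energyModelParams(gamma = 0)), 0.92)
})

test_that("all energy terms are invariant under a global rigid motion", {
  p <- energyModelParams()
  rs <- randomSystem(12, seed = 21)
  sys <- rs$system; X <- rs$frame
  Y <- rigidMove(X, 31)
  expect_equal(coulombEnergy(sys, Y, 1:7, 8:12),
               coulombEnergy(sys, X, 1:7, 8:12), tolerance = 1e-9)
  expect_equal(ljEnergy(sys, Y, intra = TRUE),
               ljEnergy(sys, X, intra = TRUE), tolerance = 1e-9)
  expect_equal(gbPolarEnergy(sys, Y, params = p),
               gbPolarEnergy(sys, X, params = p), tolerance = 1e-9)
  ## the surface estimator is exact only to quadrature resolution
  expect_equal(sasa(sys, Y, params = p)$total,
               sasa(sys, X, params = p)$total, tolerance = 2e-3)
})

test_that("analytic gradients agree with central differences", {
  p <- energyModelParams()
  toy <- makeToySystem(nAtoms = 7, nLigandAtoms = 2, seed = 13,
                       bonded = TRUE)
  sys <- toy$system; X <- toy$frame
  terms <- c("bond", "ele", "vdw", "gb")
  g <- totalGradient(sys, X, p, terms)
  h <- 1e-5
  num <- matrix(0, nrow(X), 3)
  for (i in seq_len(nrow(X))) for (k in 1:3) {
    fp <- X; fp[i, k] <- fp[i, k] + h
    fm <- X; fm[i, k] <- fm[i, k] - h
    num[i, k] <- (totalEnergy(sys, fp, p, terms) -
                  totalEnergy(sys, fm, p, terms)) / (2 * h)
  }
  expect_equal(g, num, tolerance = 1e-6)
})
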