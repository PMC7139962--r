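test_that("Kabsch superposition removes rigid motions exactly", {
  set.seed(1)
  X <- matrix(rnorm(30), 10, 3)
  id <- kabschSuperpose(X, X)
  expect_equal(id$rmsd, 0, tolerance = 1e-12)
  expect_equal(id$rotation, diag(3), tolerance = 1e-9)

  th <- pi / 2
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
              byrow = TRUE)
  Y <- X %*% R + matrix(c(3, -1, 2), 10, 3, byrow = TRUE)
  fit <- kabschSuperpose(X, Y)
  expect_lt(fit$rmsd, 1e-9)
  expect_false(fit$degenerate)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)

  ## 2-point degenerate case: translation-only fit
  ref <- rbind(c(-1, 0, 0), c(1, 0, 0))
  mob <- rbind(c(-2, 0, 0), c(2, 0, 0))
  d <- kabschSuperpose(ref, mob)
  expect_true(d$degenerate)
  expect_equal(d$rmsd, 1.0, tolerance = 1e-12)
  expect_error(kabschSuperpose(matrix(0, 0, 3), matrix(0, 0, 3)),
               "at least one")
})

test_that("Kabsch RMSD agrees with the bio3d reference implementation", {
  set.seed(7)
  for (i in 1:5) {
    X <- matrix(rnorm(24, sd = 3), 8, 3)
    Y <- X + matrix(rnorm(24, sd = 0.5), 8, 3)
    ours <- kabschSuperpose(X, Y)$rmsd
    fitted <- bio3d::fit.xyz(fixed = as.numeric(t(X)),
                             mobile = as.numeric(t(Y)),
                             fixed.inds = 1:24, mobile.inds = 1:24)
    ref <- sqrt(mean(colSums(matrix((fitted - as.numeric(t(X)))^2,
                                    nrow = 3))))
    expect_equal(ours, ref, tolerance = 1e-6)
  }
})

test_that("RMSD series is zero for static or rigidly moved trajectories", {
  set.seed(3)
  base <- matrix(rnorm(18, sd = 2), 6, 3)
  static <- new("Trajectory", frames = list(base, base, base),
                frameInterval = 10, replicaId = 1L)
  rs <- rmsdSeries(static, 1:6)
  expect_equal(rs$rmsd, rep(0, 3), tolerance = 1e-9)
  moved <- new("Trajectory",
               frames = list(base, base + matrix(5, 6, 3)),
               frameInterval = 10, replicaId = 1L)
  expect_lt(rmsdSeries(moved, 1:6)$rmsd[2], 1e-9)
})

test_that("a two-conformation trajectory yields a bimodal RMSD histogram", {
  set.seed(9)
  a <- matrix(rnorm(30, sd = 3), 10, 3)
  dir <- matrix(rnorm(30), 10, 3)
  dir <- dir - matrix(colMeans(dir), 10, 3, byrow = TRUE)
  ## displacement orthogonalized against rigid motions is approximate;
  ## measure the actual planted RMSDs after superposition
  b1 <- a + 0.8 * dir / sqrt(mean(rowSums(dir^2)))
  b2 <- a + 2.5 * dir / sqrt(mean(rowSums(dir^2)))
  r1 <- kabschSuperpose(a, b1)$rmsd
  r2 <- kabschSuperpose(a, b2)$rmsd
  frames <- c(replicate(50, b1, simplify = FALSE),
              replicate(50, b2, simplify = FALSE))
  traj <- new("Trajectory", frames = frames, frameInterval = 10,
              replicaId = 1L)
  rs <- rmsdSeries(traj, 1:10, ref = a, binWidth = 0.05)
  h <- rs$histogram
  modes <- h$mids[h$counts > 0]
  expect_equal(sort(unique(round(rs$rmsd, 6))), sort(c(r1, r2)),
               tolerance = 1e-5)
  expect_true(any(abs(modes - r1) <= 0.05) && any(abs(modes - r2) <= 0.05))
})

test_that("RMSF recovers a planted isotropic fluctuation profile", {
  ## the rigid-body fit absorbs a fraction 6/(3N) of the variance, so the
  ## sqrt(3) sd identity is tested on a scaffold large enough (N = 60)
  ## for that deflation (~1.7%) to sit inside the 5% band
  set.seed(12)
  n <- 60
  base <- matrix(rnorm(3 * n, sd = 8), n, 3)
  sys <- beadSystem(n, resIndex = rep(0:(n / 2 - 1), each = 2L))
  traj <- makeFluctuatingTrajectory(base, rep(0.5, n), nFrames = 2000,
                                    seed = 6)
  prof <- rmsfProfile(traj, sys, seq_len(n))
  expect_equal(prof$rmsf, rep(sqrt(3 * 0.25), n / 2), tolerance = 0.05)
  ## doubling the spread doubles the RMSF
  traj2 <- makeFluctuatingTrajectory(base, rep(1.0, n), nFrames = 2000,
                                     seed = 6)
  prof2 <- rmsfProfile(traj2, sys, seq_len(n))
  expect_equal(prof2$rmsf / prof$rmsf, rep(2, n / 2), tolerance = 0.1)
  ## static trajectory -> zero
  statTraj <- new("Trajectory", frames = list(base, base),
                  frameInterval = 10, replicaId = 1L)
  expect_equal(rmsfProfile(statTraj, sys, seq_len(n))$rmsf,
               rep(0, n / 2), tolerance = 1e-9)
  ## rigid global motions do not inflate fluctuations
  trajR <- makeFluctuatingTrajectory(base, rep(0.5, n), nFrames = 1000,
                                     seed = 6, rigidMotion = TRUE)
  profR <- rmsfProfile(trajR, sys, seq_len(n))
  expect_equal(profR$rmsf, rep(sqrt(0.75), n / 2), tolerance = 0.05)
})

test_that("B-factor conversion inverts exactly", {
  expect_equal(bfactorToRmsf(0), 0)
  expect_equal(bfactorToRmsf(8 * pi^2 / 3), 1.0, tolerance = 1e-12)
  expect_equal(bfactorToRmsf(78.957), sqrt(3), tolerance = 1e-4)
  B <- c(5, 26.3, 80)
  expect_equal(8 * pi^2 * bfactorToRmsf(B)^2 / 3, B, tolerance = 1e-12)
  expect_error(bfactorToRmsf(-1), ">= 0")
})

test_that("hydrogen-bond occupancy counts satisfying frames", {
  ## donor O(1) - H(2) ... acceptor O(3); geometry toggled across frames
  atoms <- beadAtoms(3, name = c("O1", "H1", "O2"))
  atoms$element <- c("O", "H", "O")
  sys <- molecularSystem(atoms, bonds = data.frame(i = 1, j = 2, k = 400,
                                                   r0 = 1.0))
  good <- rbind(c(0, 0, 0), c(1, 0, 0), c(2.8, 0, 0))     # 180 degrees
  broken <- rbind(c(0, 0, 0), c(1, 0, 0), c(6, 0, 0))
  frames <- c(replicate(7, good, simplify = FALSE),
              replicate(3, broken, simplify = FALSE))
  traj <- new("Trajectory", frames = frames, frameInterval = 10,
              replicaId = 1L)
  hb <- hbondOccupancy(sys, traj, acceptors = 3L)
  expect_equal(hb$occupancy, 0.7)
  expect_equal(hb$mean_distance, 2.8, tolerance = 1e-9)
  expect_equal(hb$mean_angle, 180, tolerance = 1e-6)

  ## 90-degree geometry never satisfies the angle gate
  bent <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 2.0, 0))
  trajB <- new("Trajectory", frames = list(bent), frameInterval = 10,
               replicaId = 1L)
  expect_equal(hbondOccupancy(sys, trajB, acceptors = 3L)$occupancy, 0)

  ## occupancy is monotone in the cutoffs
  o1 <- hbondOccupancy(sys, traj, acceptors = 3L, distCut = 2.0)$occupancy
  o2 <- hbondOccupancy(sys, traj, acceptors = 3L, distCut = 3.5)$occupancy
  o3 <- hbondOccupancy(sys, traj, acceptors = 3L, distCut = 7.0)$occupancy
  expect_true(o1 <= o2 && o2 <= o3)
  a1 <- hbondOccupancy(sys, traj, acceptors = 3L, angleCut = 170)$occupancy
  a2 <- hbondOccupancy(sys, traj, acceptors = 3L, angleCut = 120)$occupancy
  expect_true(a1 <= a2)
})

test_that("hydrogen-bond tallies match a per-frame brute-force recheck", {
  set.seed(15)
  atoms <- beadAtoms(6, name = c("O1", "H1", "N1", "H2", "O2", "O3"))
  atoms$element <- c("O", "H", "N", "H", "O", "O")
  sys <- molecularSystem(atoms,
                         bonds = data.frame(i = c(1, 3), j = c(2, 4),
                                            k = 400, r0 = 1.0))
  frames <- replicate(25, {
    X <- matrix(runif(18, 0, 5), 6, 3)
    X[2, ] <- X[1, ] + c(1, 0, 0)
    X[4, ] <- X[3, ] + c(0, 1, 0)
    X
  }, simplify = FALSE)
  traj <- new("Trajectory", frames = frames, frameInterval = 10,
              replicaId = 1L)
  hb <- hbondOccupancy(sys, traj, acceptors = 5:6, distCut = 3.5,
                       angleCut = 120)
  for (r in seq_len(nrow(hb))) {
    cnt <- 0
    for (X in frames) {
      d <- sqrt(sum((X[hb$donor[r], ] - X[hb$acceptor[r], ])^2))
      v1 <- X[hb$donor[r], ] - X[hb$hydrogen[r], ]
      v2 <- X[hb$acceptor[r], ] - X[hb$hydrogen[r], ]
      ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
      if (d <= 3.5 && ang >= 120) cnt <- cnt + 1
    }
    expect_equal(hb$occupancy[r], cnt / 25)
  }
})

test_that("mass-center distance series reproduce simple geometry", {
  sys <- beadSystem(4, mass = c(1, 1, 1, 1),
                    resIndex = c(0L, 0L, 1L, 1L))
  X <- rbind(c(-1, 0, 0), c(1, 0, 0), c(2, 4, 0), c(4, 4, 0))
  traj <- new("Trajectory", frames = list(X, X), frameInterval = 10,
              replicaId = 1L)
  d <- distanceSeries(sys, traj, 1:2, 3:4, label = "D1")
  expect_equal(as.numeric(d), c(5, 5))   # COMs (0,0,0) and (3,4,0)
  expect_equal(attr(d, "mean"), 5)
  ## coincident centers
  Y <- rbind(c(-1, 0, 0), c(1, 0, 0), c(-2, 0, 0), c(2, 0, 0))
  trajY <- new("Trajectory", frames = list(Y), frameInterval = 10,
               replicaId = 1L)
  expect_equal(as.numeric(distanceSeries(sys, trajY, 1:2, 3:4)), 0)
  expect_error(distanceSeries(sys, traj, 1:2, 2:3), "disjoint")
})
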