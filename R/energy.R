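#' @include AllClasses.R molsys.R
NULL

#' Energy model parameters with overrides
#'
#' @param ... slot overrides, e.g. `gamma = 0.00542`, `dielectricOut = 80`.
#' @return an [EnergyModelParams]
#' @export
energyModelParams <- function(...) {
  args <- list(...)
  if ("sasaPoints" %in% names(args))
    args$sasaPoints <- as.integer(args$sasaPoints)
  do.call(new, c(list("EnergyModelParams"), args))
}

.groupIdx <- function(system, group) {
  if (is.null(group)) return(seq_len(nrow(system@atoms)))
  if (is(group, "AtomGroup")) group@indices else as.integer(group)
}

## n x m matrix of pairwise distances between two coordinate blocks
.crossDist <- function(A, B) {
  an <- rowSums(A * A); bn <- rowSums(B * B)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

.checkSingular <- function(D, what) {
  if (any(D < 1e-6))
    stop(sprintf("singularity: %s pair at distance < 1e-6 A", what),
         call. = FALSE)
}

## Weight matrix over an atom subset: 1 for counted pairs, 0 for 1-2/1-3
## exclusions, the scale factor for 1-4 pairs; upper triangle only.
.intraWeights <- function(system, idx, scaleCol) {
  n <- length(idx)
  W <- matrix(0, n, n)
  W[upper.tri(W)] <- 1
  map <- integer(nrow(system@atoms)); map[idx] <- seq_along(idx)
  ex <- system@exclusions
  if (nrow(ex)) {
    keep <- ex[, 1] %in% idx & ex[, 2] %in% idx
    for (r in which(keep)) {
      i <- map[ex[r, 1]]; j <- map[ex[r, 2]]
      W[min(i, j), max(i, j)] <- 0
    }
  }
  p <- system@pairs14
  if (nrow(p)) {
    keep <- p$i %in% idx & p$j %in% idx
    for (r in which(keep)) {
      i <- map[p$i[r]]; j <- map[p$j[r]]
      W[min(i, j), max(i, j)] <- p[[scaleCol]][r]
    }
  }
  W
}

#' Coulomb electrostatic energy
#'
#' `E = k sum q_i q_j / r_ij` with no distance cutoff. In inter-group mode
#' all cross pairs between two disjoint groups are counted with no
#' exclusions; in intra mode (the default when `groupB` is missing) pairs
#' within `groupA` are counted with 1-2/1-3 exclusions removed and 1-4 pairs
#' scaled.
#'
#' @param system a parameterized [MolecularSystem].
#' @param frame n x 3 coordinates (A).
#' @param groupA,groupB [AtomGroup]s or index vectors; `groupA = NULL` means
#'   all atoms.
#' @param params an [EnergyModelParams].
#' @param intra logical; force intra mode.
#' @return energy in kcal/mol
#' @export
coulombEnergy <- function(system, frame, groupA = NULL, groupB = NULL,
                          params = energyModelParams(),
                          intra = is.null(groupB)) {
  q <- system@atoms$charge
  if (anyNA(q)) stop("charges are not set", call. = FALSE)
  ia <- .groupIdx(system, groupA)
  if (intra) {
    if (length(ia) < 2L) return(0)
    D <- .crossDist(frame[ia, , drop = FALSE], frame[ia, , drop = FALSE])
    W <- .intraWeights(system, ia, "ele_scale")
    .checkSingular(D[W > 0], "charged")
    Q <- outer(q[ia], q[ia])
    return(params@coulombK * sum(W * Q / pmax(D, 1e-12)))
  }
  ib <- .groupIdx(system, groupB)
  if (length(intersect(ia, ib)))
    stop("inter-group energy requires disjoint groups", call. = FALSE)
  D <- .crossDist(frame[ia, , drop = FALSE], frame[ib, , drop = FALSE])
  .checkSingular(D, "charged")
  params@coulombK * sum(outer(q[ia], q[ib]) / D)
}

#' Lennard-Jones 12-6 energy
#'
#' Lorentz-Berthelot combining: `Rmin_ij = rmin_half_i + rmin_half_j`,
#' `eps_ij = sqrt(eps_i eps_j)`; `E = sum eps_ij ((Rmin/r)^12 - 2 (Rmin/r)^6)`
#' with no cutoff. Modes as in [coulombEnergy()].
#'
#' @inheritParams coulombEnergy
#' @return energy in kcal/mol
#' @export
ljEnergy <- function(system, frame, groupA = NULL, groupB = NULL,
                     params = energyModelParams(),
                     intra = is.null(groupB)) {
  a <- system@atoms
  if (anyNA(a$lj_rmin_half)) stop("LJ parameters are not set", call. = FALSE)
  ia <- .groupIdx(system, groupA)
  ljSum <- function(ii, jj, W) {
    D <- .crossDist(frame[ii, , drop = FALSE], frame[jj, , drop = FALSE])
    .checkSingular(if (is.null(W)) D else D[W > 0], "LJ")
    Rmin <- outer(a$lj_rmin_half[ii], a$lj_rmin_half[jj], "+")
    EPS <- sqrt(outer(a$lj_epsilon[ii], a$lj_epsilon[jj]))
    s6 <- (Rmin / pmax(D, 1e-12))^6
    term <- EPS * (s6 * s6 - 2 * s6)
    if (is.null(W)) sum(term) else sum(W * term)
  }
  if (intra) {
    if (length(ia) < 2L) return(0)
    return(ljSum(ia, ia, .intraWeights(system, ia, "vdw_scale")))
  }
  ib <- .groupIdx(system, groupB)
  if (length(intersect(ia, ib)))
    stop("inter-group energy requires disjoint groups", call. = FALSE)
  ljSum(ia, ib, NULL)
}

#' Harmonic bond energy
#'
#' `E = sum k/2 (r - r0)^2` over the bond list (restricted to bonds internal
#' to `group` when given).
#'
#' @inheritParams coulombEnergy
#' @param group atom subset; `NULL` = all.
#' @return energy in kcal/mol
#' @export
bondEnergy <- function(system, frame, group = NULL) {
  b <- system@bonds
  if (!nrow(b)) return(0)
  idx <- .groupIdx(system, group)
  keep <- b$i %in% idx & b$j %in% idx
  if (!any(keep)) return(0)
  b <- b[keep, , drop = FALSE]
  d <- sqrt(rowSums((frame[b$i, , drop = FALSE] -
                     frame[b$j, , drop = FALSE])^2))
  sum(b$k / 2 * (d - b$r0)^2)
}

## ---- generalized Born (OBC) -------------------------------------------

## Pairwise HCT descreening integral. r, or1 (descreened atom's reduced
## radius) and sr2 (neighbor's scaled reduced radius) are same-shape arrays.
.hctIntegral <- function(r, or1, sr2) {
  U <- r + sr2
  L <- pmax(or1, abs(r - sr2))
  base <- 1 / L - 1 / U + 0.25 * (r - sr2^2 / r) * (1 / U^2 - 1 / L^2) +
    0.5 * log(L / U) / r
  corr <- ifelse(sr2 - r > or1, 2 * (1 / or1 - 1 / L), 0)
  ifelse(or1 >= U, 0, 0.5 * (base + corr))
}

#' Effective Born radii (OBC model)
#'
#' Pairwise HCT descreening integrals summed per atom, rescaled through the
#' OBC tanh correction: `1/R_i = 1/rho~_i - tanh(a P - b P^2 + g P^3)/rho_i`
#' with `P = I_i rho~_i` and `rho~_i = rho_i - offset`. An isolated atom's
#' effective radius is its intrinsic radius minus the dielectric offset.
#'
#' @inheritParams bondEnergy
#' @return numeric vector of effective radii (A) for the atoms of `group`
#' @export
effectiveBornRadii <- function(system, frame, group = NULL,
                               params = energyModelParams()) {
  idx <- .groupIdx(system, group)
  a <- system@atoms
  rho <- a$gb_radius[idx]; scr <- a$gb_screen[idx]
  if (anyNA(rho) || anyNA(scr)) stop("GB parameters are not set",
                                     call. = FALSE)
  if (any(rho <= params@gbOffset))
    stop("gb_radius must exceed the dielectric offset", call. = FALSE)
  n <- length(idx)
  or <- rho - params@gbOffset
  if (n == 1L) return(or)
  X <- frame[idx, , drop = FALSE]
  D <- .crossDist(X, X)
  OR1 <- matrix(or, n, n)                 # row atom being descreened
  SR2 <- matrix(scr * or, n, n, byrow = TRUE)
  diag(D) <- 1                            # dummy, masked below
  I <- .hctIntegral(D, OR1, SR2)
  diag(I) <- 0
  Ii <- rowSums(I)
  psi <- Ii * or
  tanhArg <- params@obcAlpha * psi - params@obcBeta * psi^2 +
    params@obcGamma * psi^3
  1 / (1 / or - tanh(tanhArg) / rho)
}

#' Generalized Born polar solvation energy
#'
#' `G_pol = -(k/2)(1/e_in - 1/e_out) sum_ij q_i q_j / f_GB` with
#' `f_GB = sqrt(r^2 + R_i R_j exp(-r^2/(4 R_i R_j)))`, self terms included.
#' When `group` is given, the subset is treated as an isolated molecule (its
#' Born radii are computed with only those atoms present).
#'
#' @inheritParams bondEnergy
#' @param bornRadii optional precomputed effective radii for the group.
#' @param perAtom logical; also return per-atom contributions (pair terms
#'   half-split between partners, self terms to their own atom).
#' @return energy in kcal/mol, or `list(total, perAtom)` if `perAtom`
#' @export
gbPolarEnergy <- function(system, frame, group = NULL,
                          params = energyModelParams(), bornRadii = NULL,
                          perAtom = FALSE) {
  idx <- .groupIdx(system, group)
  q <- system@atoms$charge[idx]
  if (anyNA(q)) stop("charges are not set", call. = FALSE)
  R <- if (is.null(bornRadii))
    effectiveBornRadii(system, frame, idx, params) else bornRadii
  X <- frame[idx, , drop = FALSE]
  D <- .crossDist(X, X)
  RR <- outer(R, R)
  f <- sqrt(D^2 + RR * exp(-D^2 / (4 * RR)))
  pref <- params@coulombK *
    (1 / params@dielectricIn - 1 / params@dielectricOut)
  M <- outer(q, q) / f
  contrib <- -(pref / 2) * rowSums(M)
  total <- sum(contrib)
  if (perAtom) list(total = total, perAtom = contrib) else total
}

## ---- solvent accessible surface area ----------------------------------

## Deterministic quasi-uniform unit-sphere point set (Fibonacci spiral).
.spherePoints <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Sphere-point counting on each atom's solvent-expanded sphere of radius
#' `r_i + probe`. Atom radii default to the Lennard-Jones `rmin/2`.
#'
#' @inheritParams bondEnergy
#' @param radii optional explicit per-atom radii (A) for the group's atoms.
#' @return list with `perAtom` (A^2, in group order) and `total` (A^2)
#' @export
sasa <- function(system, frame, group = NULL, params = energyModelParams(),
                 radii = NULL) {
  idx <- .groupIdx(system, group)
  r <- if (is.null(radii)) system@atoms$lj_rmin_half[idx] else radii
  if (anyNA(r)) stop("atom radii are not set", call. = FALSE)
  if (any(r <= 0)) stop("zero-radius atom in SASA calculation",
                        call. = FALSE)
  probe <- params@probeRadius
  pts <- .spherePoints(params@sasaPoints)
  X <- frame[idx, , drop = FALSE]
  n <- length(idx)
  D <- .crossDist(X, X)
  per <- numeric(n)
  for (i in seq_len(n)) {
    Ri <- r[i] + probe
    nb <- which(D[i, ] < Ri + r + probe & seq_len(n) != i)
    if (!length(nb)) { per[i] <- 4 * pi * Ri^2; next }
    P <- sweep(pts * Ri, 2L, X[i, ], "+")
    free <- rep(TRUE, nrow(P))
    for (j in nb) {
      if (!any(free)) break
      dj <- (P[free, 1] - X[j, 1])^2 + (P[free, 2] - X[j, 2])^2 +
        (P[free, 3] - X[j, 3])^2
      free[free] <- dj > (r[j] + probe)^2
    }
    per[i] <- 4 * pi * Ri^2 * sum(free) / nrow(P)
  }
  list(perAtom = per, total = sum(per))
}

#' Nonpolar solvation energy from a surface area
#'
#' `G_nonpol = gamma * SASA + beta`.
#'
#' @param sasaTotal surface area (A^2), `>= 0`.
#' @param params an [EnergyModelParams].
#' @return energy in kcal/mol
#' @export
nonpolarEnergy <- function(sasaTotal, params = energyModelParams()) {
  stopifnot(sasaTotal >= 0)
  params@gamma * sasaTotal + params@betaConst
}

## ---- binding components -----------------------------------------------

#' Absolute energy components of one species in one frame
#'
#' Intra-group molecular-mechanics terms plus implicit-solvent terms for the
#' group treated as an isolated molecule. `E_int` here is the bonded (bond
#' stretch) energy.
#'
#' @inheritParams bondEnergy
#' @return one-row data.frame: `E_ele`, `E_vdw`, `E_int`, `G_pol`,
#'   `G_nonpol`, `sasa_total`
#' @export
energyComponents <- function(system, frame, group = NULL,
                             params = energyModelParams()) {
  idx <- .groupIdx(system, group)
  s <- sasa(system, frame, idx, params)
  data.frame(E_ele = coulombEnergy(system, frame, idx, params = params,
                                   intra = TRUE),
             E_vdw = ljEnergy(system, frame, idx, params = params,
                              intra = TRUE),
             E_int = bondEnergy(system, frame, idx),
             G_pol = gbPolarEnergy(system, frame, idx, params),
             G_nonpol = nonpolarEnergy(s$total, params),
             sasa_total = s$total)
}

#' Single-snapshot binding energy components (single-trajectory convention)
#'
#' Each Delta term is `term(complex) - term(receptor) - term(ligand)` with
#' receptor and ligand coordinates taken from the same complex frame. Under
#' this convention the intramolecular MM terms cancel exactly, so `dE_ele`
#' and `dE_vdw` are computed as the inter-group sums and `dE_int = 0`.
#' Supplying `receptorFrame`/`ligandFrame` switches to the three-trajectory
#' convention, where every term (including `dE_int`) is a difference of
#' species evaluated at their own geometries.
#'
#' @inheritParams bondEnergy
#' @param receptorGroup,ligandGroup disjoint [AtomGroup]s covering all atoms.
#' @param receptorFrame,ligandFrame optional species-own coordinates
#'   (n_receptor x 3 / n_ligand x 3) for three-trajectory mode.
#' @return one-row data.frame of Delta components: `E_ele`, `E_vdw`,
#'   `E_int`, `G_pol`, `G_nonpol`, `sasa_total` (Delta SASA)
#' @export
snapshotBindingComponents <- function(system, frame, receptorGroup,
                                      ligandGroup,
                                      params = energyModelParams(),
                                      receptorFrame = NULL,
                                      ligandFrame = NULL) {
  ir <- .groupIdx(system, receptorGroup)
  il <- .groupIdx(system, ligandGroup)
  if (!length(il)) stop("ligand group is empty", call. = FALSE)
  if (length(intersect(ir, il)))
    stop("receptor and ligand groups overlap", call. = FALSE)
  if (!setequal(c(ir, il), seq_len(nrow(system@atoms))))
    stop("receptor and ligand groups must cover every atom", call. = FALSE)

  threeTraj <- !is.null(receptorFrame) || !is.null(ligandFrame)
  if (!threeTraj) {
    gC <- gbPolarEnergy(system, frame, NULL, params)
    gR <- gbPolarEnergy(system, frame, ir, params)
    gL <- gbPolarEnergy(system, frame, il, params)
    sC <- sasa(system, frame, NULL, params)$total
    sR <- sasa(system, frame, ir, params)$total
    sL <- sasa(system, frame, il, params)$total
    dS <- sC - sR - sL
    return(data.frame(
      E_ele = coulombEnergy(system, frame, ir, il, params),
      E_vdw = ljEnergy(system, frame, ir, il, params),
      E_int = 0,
      G_pol = gC - gR - gL,
      G_nonpol = params@gamma * dS - params@betaConst,
      sasa_total = dS))
  }
  if (is.null(receptorFrame) || is.null(ligandFrame))
    stop("three-trajectory mode needs both receptorFrame and ligandFrame",
         call. = FALSE)
  sysR <- subsetSystem(system, ir)
  sysL <- subsetSystem(system, il)
  cc <- energyComponents(system, frame, NULL, params)
  cr <- energyComponents(sysR, receptorFrame, NULL, params)
  cl <- energyComponents(sysL, ligandFrame, NULL, params)
  d <- cc
  for (k in names(d)) d[[k]] <- cc[[k]] - cr[[k]] - cl[[k]]
  ## Delta G_nonpol from the gamma*S+beta form: beta enters once with sign -1
  d$G_nonpol <- params@gamma * d$sasa_total - params@betaConst
  d
}

#' Aggregate per-frame components over replicas
#'
#' Frames are averaged within each replica; the reported mean of every term
#' is the mean of the replica means and its standard error is
#' `sd(replica means)/sqrt(N)`. Derived rows (`dH`, `dGelepol`,
#' `dGvdwnonpol`, `dGbind`) are formed per replica before aggregation so
#' their standard errors are internally consistent.
#'
#' @param components data.frame of per-frame Delta components (`E_ele`,
#'   `E_vdw`, `E_int`, `G_pol`, `G_nonpol`) with a `replica` column.
#' @param TdS the entropy term T*DeltaS (kcal/mol).
#' @param TdSse optional standard error of `TdS`; combined in quadrature into
#'   the `dGbind` standard error.
#' @return a [BindingFreeEnergyResult]
#' @export
aggregateReplicas <- function(components, TdS, TdSse = NA_real_) {
  stopifnot(nrow(components) >= 1L, "replica" %in% names(components))
  terms <- c("E_ele", "E_vdw", "E_int", "G_pol", "G_nonpol")
  repMeans <- do.call(rbind, lapply(split(components, components$replica),
    function(d) vapply(terms, function(k) mean(d[[k]]), 1.0)))
  N <- nrow(repMeans)
  der <- cbind(repMeans,
               dGelepol = repMeans[, "E_ele"] + repMeans[, "G_pol"],
               dGvdwnonpol = repMeans[, "E_vdw"] + repMeans[, "G_nonpol"],
               dH = rowSums(repMeans))
  m <- colMeans(der)
  se <- if (N > 1L) apply(der, 2L, stats::sd) / sqrt(N)
        else rep(NA_real_, ncol(der))
  names(se) <- colnames(der)
  means <- c(dEele = m[["E_ele"]], dEvdw = m[["E_vdw"]],
             dEint = m[["E_int"]], dGpol = m[["G_pol"]],
             dGnonpol = m[["G_nonpol"]], dGelepol = m[["dGelepol"]],
             dGvdwnonpol = m[["dGvdwnonpol"]], dH = m[["dH"]],
             TdS = TdS, dGbind = m[["dH"]] - TdS)
  seBind <- if (is.na(TdSse)) se[["dH"]] else
    sqrt(se[["dH"]]^2 + TdSse^2)
  ses <- c(dEele = se[["E_ele"]], dEvdw = se[["E_vdw"]],
           dEint = se[["E_int"]], dGpol = se[["G_pol"]],
           dGnonpol = se[["G_nonpol"]], dGelepol = se[["dGelepol"]],
           dGvdwnonpol = se[["dGvdwnonpol"]], dH = se[["dH"]],
           TdS = TdSse, dGbind = seBind)
  new("BindingFreeEnergyResult", means = means, se = ses,
      nReplicas = as.integer(N))
}

#' Build a BindingFreeEnergyResult from component means
#'
#' Derived rows (`dH`, `dGelepol`, `dGvdwnonpol`, `dGbind`) are recomputed
#' from the five components and the entropy term; useful for auditing
#' published tables.
#'
#' @param dEele,dEvdw,dEint,dGpol,dGnonpol,TdS component means (kcal/mol).
#' @param se optional named numeric of standard errors.
#' @param nReplicas integer.
#' @return a [BindingFreeEnergyResult]
#' @export
bindingFreeEnergyResult <- function(dEele, dEvdw, dEint, dGpol, dGnonpol,
                                    TdS, se = NULL, nReplicas = 1L) {
  dH <- dEele + dEvdw + dEint + dGpol + dGnonpol
  means <- c(dEele = dEele, dEvdw = dEvdw, dEint = dEint, dGpol = dGpol,
             dGnonpol = dGnonpol, dGelepol = dEele + dGpol,
             dGvdwnonpol = dEvdw + dGnonpol, dH = dH, TdS = TdS,
             dGbind = dH - TdS)
  ses <- stats::setNames(rep(NA_real_, length(means)), names(means))
  if (!is.null(se)) ses[names(se)] <- se
  new("BindingFreeEnergyResult", means = means, se = ses,
      nReplicas = as.integer(nReplicas))
}

## ---- per-residue decomposition ----------------------------------------

#' Per-nucleotide (per-residue) free energy decomposition
#'
#' The binding free energy (without the entropy term) is split over residues
#' into four terms: inter-group electrostatic and van der Waals pair energies
#' (each pair half to either partner's residue), the generalized-Born polar
#' difference (pair terms half-split, self terms to their own residue), and
#' the per-atom SASA difference scaled by gamma. The constant `beta` of the
#' nonpolar model enters the total once and is reported on a pseudo-residue
#' row named `offset`. Contributions are averaged over the supplied frames.
#'
#' @inheritParams snapshotBindingComponents
#' @param frames a [Trajectory] or list of coordinate matrices.
#' @return data.frame: `author_resid`, `residue_name`, `ele`, `vdw`, `pol`,
#'   `nonpol`, `total` (kcal/mol); one row per residue plus the `offset` row.
#' @export
perResidueDecomposition <- function(system, frames, receptorGroup,
                                    ligandGroup,
                                    params = energyModelParams()) {
  if (is(frames, "Trajectory")) frames <- frames@frames
  if (is.matrix(frames)) frames <- list(frames)
  ir <- .groupIdx(system, receptorGroup)
  il <- .groupIdx(system, ligandGroup)
  if (!length(il)) stop("ligand group is empty", call. = FALSE)
  a <- system@atoms
  nres <- nrow(system@residues)
  resOf <- a$residue_index + 1L          # 1-based residue slot per atom
  q <- a$charge
  acc <- matrix(0, nres, 4L,
                dimnames = list(NULL, c("ele", "vdw", "pol", "nonpol")))
  addByRes <- function(col, perAtomVals, atomIdx) {
    s <- rowsum(perAtomVals, resOf[atomIdx])
    rows <- as.integer(rownames(s))
    acc[rows, col] <<- acc[rows, col] + s[, 1L]
  }
  for (fr in frames) {
    D <- .crossDist(fr[ir, , drop = FALSE], fr[il, , drop = FALSE])
    Epair <- params@coulombK * outer(q[ir], q[il]) / D
    Rmin <- outer(a$lj_rmin_half[ir], a$lj_rmin_half[il], "+")
    EPS <- sqrt(outer(a$lj_epsilon[ir], a$lj_epsilon[il]))
    s6 <- (Rmin / D)^6
    Vpair <- EPS * (s6 * s6 - 2 * s6)
    addByRes("ele", 0.5 * rowSums(Epair), ir)
    addByRes("ele", 0.5 * colSums(Epair), il)
    addByRes("vdw", 0.5 * rowSums(Vpair), ir)
    addByRes("vdw", 0.5 * colSums(Vpair), il)
    pc <- gbPolarEnergy(system, fr, NULL, params, perAtom = TRUE)$perAtom
    pr <- gbPolarEnergy(system, fr, ir, params, perAtom = TRUE)$perAtom
    pl <- gbPolarEnergy(system, fr, il, params, perAtom = TRUE)$perAtom
    dpol <- pc
    dpol[ir] <- pc[ir] - pr
    dpol[il] <- pc[il] - pl
    addByRes("pol", dpol, seq_len(nrow(a)))
    sc <- sasa(system, fr, NULL, params)$perAtom
    sr <- sasa(system, fr, ir, params)$perAtom
    sl <- sasa(system, fr, il, params)$perAtom
    ds <- sc; ds[ir] <- sc[ir] - sr; ds[il] <- sc[il] - sl
    addByRes("nonpol", params@gamma * ds, seq_len(nrow(a)))
  }
  acc <- acc / length(frames)
  res <- system@residues
  out <- data.frame(author_resid = res$author_resid,
                    residue_name = res$residue_name,
                    ele = acc[, "ele"], vdw = acc[, "vdw"],
                    pol = acc[, "pol"], nonpol = acc[, "nonpol"])
  out <- rbind(out, data.frame(author_resid = NA_integer_,
                               residue_name = "offset", ele = 0, vdw = 0,
                               pol = 0, nonpol = -params@betaConst))
  out$total <- out$ele + out$vdw + out$pol + out$nonpol
  out
}
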