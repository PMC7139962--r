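#' @include AllClasses.R molsys.R
NULL

## Synthetic-data generators. Every generator is bit-reproducible for a
## fixed seed (each draws from its own deterministic substream, so adding a
## generator never perturbs the others) and returns its planted ground
## truth alongside the data.

#' Random bead-molecule system with known parameters
#'
#' Atoms are packed uniformly into a cubic box under a minimum-separation
#' constraint (rejection sampling with bounded retries). Charges are drawn
#' uniformly and shifted to an exact target net charge. The last
#' `nLigandAtoms` atoms form the ligand residue (`LIG`); receptor atoms are
#' grouped into residues of `atomsPerResidue` beads so that per-residue
#' decomposition is exercised.
#'
#' @param nAtoms total bead count.
#' @param nLigandAtoms beads in the ligand (last atoms).
#' @param seed integer seed.
#' @param chargeRange,rminHalfRange,epsilonRange,gbRadiusRange parameter
#'   draw ranges.
#' @param minSeparation minimum pairwise distance, A.
#' @param boxSize cubic box edge, A.
#' @param netCharge exact total charge, e.
#' @param atomsPerResidue receptor residue size.
#' @param bonded logical; chain consecutive atoms within each residue with
#'   harmonic bonds.
#' @return list: `system` (a [MolecularSystem]), `frame` (n x 3),
#'   `receptor`, `ligand` (index vectors)
#' @export
makeToySystem <- function(nAtoms = 12L, nLigandAtoms = 3L, seed = 1L,
                          chargeRange = c(-0.8, 0.8),
                          rminHalfRange = c(1.4, 2.0),
                          epsilonRange = c(0.05, 0.2),
                          gbRadiusRange = c(1.3, 1.9),
                          minSeparation = 2.8, boxSize = NULL,
                          netCharge = 0, atomsPerResidue = 3L,
                          bonded = FALSE) {
  stopifnot(nLigandAtoms >= 1L, nLigandAtoms < nAtoms)
  if (is.null(boxSize)) boxSize <- max(8, 2.2 * minSeparation * nAtoms^(1/3))
  withSeed(subSeed(seed, "toy_system"), {
    X <- matrix(NA_real_, nAtoms, 3L)
    X[1L, ] <- stats::runif(3, 0, boxSize)
    for (i in 2L:nAtoms) {
      placed <- FALSE
      for (try in seq_len(2000L)) {
        p <- stats::runif(3, 0, boxSize)
        d2 <- rowSums((X[seq_len(i - 1L), , drop = FALSE] -
                       matrix(p, i - 1L, 3L, byrow = TRUE))^2)
        if (all(d2 >= minSeparation^2)) {
          X[i, ] <- p; placed <- TRUE; break
        }
      }
      if (!placed)
        stop("packing failure: could not honour minSeparation",
             call. = FALSE)
    }
    q <- stats::runif(nAtoms, chargeRange[1L], chargeRange[2L])
    q <- q - mean(q) + netCharge / nAtoms
    nRec <- nAtoms - nLigandAtoms
    resIdx <- c((seq_len(nRec) - 1L) %/% atomsPerResidue,
                rep(max(0L, (nRec - 1L) %/% atomsPerResidue) + 1L,
                    nLigandAtoms))
    atoms <- data.frame(
      name = paste0("B", seq_len(nAtoms)),
      element = "C",
      mass = stats::runif(nAtoms, 10, 16),
      charge = q,
      lj_rmin_half = stats::runif(nAtoms, rminHalfRange[1L],
                                  rminHalfRange[2L]),
      lj_epsilon = stats::runif(nAtoms, epsilonRange[1L], epsilonRange[2L]),
      gb_radius = stats::runif(nAtoms, gbRadiusRange[1L], gbRadiusRange[2L]),
      gb_screen = stats::runif(nAtoms, 0.7, 0.9),
      residue_index = resIdx,
      residue_name = ifelse(resIdx == max(resIdx), "LIG", "BEA"),
      author_resid = resIdx + 1L)
    bonds <- NULL
    if (bonded) {
      ij <- which(diff(resIdx) == 0L)
      if (length(ij))
        bonds <- data.frame(i = ij, j = ij + 1L, k = 200,
                            r0 = minSeparation)
    }
    list(system = molecularSystem(atoms, bonds = bonds), frame = X,
         receptor = seq_len(nRec), ligand = nRec + seq_len(nLigandAtoms))
  })
}

#' Two-state (open/closed) Markov distance series with Gaussian emission
#'
#' A first-order Markov chain on \{open, closed\} with stay probabilities
#' `pStayOpen`/`pStayClosed`; the emitted distance is the state mean plus
#' Gaussian noise. The stationary open probability is
#' `(1 - pStayClosed) / ((1 - pStayOpen) + (1 - pStayClosed))`.
#'
#' @param nFrames series length.
#' @param pStayOpen,pStayClosed stay probabilities, in (0, 1].
#' @param meanOpen,meanClosed emission means, A (`meanClosed < meanOpen`).
#' @param emissionSd emission standard deviation, A.
#' @param seed integer seed.
#' @param start starting state, `"open"` or `"closed"`.
#' @return list: `distance` (numeric), `labels` (character ground truth),
#'   `stationaryOpen` (planted stationary open probability)
#' @export
makeTwoStateSeries <- function(nFrames = 10000L, pStayOpen = 0.98,
                               pStayClosed = 0.98, meanOpen = 22.98,
                               meanClosed = 20.59, emissionSd = 0.6,
                               seed = 1L, start = "open") {
  stopifnot(meanClosed < meanOpen, pStayOpen > 0, pStayOpen <= 1,
            pStayClosed > 0, pStayClosed <= 1, emissionSd >= 0)
  withSeed(subSeed(seed, "two_state"), {
    state <- character(nFrames)
    state[1L] <- start
    u <- stats::runif(nFrames)
    for (t in seq_len(nFrames - 1L)) {
      stay <- if (state[t] == "open") pStayOpen else pStayClosed
      state[t + 1L] <- if (u[t] <= stay) state[t]
                       else if (state[t] == "open") "closed" else "open"
    }
    mu <- ifelse(state == "open", meanOpen, meanClosed)
    d <- mu + stats::rnorm(nFrames, 0, emissionSd)
    pOpen <- (1 - pStayClosed) /
      ((1 - pStayOpen) + (1 - pStayClosed))
    list(distance = d, labels = state, stationaryOpen = pOpen)
  })
}

#' Per-frame energy-component tables with known means and spreads
#'
#' Independent Gaussian draws per term, frame and replica: a fixture for
#' replica aggregation (grand means recover `means`; the reported standard
#' error approaches `sds/sqrt(nFrames)/sqrt(nReplicas)`).
#'
#' @param means,sds named numeric over `E_ele`, `E_vdw`, `E_int`, `G_pol`,
#'   `G_nonpol`.
#' @param nFrames frames per replica.
#' @param nReplicas replica count.
#' @param seed integer seed.
#' @return data.frame of per-frame components with a `replica` column
#' @export
makeEnergyFrames <- function(means, sds, nFrames = 500L, nReplicas = 10L,
                             seed = 1L) {
  terms <- c("E_ele", "E_vdw", "E_int", "G_pol", "G_nonpol")
  stopifnot(all(terms %in% names(means)), all(terms %in% names(sds)),
            all(sds[terms] >= 0))
  withSeed(subSeed(seed, "energy_frames"), {
    out <- do.call(rbind, lapply(seq_len(nReplicas), function(r) {
      d <- as.data.frame(lapply(terms, function(k)
        stats::rnorm(nFrames, means[[k]], sds[[k]])))
      names(d) <- terms
      d$replica <- r
      d
    }))
    rownames(out) <- NULL
    out
  })
}

#' Fluctuating trajectory about a base frame with prescribed per-atom spread
#'
#' Isotropic Gaussian displacement per atom and frame (so the expected RMSF
#' of atom i is `sd_i * sqrt(3)`), optionally composed with a random global
#' rigid motion per frame to exercise superposition.
#'
#' @param base n x 3 base coordinates.
#' @param perAtomSd per-atom displacement sd (A), length n.
#' @param nFrames frame count.
#' @param seed integer seed.
#' @param rigidMotion logical; apply a random rotation + translation to
#'   every frame.
#' @param frameInterval ps.
#' @return a [Trajectory]
#' @export
makeFluctuatingTrajectory <- function(base, perAtomSd, nFrames = 2000L,
                                      seed = 1L, rigidMotion = FALSE,
                                      frameInterval = 10) {
  n <- nrow(base)
  stopifnot(length(perAtomSd) == n)
  withSeed(subSeed(seed, "fluct_traj"), {
    frames <- lapply(seq_len(nFrames), function(f) {
      fr <- base + matrix(stats::rnorm(3L * n), n, 3L) * perAtomSd
      if (rigidMotion) {
        M <- matrix(stats::rnorm(9), 3L)
        R <- qr.Q(qr(M))
        if (det(R) < 0) R[, 1L] <- -R[, 1L]
        fr <- fr %*% R + matrix(stats::runif(3, -20, 20), n, 3L,
                                byrow = TRUE)
      }
      fr
    })
    new("Trajectory", frames = frames, frameInterval = frameInterval,
        replicaId = 1L)
  })
}

#' Write a toy system's parameters as a TSV table
#'
#' Emits the same columnar format [readParameters()] consumes (keys
#' `RESNAME:ATOMNAME`), closing the round-trip loop for synthetic systems.
#'
#' @param system a parameterized [MolecularSystem].
#' @param file output path.
#' @return invisibly, the path
#' @export
writeParameterTable <- function(system, file) {
  a <- system@atoms
  tab <- data.frame(atom_key = paste0(a$residue_name, ":", a$name),
                    mass = a$mass, charge = a$charge,
                    rmin_half = a$lj_rmin_half, epsilon = a$lj_epsilon,
                    gb_radius = a$gb_radius, gb_screen = a$gb_screen)
  utils::write.table(tab, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
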