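#' @include AllClasses.R molsys.R
NULL

#' Kabsch least-squares superposition
#'
#' Optimal proper rotation (determinant +1 enforced by sign correction on
#' the smallest singular direction) and translation mapping `mobile` onto
#' `ref`. Degenerate point sets (fewer than 3 points, or collinear) fall
#' back to a translation-only fit, flagged in the result.
#'
#' @param ref,mobile m x 3 coordinate matrices (equal row counts).
#' @param weights optional non-negative per-point weights.
#' @return list: `rotation` (3 x 3), `translation` (length 3; the fit is
#'   `mobile %*% t(rotation) + translation`), `rmsd` (A), `degenerate`
#'   (logical)
#' @export
kabschSuperpose <- function(ref, mobile, weights = NULL) {
  stopifnot(nrow(ref) == nrow(mobile))
  m <- nrow(ref)
  if (m < 1L) stop("superposition needs at least one point", call. = FALSE)
  w <- if (is.null(weights)) rep(1, m) else weights
  stopifnot(length(w) == m, all(w >= 0), sum(w) > 0)
  w <- w / sum(w)
  cr <- colSums(ref * w); cm <- colSums(mobile * w)
  A <- sweep(ref, 2L, cr); B <- sweep(mobile, 2L, cm)
  H <- t(B * w) %*% A
  sv <- svd(H)
  degenerate <- m < 3L || sv$d[2L] < 1e-8 * max(sv$d[1L], 1e-300)
  if (degenerate) {
    R <- diag(3)
  } else {
    d <- sign(det(sv$v %*% t(sv$u)))
    R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  }
  fitted <- B %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((fitted - A)^2)))
  list(rotation = R, translation = as.numeric(cr - cm %*% t(R)),
       rmsd = rmsd, degenerate = degenerate)
}

.applyFit <- function(coords, fit) {
  sweep(coords %*% t(fit$rotation), 2L, fit$translation, "+")
}

#' Per-frame RMSD of a selection relative to a reference frame
#'
#' Each frame's selected atoms are superposed (Kabsch) onto the reference
#' selection before the RMSD is taken; a histogram of the values is returned
#' for distribution panels.
#'
#' @param traj a [Trajectory].
#' @param selection an [AtomGroup] or index vector.
#' @param ref reference frame number (default 1, the starting structure) or
#'   an explicit n x 3 matrix.
#' @param binWidth histogram bin width, A.
#' @return list: `rmsd` (numeric per frame), `histogram` (`hist` object)
#' @export
rmsdSeries <- function(traj, selection, ref = 1L, binWidth = 0.1) {
  idx <- if (is(selection, "AtomGroup")) selection@indices
         else as.integer(selection)
  if (!length(idx)) stop("empty selection", call. = FALSE)
  refX <- if (is.matrix(ref)) ref[idx, , drop = FALSE]
          else traj@frames[[ref]][idx, , drop = FALSE]
  vals <- vapply(traj@frames, function(fr)
    kabschSuperpose(refX, fr[idx, , drop = FALSE])$rmsd, 1.0)
  breaks <- seq(0, max(vals) + binWidth, by = binWidth)
  list(rmsd = vals,
       histogram = graphics::hist(vals, breaks = breaks, plot = FALSE))
}

#' Root-mean-square fluctuation per residue (or per atom)
#'
#' Frames are superposed on the selection onto frame 1, the mean structure
#' is formed, frames are re-superposed onto that mean (one refinement pass),
#' and `RMSF_i = sqrt(<|r_i - <r_i>|^2>)` is computed per selected atom,
#' then averaged over each residue's selected atoms.
#'
#' @param traj a [Trajectory] (>= 2 frames).
#' @param system the [MolecularSystem] (residue grouping and labels).
#' @param selection an [AtomGroup] or index vector.
#' @param perResidue logical; FALSE returns per-atom values.
#' @return data.frame: `author_resid`, `residue_name`, `rmsf` (A); or with
#'   `atom` column when `perResidue = FALSE`
#' @export
rmsfProfile <- function(traj, system, selection, perResidue = TRUE) {
  idx <- if (is(selection, "AtomGroup")) selection@indices
         else as.integer(selection)
  if (!length(idx)) stop("empty selection", call. = FALSE)
  if (length(traj@frames) < 2L) stop("RMSF needs >= 2 frames",
                                     call. = FALSE)
  sel <- lapply(traj@frames, function(fr) fr[idx, , drop = FALSE])
  refX <- sel[[1L]]
  aligned <- lapply(sel, function(x) .applyFit(x, kabschSuperpose(refX, x)))
  meanX <- Reduce(`+`, aligned) / length(aligned)
  aligned <- lapply(sel, function(x) .applyFit(x, kabschSuperpose(meanX, x)))
  meanX <- Reduce(`+`, aligned) / length(aligned)
  msf <- Reduce(`+`, lapply(aligned, function(x) rowSums((x - meanX)^2))) /
    length(aligned)
  rmsf <- sqrt(msf)
  a <- system@atoms[idx, , drop = FALSE]
  if (!perResidue)
    return(data.frame(atom = idx, author_resid = a$author_resid,
                      residue_name = a$residue_name, rmsf = rmsf))
  agg <- rowsum(rmsf, a$residue_index) / as.vector(table(a$residue_index))
  ri <- as.integer(rownames(agg)) + 1L
  res <- system@residues[ri, , drop = FALSE]
  data.frame(author_resid = res$author_resid,
             residue_name = res$residue_name, rmsf = as.numeric(agg))
}

#' Convert a crystallographic B-factor to an RMSF
#'
#' `RMSF = sqrt(3 B / (8 pi^2))`.
#'
#' @param B temperature factor(s), A^2, `>= 0`.
#' @return RMSF in A
#' @export
bfactorToRmsf <- function(B) {
  if (any(B < 0)) stop("B-factors must be >= 0", call. = FALSE)
  sqrt(3 * B / (8 * pi^2))
}

#' Hydrogen-bond occupancy over a trajectory
#'
#' A donor-hydrogen-acceptor triple satisfies a frame when the donor
#' heavy-atom to acceptor distance is `<= distCut` and the
#' donor-hydrogen-acceptor angle is `>= angleCut`. Occupancy is the fraction
#' of frames satisfied; mean distance and angle are computed over satisfying
#' frames only. Donor-hydrogen pairs default to the system's bond list
#' (hydrogens bonded to N or O); donors without an attached hydrogen are
#' skipped with a warning.
#'
#' @param system the [MolecularSystem].
#' @param traj a [Trajectory].
#' @param acceptors [AtomGroup] or indices of acceptor heavy atoms.
#' @param donors optional data.frame `donor`, `hydrogen` (atom indices);
#'   derived from the bond list when NULL.
#' @param distCut donor-acceptor distance cutoff, A.
#' @param angleCut D-H-A angle cutoff, degrees.
#' @return data.frame: `donor`, `hydrogen`, `acceptor` (atom indices),
#'   `donor_label`, `acceptor_label`, `occupancy`, `mean_distance` (A),
#'   `mean_angle` (deg)
#' @export
hbondOccupancy <- function(system, traj, acceptors, donors = NULL,
                           distCut = 3.5, angleCut = 135) {
  a <- system@atoms
  acc <- if (is(acceptors, "AtomGroup")) acceptors@indices
         else as.integer(acceptors)
  if (is.null(donors)) {
    b <- system@bonds
    isH <- a$element == "H"
    isDon <- a$element %in% c("N", "O")
    d1 <- b[isH[b$j] & isDon[b$i], c("i", "j")]
    d2 <- b[isH[b$i] & isDon[b$j], c("j", "i")]
    names(d1) <- names(d2) <- c("donor", "hydrogen")
    donors <- rbind(d1, d2)
  }
  if (!nrow(donors)) stop("no donor-hydrogen pairs available",
                          call. = FALSE)
  bad <- !donors$hydrogen %in% c(system@bonds$i, system@bonds$j)
  if (any(bad)) {
    warning(sprintf("%d donor(s) without a bonded hydrogen skipped",
                    sum(bad)), call. = FALSE)
    donors <- donors[!bad, , drop = FALSE]
  }
  cand <- expand.grid(pair = seq_len(nrow(donors)), acceptor = acc)
  cand$donor <- donors$donor[cand$pair]
  cand$hydrogen <- donors$hydrogen[cand$pair]
  cand <- cand[cand$donor != cand$acceptor, , drop = FALSE]
  nf <- length(traj@frames)
  hits <- matrix(FALSE, nrow(cand), nf)
  dist <- ang <- matrix(NA_real_, nrow(cand), nf)
  for (f in seq_len(nf)) {
    X <- traj@frames[[f]]
    dv <- X[cand$acceptor, , drop = FALSE] - X[cand$donor, , drop = FALSE]
    d <- sqrt(rowSums(dv^2))
    v1 <- X[cand$donor, , drop = FALSE] - X[cand$hydrogen, , drop = FALSE]
    v2 <- X[cand$acceptor, , drop = FALSE] - X[cand$hydrogen, , drop = FALSE]
    cosA <- rowSums(v1 * v2) /
      (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
    A <- acos(pmin(pmax(cosA, -1), 1)) * 180 / pi
    hits[, f] <- d <= distCut & A >= angleCut
    dist[, f] <- d; ang[, f] <- A
  }
  occ <- rowMeans(hits)
  lab <- function(i) paste0(a$residue_name[i], a$author_resid[i], ":",
                            a$name[i])
  out <- data.frame(donor = cand$donor, hydrogen = cand$hydrogen,
                    acceptor = cand$acceptor,
                    donor_label = lab(cand$donor),
                    acceptor_label = lab(cand$acceptor),
                    occupancy = occ,
                    mean_distance = vapply(seq_len(nrow(cand)), function(r)
                      if (any(hits[r, ])) mean(dist[r, hits[r, ]])
                      else NA_real_, 1.0),
                    mean_angle = vapply(seq_len(nrow(cand)), function(r)
                      if (any(hits[r, ])) mean(ang[r, hits[r, ]])
                      else NA_real_, 1.0))
  rownames(out) <- NULL
  out
}

#' Mass-center distance time series
#'
#' Per-frame Euclidean distance between the centers of mass of two disjoint
#' atom groups (e.g., the junction distance D1 or the pocket distances
#' D2-D7 / T3 of the aptamer).
#'
#' @param system the [MolecularSystem] (masses set).
#' @param traj a [Trajectory].
#' @param groupA,groupB disjoint, non-empty [AtomGroup]s or index vectors.
#' @param label optional series label.
#' @return numeric vector (A) with attributes `mean`, `sd`, `label`
#' @export
distanceSeries <- function(system, traj, groupA, groupB, label = "") {
  ia <- if (is(groupA, "AtomGroup")) groupA@indices else as.integer(groupA)
  ib <- if (is(groupB, "AtomGroup")) groupB@indices else as.integer(groupB)
  if (!length(ia) || !length(ib)) stop("empty group", call. = FALSE)
  if (length(intersect(ia, ib)))
    stop("distance groups must be disjoint", call. = FALSE)
  vals <- vapply(traj@frames, function(fr)
    sqrt(sum((centerOfMass(system, ia, fr) -
              centerOfMass(system, ib, fr))^2)), 1.0)
  structure(vals, mean = mean(vals), sd = stats::sd(vals), label = label)
}
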