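#' @include AllClasses.R
NULL

#' Number of atoms
#' @param x a MolecularSystem, Trajectory or AtomGroup
#' @return integer
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "MolecularSystem", function(x) nrow(x@atoms))

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "Trajectory", function(x) nrow(x@frames[[1L]]))

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "AtomGroup", function(x) length(x@indices))

#' Number of frames in a trajectory
#' @param x a Trajectory
#' @return integer
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname nFrames
#' @export
setMethod("nFrames", "Trajectory", function(x) length(x@frames))

#' Per-atom table of a system
#' @param x a MolecularSystem
#' @return data.frame, one row per atom
#' @export
setGeneric("atomData", function(x) standardGeneric("atomData"))

#' @rdname atomData
#' @export
setMethod("atomData", "MolecularSystem", function(x) x@atoms)

#' Residue table of a system (author numbering preserved)
#' @param x a MolecularSystem
#' @return data.frame: residue_name, author_resid, first, last
#' @export
setGeneric("residueData", function(x) standardGeneric("residueData"))

#' @rdname residueData
#' @export
setMethod("residueData", "MolecularSystem", function(x) x@residues)

#' Extract one coordinate frame
#' @param x a Trajectory
#' @param i frame number (1-based)
#' @return n_atoms x 3 matrix (Angstrom)
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))

#' @rdname getFrame
#' @export
setMethod("getFrame", "Trajectory", function(x, i) x@frames[[i]])

#' Atom indices of a group
#' @param x an AtomGroup
#' @return integer vector (1-based, order preserving)
#' @export
setGeneric("atomIndices", function(x) standardGeneric("atomIndices"))

#' @rdname atomIndices
#' @export
setMethod("atomIndices", "AtomGroup", function(x) x@indices)

#' Net charge of a system
#' @param x a MolecularSystem
#' @return numeric, sum of partial charges (e)
#' @export
setGeneric("netCharge", function(x) standardGeneric("netCharge"))

#' @rdname netCharge
#' @export
setMethod("netCharge", "MolecularSystem", function(x) sum(x@atoms$charge))

#' State percentages of a StateSeries
#' @param x a StateSeries
#' @return named numeric: pct_open, pct_middle, pct_closed (sum to 100)
#' @export
setGeneric("statePercent", function(x) standardGeneric("statePercent"))

#' @rdname statePercent
#' @export
setMethod("statePercent", "StateSeries", function(x) {
  n <- length(x@labels)
  cnt <- table(x@labels)
  c(pct_open = 100 * cnt[["open"]] / n,
    pct_middle = 100 * cnt[["middle"]] / n,
    pct_closed = 100 * cnt[["closed"]] / n)
})

setMethod("show", "MolecularSystem", function(object) {
  a <- object@atoms
  cat("MolecularSystem:", nrow(a), "atoms,", nrow(object@residues),
      "residues,", nrow(object@bonds), "bonds\n")
  cat("  parameters:",
      if (anyNA(a$charge)) "incomplete (run readParameters)" else
        sprintf("complete (net charge %+.4f e)", sum(a$charge)), "\n")
  res <- object@residues
  lab <- paste0(res$residue_name, res$author_resid)
  cat("  residues:", paste(utils::head(lab, 8L), collapse = " "),
      if (nrow(res) > 8L) "..." else "", "\n")
})

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory:", length(object@frames), "frames x",
      nrow(object@frames[[1L]]), "atoms, interval",
      object@frameInterval, "ps, replica", object@replicaId, "\n")
})

setMethod("show", "AtomGroup", function(object) {
  cat("AtomGroup:", length(object@indices), "of", object@nAtomsParent,
      "atoms\n")
})

setMethod("show", "BindingFreeEnergyResult", function(object) {
  cat("MM-GB/SA binding free energy (N =", object@nReplicas, "replicas)\n")
  m <- object@means; s <- object@se
  for (k in names(m))
    cat(sprintf("  %-12s %8.2f %s\n", k, m[[k]],
                if (is.na(s[[k]])) "" else sprintf("+/- %.2f", s[[k]])))
})

setMethod("show", "StateSeries", function(object) {
  p <- statePercent(object)
  cat(sprintf(paste0("StateSeries: %d frames; open %.2f%% / middle %.2f%% /",
                     " closed %.2f%%\n"),
              length(object@labels), p[["pct_open"]], p[["pct_middle"]],
              p[["pct_closed"]]))
  cat(sprintf("  thresholds: closed < %.2f A, open > %.2f A (%s)\n",
              object@closedMax, object@openMin, object@source))
})

setMethod("show", "NormalModeResult", function(object) {
  cat("NormalModeResult:", length(object@frequencies), "real modes,",
      object@nZeroModes, "rigid-body,", object@nImaginary, "imaginary\n")
  if (!is.na(object@Svib))
    cat(sprintf("  S_vib = %.6f kcal/(mol K)\n", object@Svib))
})
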