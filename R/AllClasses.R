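#' @import methods
NULL

## Required columns of the per-atom table of a MolecularSystem. Parameter
## columns (mass .. gb_screen) may be NA on a freshly parsed skeleton and are
## filled by readParameters().
.ATOM_COLS <- c("atom_id", "name", "element", "mass", "charge",
                "lj_rmin_half", "lj_epsilon", "gb_radius", "gb_screen",
                "residue_index", "residue_name", "author_resid", "bfactor")

#' MolecularSystem: atoms, residues, connectivity and force-field parameters
#'
#' The central container of the package: an ordered atom table (names,
#' elements, masses, partial charges, Lennard-Jones `rmin/2` and `epsilon`,
#' generalized-Born intrinsic radii and screening factors), a residue table
#' preserving the author (PDB) residue numbering used in all reports, the
#' bond list, and the 1-2/1-3 exclusion and 1-4 scaled-pair sets derived from
#' it. Coordinates live outside the system, in plain `n x 3` matrices or a
#' [Trajectory].
#'
#' @slot atoms data.frame with one row per atom (see [molecularSystem()]).
#' @slot residues data.frame: `residue_name`, `author_resid`, `first`, `last`
#'   (1-based atom index range).
#' @slot bonds data.frame: `i`, `j` (atom indices), `k` (force constant,
#'   kcal/(mol A^2), for the harmonic form `k/2 (r - r0)^2`), `r0` (A).
#' @slot exclusions integer matrix, two columns, each row a 1-2 or 1-3 pair
#'   excluded from nonbonded sums.
#' @slot pairs14 data.frame: `i`, `j`, `ele_scale`, `vdw_scale` for pairs
#'   three bonds apart.
#' @export
setClass("MolecularSystem",
  representation(atoms = "data.frame", residues = "data.frame",
                 bonds = "data.frame", exclusions = "matrix",
                 pairs14 = "data.frame"))

setValidity("MolecularSystem", function(object) {
  a <- object@atoms
  miss <- setdiff(.ATOM_COLS, names(a))
  if (length(miss)) return(paste("atom table lacks columns:",
                                 paste(miss, collapse = ", ")))
  n <- nrow(a)
  if (n < 1L) return("system must contain at least one atom")
  if (any(!is.na(a$mass) & a$mass <= 0)) return("atom masses must be > 0")
  if (any(!is.na(a$lj_rmin_half) & a$lj_rmin_half < 0))
    return("lj_rmin_half must be >= 0")
  if (any(!is.na(a$lj_epsilon) & a$lj_epsilon < 0))
    return("lj_epsilon must be >= 0")
  if (any(!is.na(a$gb_radius) & a$gb_radius <= 0))
    return("gb_radius must be > 0")
  idx <- c(object@exclusions, object@pairs14$i, object@pairs14$j,
           object@bonds$i, object@bonds$j)
  if (length(idx) && (any(idx < 1L) || any(idx > n)))
    return("atom index out of range in bonds/exclusions/1-4 pairs")
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  exk <- if (nrow(object@exclusions)) key(object@exclusions[, 1],
                                          object@exclusions[, 2]) else character()
  p14 <- if (nrow(object@pairs14)) key(object@pairs14$i, object@pairs14$j)
         else character()
  if (length(intersect(exk, p14)))
    return("exclusion and 1-4 pair sets must be disjoint")
  if (nrow(object@bonds)) {
    bk <- key(object@bonds$i, object@bonds$j)
    if (!all(bk %in% exk))
      return("every bonded pair must appear in the exclusion set")
  }
  TRUE
})

#' Trajectory: ordered coordinate frames at a fixed recording interval
#'
#' @slot frames list of `n_atoms x 3` numeric matrices (Angstrom).
#' @slot frameInterval numeric, spacing between stored frames in ps.
#' @slot replicaId integer tag for multi-replica bookkeeping.
#' @export
setClass("Trajectory",
  representation(frames = "list", frameInterval = "numeric",
                 replicaId = "integer"),
  prototype(frameInterval = 10, replicaId = 1L))

setValidity("Trajectory", function(object) {
  if (!length(object@frames)) return("trajectory must contain >= 1 frame")
  nc <- vapply(object@frames, nrow, 1L)
  if (length(unique(nc)) != 1L)
    return("all frames must have the same atom count")
  if (any(vapply(object@frames, ncol, 1L) != 3L))
    return("frames must be n x 3 matrices")
  if (object@frameInterval <= 0) return("frameInterval must be > 0")
  TRUE
})

#' AtomGroup: an ordered subset of a system's atoms
#'
#' @slot indices integer vector of 1-based atom indices, unique, file order.
#' @slot nAtomsParent integer, atom count of the parent system (for
#'   validation).
#' @export
setClass("AtomGroup",
  representation(indices = "integer", nAtomsParent = "integer"))

setValidity("AtomGroup", function(object) {
  i <- object@indices
  if (anyDuplicated(i)) return("atom indices must be unique")
  if (length(i) && (any(i < 1L) || any(i > object@nAtomsParent)))
    return("atom index out of range")
  TRUE
})

#' Parameters of the implicit-solvent energy model
#'
#' Defaults follow standard implicit-solvent post-processing practice:
#' Coulomb constant 332.0637 kcal A/(mol e^2), interior/solvent dielectrics
#' 1/80, nonpolar surface coefficient gamma = 0.00542 kcal/(mol A^2) with
#' offset beta = 0.92 kcal/mol, probe radius 1.4 A, 960 sphere points for the
#' Shrake-Rupley surface, AMBER-style 1-4 scalings (electrostatics 1/1.2,
#' Lennard-Jones 1/2), and OBC-II Born-radius rescaling (alpha 1, beta 0.8,
#' gamma 4.85, dielectric offset 0.09 A).
#'
#' @slot coulombK numeric. @slot dielectricIn numeric. @slot dielectricOut
#'   numeric. @slot gamma numeric. @slot betaConst numeric. @slot probeRadius
#'   numeric. @slot sasaPoints integer. @slot ele14Scale numeric.
#'   @slot vdw14Scale numeric. @slot obcAlpha numeric. @slot obcBeta numeric.
#'   @slot obcGamma numeric. @slot gbOffset numeric.
#' @export
setClass("EnergyModelParams",
  representation(coulombK = "numeric", dielectricIn = "numeric",
                 dielectricOut = "numeric", gamma = "numeric",
                 betaConst = "numeric", probeRadius = "numeric",
                 sasaPoints = "integer", ele14Scale = "numeric",
                 vdw14Scale = "numeric", obcAlpha = "numeric",
                 obcBeta = "numeric", obcGamma = "numeric",
                 gbOffset = "numeric"),
  prototype(coulombK = 332.0637, dielectricIn = 1, dielectricOut = 80,
            gamma = 0.00542, betaConst = 0.92, probeRadius = 1.4,
            sasaPoints = 960L, ele14Scale = 1 / 1.2, vdw14Scale = 0.5,
            obcAlpha = 1.0, obcBeta = 0.8, obcGamma = 4.85,
            gbOffset = 0.09))

setValidity("EnergyModelParams", function(object) {
  if (object@dielectricIn <= 0 || object@dielectricOut <= 0)
    return("dielectrics must be > 0")
  if (object@sasaPoints < 92L) return("sasaPoints must be >= 92")
  if (object@gamma < 0) return("gamma must be >= 0")
  TRUE
})

#' Replica-aggregated MM-GB/SA binding free energy
#'
#' Houses the mean of every component over replicas, the derived sums, and
#' the per-term standard error sigma = sd(replica means)/sqrt(N).
#'
#' @slot means named numeric: `dEele`, `dEvdw`, `dEint`, `dGpol`, `dGnonpol`,
#'   `dGelepol`, `dGvdwnonpol`, `dH`, `TdS`, `dGbind` (kcal/mol).
#' @slot se named numeric, same names (kcal/mol); NA where undefined.
#' @slot nReplicas integer.
#' @export
setClass("BindingFreeEnergyResult",
  representation(means = "numeric", se = "numeric", nReplicas = "integer"))

setValidity("BindingFreeEnergyResult", function(object) {
  need <- c("dEele", "dEvdw", "dEint", "dGpol", "dGnonpol", "dGelepol",
            "dGvdwnonpol", "dH", "TdS", "dGbind")
  if (!all(need %in% names(object@means)))
    return("means must contain every energy term")
  m <- object@means
  if (abs(m["dH"] - (m["dEele"] + m["dEvdw"] + m["dEint"] +
                     m["dGpol"] + m["dGnonpol"])) > 1e-9)
    return("dH must equal the sum of its five components")
  if (abs(m["dGbind"] - (m["dH"] - m["TdS"])) > 1e-9)
    return("dGbind must equal dH - TdS")
  TRUE
})

#' Per-frame open/middle/closed state labels with their thresholds
#'
#' @slot labels factor with levels `closed`, `middle`, `open`.
#' @slot closedMax numeric (A): below it the frame is closed.
#' @slot openMin numeric (A): above it the frame is open.
#' @slot source character, `"derived"` or `"configured"`.
#' @export
setClass("StateSeries",
  representation(labels = "factor", closedMax = "numeric",
                 openMin = "numeric", source = "character"),
  prototype(source = "configured"))

setValidity("StateSeries", function(object) {
  if (!identical(levels(object@labels), c("closed", "middle", "open")))
    return("labels must have levels closed/middle/open")
  if (object@closedMax >= object@openMin)
    return("closedMax must be < openMin")
  TRUE
})

#' Harmonic normal-mode result
#'
#' @slot frequencies numeric, nonzero real frequencies in cm^-1, ascending.
#' @slot nZeroModes integer, rigid-body modes removed (6 nonlinear, 5 linear).
#' @slot nImaginary integer, modes with eigenvalue < 0 beyond the threshold.
#' @slot Svib numeric, vibrational entropy in kcal/(mol K) (NA until set).
#' @slot minimizedEnergy numeric, energy at the analysed geometry (kcal/mol).
#' @slot gradientRms numeric, RMS gradient at convergence (kcal/(mol A)).
#' @export
setClass("NormalModeResult",
  representation(frequencies = "numeric", nZeroModes = "integer",
                 nImaginary = "integer", Svib = "numeric",
                 minimizedEnergy = "numeric", gradientRms = "numeric"),
  prototype(Svib = NA_real_, minimizedEnergy = NA_real_,
            gradientRms = NA_real_))
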