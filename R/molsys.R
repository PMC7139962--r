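#' @include AllClasses.R selection.R
NULL

## ---- construction -----------------------------------------------------

.emptyExclusions <- function() matrix(integer(), ncol = 2L)

.emptyPairs14 <- function()
  data.frame(i = integer(), j = integer(),
             ele_scale = numeric(), vdw_scale = numeric())

## Walk the bond graph to derive 1-2/1-3 exclusions and 1-4 scaled pairs.
.connectivity <- function(n, bonds, ele14Scale, vdw14Scale) {
  if (is.null(bonds) || nrow(bonds) == 0L)
    return(list(exclusions = .emptyExclusions(), pairs14 = .emptyPairs14()))
  adj <- vector("list", n)
  for (b in seq_len(nrow(bonds))) {
    i <- bonds$i[b]; j <- bonds$j[b]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  ex <- rbind(as.matrix(bonds[, c("i", "j")]))
  ## 1-3: two bonds apart
  for (j in seq_len(n)) {
    nb <- adj[[j]]
    if (length(nb) >= 2L) {
      cp <- t(utils::combn(nb, 2L))
      ex <- rbind(ex, cp)
    }
  }
  ex <- ex[!duplicated(key(ex[, 1], ex[, 2])) & ex[, 1] != ex[, 2], ,
           drop = FALSE]
  exk <- key(ex[, 1], ex[, 2])
  ## 1-4: three bonds apart, not already excluded
  p14 <- matrix(integer(), ncol = 2L)
  for (b in seq_len(nrow(bonds))) {
    i <- bonds$i[b]; j <- bonds$j[b]
    for (a in setdiff(adj[[i]], j)) for (d in setdiff(adj[[j]], i))
      if (a != d) p14 <- rbind(p14, c(min(a, d), max(a, d)))
  }
  if (nrow(p14)) {
    p14 <- p14[!duplicated(key(p14[, 1], p14[, 2])), , drop = FALSE]
    p14 <- p14[!(key(p14[, 1], p14[, 2]) %in% exk), , drop = FALSE]
  }
  list(exclusions = matrix(as.integer(ex), ncol = 2L),
       pairs14 = if (nrow(p14))
         data.frame(i = as.integer(p14[, 1]), j = as.integer(p14[, 2]),
                    ele_scale = ele14Scale, vdw_scale = vdw14Scale)
       else .emptyPairs14())
}

.residueTable <- function(atoms) {
  brk <- cumsum(c(1L, as.integer(diff(atoms$residue_index) != 0)))
  first <- which(!duplicated(brk))
  last <- c(first[-1L] - 1L, nrow(atoms))
  data.frame(residue_name = atoms$residue_name[first],
             author_resid = atoms$author_resid[first],
             first = first, last = last)
}

#' Construct a MolecularSystem from an atom table
#'
#' @param atoms data.frame with at least `name`, `residue_name`,
#'   `author_resid` columns; parameter columns (`mass`, `charge`,
#'   `lj_rmin_half`, `lj_epsilon`, `gb_radius`, `gb_screen`) and `element`,
#'   `bfactor`, `atom_id`, `residue_index` are filled with defaults/NA when
#'   absent.
#' @param bonds optional data.frame `i`, `j`, `k`, `r0` (harmonic bonds,
#'   `k/2 (r-r0)^2`, kcal/(mol A^2), A). The 1-2/1-3 exclusion list and 1-4
#'   scaled pairs are derived from the bond graph.
#' @param ele14Scale,vdw14Scale scale factors stored on derived 1-4 pairs.
#' @return a [MolecularSystem]
#' @export
molecularSystem <- function(atoms, bonds = NULL,
                            ele14Scale = 1 / 1.2, vdw14Scale = 0.5) {
  atoms <- as.data.frame(atoms)
  n <- nrow(atoms)
  if (is.null(atoms$atom_id)) atoms$atom_id <- seq_len(n)
  if (is.null(atoms$residue_index)) {
    ids <- paste(atoms$residue_name, atoms$author_resid)
    atoms$residue_index <- cumsum(c(1L, as.integer(
      ids[-1L] != ids[-length(ids)]))) - 1L
  }
  if (is.null(atoms$element)) atoms$element <- .inferElement(atoms$name)
  for (col in c("mass", "charge", "lj_rmin_half", "lj_epsilon",
                "gb_radius", "gb_screen", "bfactor"))
    if (is.null(atoms[[col]])) atoms[[col]] <- NA_real_
  atoms <- atoms[, .ATOM_COLS]
  if (!is.null(bonds)) {
    bonds <- as.data.frame(bonds)
    stopifnot(all(c("i", "j", "k", "r0") %in% names(bonds)))
  } else {
    bonds <- data.frame(i = integer(), j = integer(), k = numeric(),
                        r0 = numeric())
  }
  conn <- .connectivity(n, bonds, ele14Scale, vdw14Scale)
  new("MolecularSystem", atoms = atoms, residues = .residueTable(atoms),
      bonds = bonds, exclusions = conn$exclusions, pairs14 = conn$pairs14)
}

## Element from a PDB atom name: strip leading digits, take the first
## alphabetic character (adequate for organic/RNA atoms; an explicit element
## column always wins).
.inferElement <- function(names) {
  toupper(substr(gsub("^[0-9]+", "", names), 1L, 1L))
}

## ---- PDB I/O ----------------------------------------------------------

.asLines <- function(input) {
  if (length(input) == 1L && !grepl("\n", input) && file.exists(input))
    return(readLines(input, warn = FALSE))
  if (length(input) == 1L) return(strsplit(input, "\n")[[1L]])
  input
}

## Pre-scan of PDB text: locate ATOM/HETATM records, enforce the package's
## dialect (parsable coordinates, altloc '' or 'A' only), and split models.
.scanPDB <- function(lines) {
  rec <- substr(lines, 1, 6)
  isAtom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(isAtom))
    stop("PDB format error: no ATOM/HETATM records found", call. = FALSE)
  for (ln in which(isAtom)) {
    l <- lines[ln]
    if (nchar(l) < 54)
      stop(sprintf("PDB format error at line %d: record too short", ln),
           call. = FALSE)
    xyz <- suppressWarnings(as.numeric(c(substr(l, 31, 38),
                                         substr(l, 39, 46),
                                         substr(l, 47, 54))))
    if (anyNA(xyz))
      stop(sprintf("PDB format error at line %d: unparsable coordinates",
                   ln), call. = FALSE)
    alt <- substr(l, 17, 17)
    if (!alt %in% c(" ", "", "A"))
      stop(sprintf("PDB format error at line %d: altloc '%s' not supported",
                   ln, alt), call. = FALSE)
  }
  modelStarts <- which(rec == "MODEL ")
  nModels <- max(1L, length(modelStarts))
  ## per-model atom counts (single implicit model when no MODEL cards)
  if (length(modelStarts)) {
    modelId <- findInterval(seq_along(lines), modelStarts)
    counts <- tabulate(modelId[isAtom], nbins = length(modelStarts))
  } else counts <- sum(isAtom)
  list(nModels = nModels, atomCounts = counts)
}

## Shared reader: bio3d does the parsing; the pre-scan enforces dialect.
.readPDBmulti <- function(lines, multi) {
  f <- tempfile(fileext = ".pdb")
  on.exit(unlink(f))
  writeLines(lines, f)
  bio3d::read.pdb(f, multi = multi, verbose = FALSE)
}

.systemFromBio3d <- function(pdb) {
  at <- pdb$atom
  elem <- at$elesy
  blank <- is.na(elem) | !nzchar(trimws(elem))
  elem[blank] <- .inferElement(at$elety[blank])
  atoms <- data.frame(atom_id = at$eleno, name = at$elety,
                      element = trimws(elem),
                      residue_name = at$resid, author_resid = at$resno,
                      bfactor = at$b)
  ## residue breaks must honour chain as well as author number
  ids <- paste(at$chain, at$resno, at$resid)
  atoms$residue_index <- cumsum(c(1L, as.integer(
    ids[-1L] != ids[-length(ids)]))) - 1L
  molecularSystem(atoms)
}

#' Read a PDB structure (first model)
#'
#' Accepts a file path or PDB text. ATOM and HETATM records are both kept;
#' author residue numbers and B-factors are preserved; alternate locations
#' other than ''/'A' are rejected. If the file holds several models, only
#' model 1 is returned, with a warning (use [readTrajectory()] for all
#' models).
#'
#' @param input path or character (single string or vector of lines).
#' @return list with `system` (a [MolecularSystem] skeleton, parameters NA
#'   until [readParameters()]) and `frame` (n x 3 coordinate matrix, A).
#' @export
readPDB <- function(input) {
  lines <- .asLines(input)
  scan <- .scanPDB(lines)
  if (scan$nModels > 1L)
    warning(sprintf("file contains %d models; returning model 1 only",
                    scan$nModels), call. = FALSE)
  pdb <- .readPDBmulti(lines, multi = FALSE)
  sys <- .systemFromBio3d(pdb)
  frame <- matrix(pdb$xyz[1, ], ncol = 3L, byrow = TRUE)
  list(system = sys, frame = frame)
}

#' Read a multi-model PDB as a trajectory
#'
#' One frame per MODEL block (a file without MODEL cards yields a one-frame
#' trajectory). Models must agree in atom count.
#'
#' @param input path or PDB text.
#' @param frameInterval spacing between stored frames, ps.
#' @param replicaId integer replica tag.
#' @return a [Trajectory]
#' @export
readTrajectory <- function(input, frameInterval = 10, replicaId = 1L) {
  lines <- .asLines(input)
  scan <- .scanPDB(lines)
  if (length(unique(scan$atomCounts)) != 1L)
    stop(sprintf("structural mismatch: models differ in atom count (%s)",
                 paste(unique(scan$atomCounts), collapse = " vs ")),
         call. = FALSE)
  pdb <- .readPDBmulti(lines, multi = scan$nModels > 1L)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  frames <- lapply(seq_len(nrow(xyz)), function(i)
    matrix(xyz[i, ], ncol = 3L, byrow = TRUE))
  new("Trajectory", frames = frames, frameInterval = frameInterval,
      replicaId = as.integer(replicaId))
}

#' Write coordinates as a (multi-model) PDB file
#'
#' @param system a [MolecularSystem].
#' @param frames a single n x 3 matrix, a list of them, or a [Trajectory].
#' @param file output path.
#' @return invisibly, the path
#' @export
writePDB <- function(system, frames, file) {
  if (is(frames, "Trajectory")) frames <- frames@frames
  if (is.matrix(frames)) frames <- list(frames)
  xyz <- do.call(rbind, lapply(frames, function(f) as.numeric(t(f))))
  a <- system@atoms
  b <- ifelse(is.na(a$bfactor), 0, a$bfactor)
  bio3d::write.pdb(pdb = NULL, file = file, xyz = xyz, resno = a$author_resid,
                   resid = a$residue_name, eleno = a$atom_id, elety = a$name,
                   b = b)
  invisible(file)
}

## ---- parameter tables -------------------------------------------------

#' Load per-atom force-field parameters from a TSV table
#'
#' The table is tab-separated with header columns `atom_key`, `mass`,
#' `charge`, `rmin_half`, `epsilon`, `gb_radius`, `gb_screen`. `atom_key` is
#' either `RESNAME:ATOMNAME` or a bare atom id; every atom of the system must
#' be covered.
#'
#' @param system a [MolecularSystem] skeleton.
#' @param file path to the TSV parameter table (or its text).
#' @return the system with parameters populated; the net charge is reported
#'   with a message.
#' @export
readParameters <- function(system, file) {
  lines <- .asLines(file)
  tab <- utils::read.table(text = lines, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  need <- c("atom_key", "mass", "charge", "rmin_half", "epsilon",
            "gb_radius", "gb_screen")
  if (!all(need %in% names(tab)))
    stop("parameter table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  tab$atom_key <- as.character(tab$atom_key)
  if (anyDuplicated(tab$atom_key)) {
    dup <- unique(tab$atom_key[duplicated(tab$atom_key)])
    conflict <- vapply(dup, function(k) {
      sub <- tab[tab$atom_key == k, need[-1L]]
      nrow(unique(sub)) > 1L
    }, logical(1))
    if (any(conflict))
      stop("parameterization error: conflicting duplicate keys: ",
           paste(dup[conflict], collapse = ", "), call. = FALSE)
    tab <- tab[!duplicated(tab$atom_key), ]
  }
  a <- system@atoms
  keyName <- paste0(a$residue_name, ":", a$name)
  keyId <- as.character(a$atom_id)
  row <- match(keyName, tab$atom_key)
  row[is.na(row)] <- match(keyId, tab$atom_key)[is.na(row)]
  if (anyNA(row))
    stop("parameterization error: no parameters for atoms: ",
         paste(unique(keyName[is.na(row)]), collapse = ", "), call. = FALSE)
  a$mass <- tab$mass[row]
  a$charge <- tab$charge[row]
  a$lj_rmin_half <- tab$rmin_half[row]
  a$lj_epsilon <- tab$epsilon[row]
  a$gb_radius <- tab$gb_radius[row]
  a$gb_screen <- tab$gb_screen[row]
  system@atoms <- a
  validObject(system)
  message(sprintf("parameters loaded for %d atoms; net charge %+.6f e",
                  nrow(a), sum(a$charge)))
  system
}

#' Write the per-atom table as TSV
#' @param system a [MolecularSystem].
#' @param file output path.
#' @return invisibly, the path
#' @export
writeAtomTable <- function(system, file) {
  utils::write.table(system@atoms, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

## ---- geometry helpers on systems --------------------------------------

#' Center of mass of an atom group
#'
#' @param system a [MolecularSystem] with masses populated.
#' @param group an [AtomGroup] (or integer indices).
#' @param frame n x 3 coordinate matrix for the whole system.
#' @return length-3 numeric (A)
#' @export
centerOfMass <- function(system, group, frame) {
  idx <- if (is(group, "AtomGroup")) group@indices else as.integer(group)
  if (!length(idx)) stop("center of mass of an empty group", call. = FALSE)
  m <- system@atoms$mass[idx]
  if (anyNA(m)) stop("masses are not set; load parameters first",
                     call. = FALSE)
  M <- sum(m)
  if (M <= 0) stop("zero total mass", call. = FALSE)
  colSums(frame[idx, , drop = FALSE] * m) / M
}

#' Extract a self-contained subsystem
#'
#' Atoms are reindexed 1..k in the original order; bonds, exclusions and 1-4
#' pairs internal to the subset are remapped, pairs crossing the boundary are
#' dropped.
#'
#' @param system a [MolecularSystem].
#' @param group an [AtomGroup] or integer indices.
#' @return a [MolecularSystem]
#' @export
subsetSystem <- function(system, group) {
  idx <- if (is(group, "AtomGroup")) group@indices else as.integer(group)
  idx <- sort(idx)
  map <- integer(nrow(system@atoms)); map[idx] <- seq_along(idx)
  a <- system@atoms[idx, , drop = FALSE]
  rownames(a) <- NULL
  keep2 <- function(i, j) i %in% idx & j %in% idx
  b <- system@bonds[keep2(system@bonds$i, system@bonds$j), , drop = FALSE]
  if (nrow(b)) { b$i <- map[b$i]; b$j <- map[b$j] }
  sub <- molecularSystem(a, bonds = if (nrow(b)) b else NULL)
  sub
}
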