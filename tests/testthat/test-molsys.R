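pdbLine <- function(serial, name, resname, resid, x, y, z, b = 0,
                    record = "ATOM") {
  sprintf("%-6s%5d %-4s %-4s%5d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          record, serial, name, resname, resid, x, y, z, 1, b)
}

test_that("a single ATOM record parses to one atom at the stated position", {
  txt <- pdbLine(1, "C1", "LIG", 1, 1.234, 2.345, 3.456, b = 12.5)
  out <- readPDB(txt)
  expect_equal(nAtoms(out$system), 1L)
  expect_equal(as.numeric(out$frame), c(1.234, 2.345, 3.456))
  expect_equal(atomData(out$system)$bfactor, 12.5)
  expect_equal(atomData(out$system)$author_resid, 1L)
})

test_that("multi-model input to readPDB keeps model 1 with a warning", {
  txt <- c("MODEL        1",
           pdbLine(1, "C1", "LIG", 1, 0, 0, 0),
           "ENDMDL",
           "MODEL        2",
           pdbLine(1, "C1", "LIG", 1, 9, 9, 9),
           "ENDMDL")
  expect_warning(out <- readPDB(txt), "model 1")
  expect_equal(as.numeric(out$frame), c(0, 0, 0))
})

test_that("degenerate PDB inputs raise format errors", {
  expect_error(readPDB("REMARK nothing here"), "no ATOM/HETATM")
  expect_error(readPDB("ATOM      1  C1  LIG     1      bad coords"),
               "line 1")
})

test_that("multi-model trajectories load frame-per-model in file order", {
  mdl <- function(k, x) c(sprintf("MODEL %8d", k),
                          pdbLine(1, "C1", "LIG", 1, x, 0, 0),
                          pdbLine(2, "O1", "LIG", 1, x + 1.5, 0, 0),
                          "ENDMDL")
  traj <- readTrajectory(c(mdl(1, 0), mdl(2, 1), mdl(3, 2)))
  expect_equal(nFrames(traj), 3L)
  expect_equal(getFrame(traj, 3)[1, 1], 2)
  single <- readTrajectory(c(pdbLine(1, "C1", "LIG", 1, 0, 0, 0)))
  expect_equal(nFrames(single), 1L)
  bad <- c("MODEL        1",
           pdbLine(1, "C1", "LIG", 1, 0, 0, 0),
           pdbLine(2, "O1", "LIG", 1, 1, 0, 0),
           "ENDMDL", "MODEL        2",
           pdbLine(1, "C1", "LIG", 1, 0, 0, 0),
           "ENDMDL")
  expect_error(readTrajectory(bad), "mismatch")
})

test_that("PDB round-trip preserves coordinates to PDB precision", {
  toy <- makeToySystem(nAtoms = 6, nLigandAtoms = 2, seed = 5)
  f <- tempfile(fileext = ".pdb")
  writePDB(toy$system, list(toy$frame, toy$frame + 0.25), f)
  back <- readTrajectory(f)
  expect_equal(nFrames(back), 2L)
  expect_equal(getFrame(back, 1), toy$frame, tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_equal(getFrame(back, 2), toy$frame + 0.25, tolerance = 1e-3,
               ignore_attr = TRUE)
  sys2 <- suppressWarnings(readPDB(f))$system
  expect_equal(atomData(sys2)$author_resid,
               atomData(toy$system)$author_resid)
})

test_that("parameter tables populate atoms and report net charge", {
  toy <- makeToySystem(nAtoms = 5, nLigandAtoms = 2, seed = 2,
                       netCharge = -1)
  f <- tempfile(fileext = ".tsv")
  writeParameterTable(toy$system, f)
  skel <- toy$system
  skel@atoms$charge <- NA_real_
  skel@atoms$mass <- NA_real_
  expect_message(sys <- readParameters(skel, f), "net charge")
  expect_equal(netCharge(sys), -1, tolerance = 1e-9)
  expect_equal(atomData(sys)$mass, atomData(toy$system)$mass)

  ## missing atom named in the error
  tab <- read.table(f, header = TRUE, sep = "\t")
  miss <- tempfile(fileext = ".tsv")
  write.table(tab[-1, ], miss, sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(readParameters(skel, miss), tab$atom_key[1])

  ## conflicting duplicate key rejected
  dup <- rbind(tab, transform(tab[1, ], charge = charge + 1))
  dupf <- tempfile(fileext = ".tsv")
  write.table(dup, dupf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readParameters(skel, dupf), "conflicting")
})

test_that("selection grammar handles lists, boolean operators and misses", {
  atoms <- beadAtoms(6,
                     name = c("P", "C4'", "O3'", "P", "C4'", "N1"),
                     resIndex = c(0L, 0L, 0L, 1L, 1L, 1L),
                     resName = c(rep("U", 3), rep("A", 3)),
                     authorResid = c(51L, 51L, 51L, 74L, 74L, 74L))
  sys <- molecularSystem(atoms)
  expect_equal(atomIndices(selectAtoms(sys, "resid 51 74 and name P")),
               c(1L, 4L))
  expect_equal(atomIndices(selectAtoms(sys, "name P O3' C4'")),
               c(1L, 2L, 3L, 4L, 5L))
  expect_equal(atomIndices(selectAtoms(sys, "resname A and not name P")),
               c(5L, 6L))
  expect_equal(atomIndices(selectAtoms(sys, "name N1 or name O3'")),
               c(3L, 6L))
  expect_warning(g <- selectAtoms(sys, "resid 999"), "no atoms")
  expect_equal(nAtoms(g), 0L)
  expect_error(selectAtoms(sys, "name P and"), "parse error")
})

test_that("selection is idempotent and intersection-distributive", {
  toy <- makeToySystem(nAtoms = 9, nLigandAtoms = 3, seed = 4)
  sys <- toy$system
  a <- atomIndices(selectAtoms(sys, "resname LIG"))
  expect_identical(a, atomIndices(selectAtoms(sys, "resname LIG")))
  both <- atomIndices(selectAtoms(sys, "resname LIG and resid 1 3"))
  expect_identical(both,
                   intersect(a, atomIndices(selectAtoms(sys, "resid 1 3"))))
})

test_that("center of mass is mass-weighted and translation-equivariant", {
  sys <- beadSystem(2, mass = c(1, 1))
  X <- rbind(c(0, 0, 0), c(2, 0, 0))
  expect_equal(centerOfMass(sys, 1:2, X), c(1, 0, 0))
  expect_equal(centerOfMass(sys, 1L, X), c(0, 0, 0))
  sys13 <- beadSystem(2, mass = c(1, 3))
  X2 <- rbind(c(0, 0, 0), c(4, 0, 0))
  expect_equal(centerOfMass(sys13, 1:2, X2), c(3, 0, 0))
  t <- c(5, -2, 7)
  expect_equal(centerOfMass(sys13, 1:2, sweep(X2, 2, t, "+")),
               centerOfMass(sys13, 1:2, X2) + t)
  expect_error(centerOfMass(sys, integer(), X), "empty")
})

test_that("system validity enforces connectivity invariants", {
  expect_error(molecularSystem(within(beadAtoms(2), mass <- -1)), "mass")
  sys <- beadSystem(4, bonds = data.frame(i = 1:3, j = 2:4, k = 100,
                                          r0 = 1.5))
  key <- function(m) paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
  expect_true(all(key(as.matrix(sys@bonds[, c("i", "j")])) %in%
                  key(sys@exclusions)))
  ## 1-4 pair of the chain, disjoint from exclusions
  expect_equal(nrow(sys@pairs14), 1L)
  expect_equal(c(sys@pairs14$i, sys@pairs14$j), c(1L, 4L))
})
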