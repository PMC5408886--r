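test_that("altloc resolution keeps the highest-occupancy copy, ties to A", {
  path <- writePdbFixture(c(
    pdbLine("ATOM", 1, "CA", "A", "ALA", "A", 1, 0, 0, 0, occ = 0.6),
    pdbLine("ATOM", 2, "CA", "B", "ALA", "A", 1, 5, 0, 0, occ = 0.4),
    pdbLine("ATOM", 3, "CB", "B", "ALA", "A", 1, 1, 0, 0, occ = 0.5),
    pdbLine("ATOM", 4, "CB", "A", "ALA", "A", 1, 2, 0, 0, occ = 0.5)))
  atoms <- readStructure(path, c(A = 0))
  ca <- atoms[atoms$elety == "CA", ]
  expect_equal(nrow(ca), 1L)
  expect_equal(ca$x, 0)          # occupancy 0.6 wins
  cb <- atoms[atoms$elety == "CB", ]
  expect_equal(cb$alt, "A")      # occupancy tie falls to altloc A
  expect_equal(cb$x, 2)
})

test_that("hydrogens are dropped and offsets map author numbering", {
  path <- writePdbFixture(c(
    pdbLine("ATOM", 1, "CA", " ", "ALA", "A", 101, 0, 0, 0),
    pdbLine("ATOM", 2, "HA", " ", "ALA", "A", 101, 1, 0, 0, element = "H"),
    pdbLine("ATOM", 3, "CA", " ", "GLY", "B", 12, 3, 0, 0)))
  atoms <- readStructure(path, c(A = -86))
  expect_equal(nrow(atoms), 2L)  # H gone
  expect_equal(atoms$seq_index[atoms$chain == "A"], 15L)
  expect_true(is.na(atoms$seq_index[atoms$chain == "B"]))  # no offset given
  expect_error(readStructure(path, c(Q = 0)), "unknown chain")
  expect_error(readStructure(tempfile(), c(A = 0)), "cannot read")
})

test_that("contact rule is inclusive at the cutoff and skips backbone", {
  # ligand atom at the origin; side chains at 4.9 / 5.0 / 5.1 A
  atoms <- rbind(
    atomRow("ATOM", "A", 15, "PHE", "CA", 20, 0, 0),
    atomRow("ATOM", "A", 15, "PHE", "CG", 4.9, 0, 0),
    atomRow("ATOM", "A", 16, "PHE", "CA", 20, 2, 0),
    atomRow("ATOM", "A", 16, "PHE", "CG", 5.0, 0, 0),
    atomRow("ATOM", "A", 17, "PHE", "CA", 20, 4, 0),
    atomRow("ATOM", "A", 17, "PHE", "CG", 5.1, 0, 0),
    # backbone oxygen right on the ligand must not count
    atomRow("ATOM", "A", 18, "PHE", "O", 0.5, 0, 0),
    atomRow("ATOM", "A", 18, "PHE", "CA", 20, 6, 0),
    atomRow("HETATM", "X", 900, "LIG", "C1", 0, 0, 0))
  cs <- contactPositions(atoms, list(het_code = "LIG"), tm6Annotation(),
                         cutoff = 5.0, structureId = "fix")
  expect_equal(sitePositions(cs), c("6x50", "6x51"))
  expect_equal(contactTable(cs)$min_dist, c(4.9, 5.0))
})

test_that("glycine is testable through its C-alpha", {
  atoms <- rbind(
    atomRow("ATOM", "A", 15, "GLY", "CA", 4.0, 0, 0),
    atomRow("ATOM", "A", 15, "GLY", "N", 10, 0, 0),
    atomRow("ATOM", "A", 16, "GLY", "CA", 9, 0, 0),
    atomRow("HETATM", "X", 900, "LIG", "C1", 0, 0, 0))
  cs <- contactPositions(atoms, list(het_code = "LIG"), tm6Annotation())
  expect_equal(sitePositions(cs), "6x50")
})

test_that("unmappable in-contact residues are reported, not dropped", {
  atoms <- rbind(
    atomRow("ATOM", "A", 15, "PHE", "CB", 3, 0, 0),
    atomRow("ATOM", "A", 2, "PHE", "CB", 3, 1, 0),  # seq 2: outside segments
    atomRow("HETATM", "X", 900, "LIG", "C1", 0, 0, 0))
  expect_warning(
    cs <- contactPositions(atoms, list(het_code = "LIG"), tm6Annotation()),
    "no generic position")
  expect_equal(sitePositions(cs), "6x50")
  expect_equal(cs@unmapped$seq_index, 2L)
  expect_error(contactPositions(atoms, list(het_code = "XYZ"),
                                tm6Annotation()), "not found")
})

test_that("contact sets grow monotonically with the cutoff", {
  spec <- smallSpec(seed = 3)
  rs <- makeReceptorSet(spec)
  ann <- rs$annotations[[1]]
  path <- tempfile(fileext = ".pdb")
  makeComplex(spec, ann, spec$sitePositions, path)
  atoms <- readStructure(path, c(A = 0))
  prev <- character(0)
  for (cut in c(3, 4.5, 5, 6, 8)) {
    cur <- sitePositions(contactPositions(atoms, list(het_code = "LIG"),
                                          ann, cutoff = cut))
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("contact extraction matches the brute-force all-pairs oracle", {
  for (seed in 1:4) {
    spec <- smallSpec(seed = seed)
    rs <- makeReceptorSet(spec)
    ann <- rs$annotations[[seed %% length(rs$annotations) + 1L]]
    planted <- sample(spec$sitePositions, 3)
    path <- tempfile(fileext = ".pdb")
    makeComplex(spec, ann, planted, path, seed = seed)
    atoms <- readStructure(path, c(A = 0))
    cs <- contactPositions(atoms, list(het_code = "LIG"), ann)
    expect_equal(sitePositions(cs),
                 bruteContacts(atoms, "LIG", ann, 5.0))
    expect_equal(sitePositions(cs), sortGeneric(planted))
  }
})

test_that("union of contact sets keeps provenance and rejects mixed cutoffs", {
  mk <- function(id, rec, pos, cutoff = 5) {
    new("ContactSet", structureId = id, receptorId = rec, cutoff = cutoff,
        contacts = data.frame(generic = pos, seq_index = NA_integer_,
                              resno = NA_integer_, chain = "A",
                              min_dist = 4, atom = "CB",
                              stringsAsFactors = FALSE),
        unmapped = data.frame())
  }
  u <- unionContacts(list(mk("s1", "r1", c("6x50", "7x40")),
                          mk("s2", "r2", c("6x50", "3x36"))))
  expect_equal(u$generic, c("3x36", "6x50", "7x40"))
  expect_equal(u$n_structures[u$generic == "6x50"], 2L)
  expect_equal(u$receptors[u$generic == "6x50"][[1]], c("r1", "r2"))
  # single input set is its own union
  one <- unionContacts(list(mk("s1", "r1", c("6x50", "7x40"))))
  expect_equal(one$generic, c("6x50", "7x40"))
  expect_error(unionContacts(list(mk("s1", "r1", "6x50"),
                                  mk("s2", "r1", "6x50", cutoff = 4))),
               "cutoff")
})
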