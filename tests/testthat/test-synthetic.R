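test_that("generators are deterministic under the spec seed", {
  spec <- smallSpec(seed = 7)
  a <- makeReceptorSet(spec); b <- makeReceptorSet(spec)
  expect_identical(as.character(a$alignment), as.character(b$alignment))
  expect_identical(a$familyMap, b$familyMap)
  ta <- makeMutationTable(spec, a); tb <- makeMutationTable(spec, b)
  expect_identical(ta, tb)
  p1 <- tempfile(fileext = ".pdb"); p2 <- tempfile(fileext = ".pdb")
  makeComplex(spec, a$annotations[[1]], spec$sitePositions, p1)
  makeComplex(spec, a$annotations[[1]], spec$sitePositions, p2)
  expect_identical(readLines(p1), readLines(p2))
  # the generators do not disturb the caller's RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99); makeReceptorSet(spec); after <- runif(1)
  expect_identical(before, after)
})

test_that("family blocks behave: zero within-family rate gives clones", {
  spec0 <- smallSpec(seed = 8, withinFamilyP = 0)
  rs <- makeReceptorSet(spec0)
  fam <- split(names(rs$familyMap), unname(rs$familyMap))
  for (members in fam) {
    seqs <- as.character(rs$alignment[members])
    # conserved Cys anchors aside, members are identical copies
    expect_true(all(seqs == seqs[1]))
  }
})

test_that("generated distances recover the planted block structure", {
  spec <- syntheticSpec(seed = 10, nReceptors = 20, nFamilies = 3,
                        backgroundRecords = 10)
  rs <- makeReceptorSet(spec)
  d <- distanceMatrix(rs$alignment, "p_distance")
  fam <- rs$familyMap[rownames(d)]
  same <- outer(fam, fam, "==") & upper.tri(d)
  diff <- !outer(fam, fam, "==") & upper.tri(d)
  expect_lt(mean(d[same]), mean(d[diff]))
})

test_that("complex geometry plants exactly the requested contacts", {
  spec <- smallSpec(seed = 12)
  rs <- makeReceptorSet(spec)
  ann <- rs$annotations[[2]]
  planted <- c("3x32", "6x50", "45x52")
  path <- tempfile(fileext = ".pdb")
  out <- makeComplex(spec, ann, planted, path)
  atoms <- readStructure(path, c(A = 0))
  cs <- contactPositions(atoms, list(het_code = "LIG"), ann,
                         cutoff = spec$cutoff)
  expect_equal(sitePositions(cs), sortGeneric(planted))
  # placement constraints verified by an independent scan
  lig <- atoms[atoms$type == "HETATM", ]
  rec <- atoms[atoms$type == "ATOM", ]
  plantedSeq <- genericToSeq(ann, planted)
  for (si in unique(rec$seq_index)) {
    ra <- rec[rec$seq_index == si, ]
    dmin <- min(sqrt(outer(ra$x, lig$x, "-")^2 + outer(ra$y, lig$y, "-")^2 +
                       outer(ra$z, lig$z, "-")^2))
    if (si %in% plantedSeq) expect_lte(dmin, spec$cutoff - spec$margin + 1e-9)
    else expect_gte(dmin, spec$cutoff + spec$margin - 1e-9)
  }
  expect_error(makeComplex(spec, ann, "2x99", path), "unknown|bounds|mappable")
})

test_that("zero margin and jitter put planted atoms exactly at the cutoff", {
  spec <- smallSpec(seed = 14, margin = 0, ligandJitter = 0)
  rs <- makeReceptorSet(spec)
  ann <- rs$annotations[[1]]
  path <- tempfile(fileext = ".pdb")
  makeComplex(spec, ann, c("6x50", "7x40"), path)
  atoms <- readStructure(path, c(A = 0))
  cs <- contactPositions(atoms, list(het_code = "LIG"), ann, cutoff = 5)
  # boundary distances sit at the cutoff (up to PDB coordinate precision)
  # on the inclusive side, and the positions are included
  expect_equal(sitePositions(cs), c("6x50", "7x40"))
  expect_true(all(contactTable(cs)$min_dist <= 5))
  expect_true(all(contactTable(cs)$min_dist > 5 - 0.01))
})

test_that("mutation tables plant recoverable positions and valid records", {
  spec <- smallSpec(seed = 15)
  rs <- makeReceptorSet(spec)
  tab <- makeMutationTable(spec, rs)
  v <- validateMutationTable(tab)
  expect_equal(nrow(v$rejected), 0L)
  expect_equal(effectPositions(tab, spec$threshold)$generic,
               spec$sitePositions)
  # wild-type letters come from the actual receptor sequences
  i <- sample(nrow(tab), 20)
  expect_equal(tab$wt_aa[i], vapply(i, function(k)
    substring(receptorSequence(rs$annotations[[tab$receptor_id[k]]]),
              tab$seq_index[k], tab$seq_index[k]), ""))
})

test_that("positions planted in three families surface as hotspots", {
  spec <- smallSpec(seed = 16)
  rs <- makeReceptorSet(spec)
  tab <- makeMutationTable(spec, rs)
  em <- effectPositions(tab, spec$threshold)
  prof <- buildSiteProfile(
    data.frame(generic = character(0), n_structures = integer(0),
               structures = I(list()), receptors = I(list()),
               min_dist = numeric(0)), em, rs$familyMap)
  expected <- em$generic[em$n_families >= 3]
  expect_equal(hotspotPositions(prof, 3), expected)
})

test_that("per-record pass rate matches its binomial expectation", {
  spec <- syntheticSpec(seed = 18, nReceptors = 8, nFamilies = 4,
                        passProb = 0.8, backgroundRecords = 0,
                        sitePositions = genericPosition(
                          rep(1:7, each = 5), rep(seq(30, 54, 6), 7)))
  rs <- makeReceptorSet(spec)
  tab <- makeMutationTable(spec, rs, guarantee = FALSE)
  n <- nrow(tab)
  expect_gt(n, 150)
  passes <- sum(callEffect(tab, spec$threshold)$passes)
  sigma <- sqrt(n * 0.8 * 0.2)
  expect_lt(abs(passes - 0.8 * n), 3 * sigma)
})

test_that("study bundles carry consistent ground truth and artifacts", {
  spec <- smallSpec(seed = 19)
  study <- makeStudy(spec)
  expect_setequal(names(study$evidence), spec$sitePositions)
  expect_setequal(union(study$structurePositions, study$mutationPositions),
                  spec$sitePositions)
  # every structural position is planted in at least one structure
  expect_setequal(unique(unlist(study$structures$planted)),
                  study$structurePositions)
  expect_true(all(file.exists(study$structures$path)))
  expect_true(file.exists(file.path(study$dir, "mutations.csv")))
  unlink(study$dir, recursive = TRUE)
})
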