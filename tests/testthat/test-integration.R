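# small constructors for the two evidence tables feeding the profile
unionDF <- function(pos, receptors = "r1", structures = "s1") {
  if (!length(pos))
    return(data.frame(generic = character(0), n_structures = integer(0),
                      structures = I(list()), receptors = I(list()),
                      min_dist = numeric(0)))
  data.frame(generic = pos, n_structures = length(structures),
             structures = I(rep(list(structures), length(pos))),
             receptors = I(rep(list(receptors), length(pos))),
             min_dist = 4, stringsAsFactors = FALSE)
}
effectDF <- function(pos, families = list("famA"), ligands = 1L,
                     modalities = list(c("NAM", "PAM")), receptors = "r1") {
  if (!length(pos))
    return(effectPositions(mutRecord(fold_effect = 1)))
  if (!is.list(families)) families <- list(families)
  families <- rep(families, length.out = length(pos))
  modalities <- rep(modalities, length.out = length(pos))
  data.frame(generic = pos,
             n_receptors = length(receptors),
             n_families = vapply(families, length, 0L),
             n_ligands = rep(ligands, length.out = length(pos)),
             receptors = I(rep(list(receptors), length(pos))),
             families = I(families), ligands = I(lapply(
               rep(ligands, length.out = length(pos)),
               function(k) paste0("L", seq_len(k)))),
             modalities = I(modalities), stringsAsFactors = FALSE)
}

test_that("profile is the union of evidence and keeps both provenances", {
  prof <- buildSiteProfile(unionDF(c("2x56", "3x32")),
                           effectDF(c("3x32", "6x50")),
                           familyMap = c(r1 = "famS"))
  t <- profileTable(prof)
  expect_equal(t$generic, c("2x56", "3x32", "6x50"))
  expect_equal(t$in_structure, c(TRUE, TRUE, FALSE))
  expect_equal(t$in_mutation, c(FALSE, TRUE, TRUE))
  # structures credit their receptor's family
  expect_equal(t$families[[1]], "famS")
  expect_equal(t$families[[2]], c("famA", "famS"))
  # empty mutational evidence: profile is the contact union
  p2 <- buildSiteProfile(unionDF(c("2x56", "3x32")), effectDF(character(0)))
  expect_equal(sitePositions(p2), c("2x56", "3x32"))
  expect_true(all(!profileTable(p2)$in_mutation))
})

test_that("venn partition is disjoint, covering and obeys inclusion-exclusion", {
  prof <- buildSiteProfile(unionDF(c("2x56", "3x32")),
                           effectDF(c("3x32", "6x50")))
  v <- vennPartition(prof)
  expect_equal(v$both, "3x32")
  allPos <- c(v$structure_only, v$mutation_only, v$both)
  expect_equal(sort(allPos), sort(sitePositions(prof)))
  expect_equal(anyDuplicated(allPos), 0L)
  # disjoint inputs and identical inputs
  expect_equal(vennPartition(buildSiteProfile(unionDF("2x56"),
                                              effectDF("6x50")))$both,
               character(0))
  vSame <- vennPartition(buildSiteProfile(unionDF("6x50"), effectDF("6x50")))
  expect_equal(vSame$structure_only, character(0))
  expect_equal(vSame$mutation_only, character(0))
})

test_that("hotspots need mutational evidence in enough families", {
  pos <- c("2x56", "3x32", "6x50")
  prof <- buildSiteProfile(unionDF(character(0)),
                           effectDF(pos, families = list(
                             c("f1", "f2", "f3"), c("f1", "f2"), "f1")))
  expect_equal(hotspotPositions(prof), "2x56")
  expect_equal(hotspotPositions(prof, minFamilies = 1), pos)
  expect_error(hotspotPositions(prof, minFamilies = 0), "minFamilies")
  # nesting: a stricter family requirement only removes positions
  for (k in 1:4)
    expect_true(all(hotspotPositions(prof, k + 1) %in%
                      hotspotPositions(prof, k)))
})

test_that("overlap statistics reproduce constructed fractions", {
  # 19 of 28 positions multi-family -> 67.9 -> 68 displayed
  pos <- genericPosition(2, 31:58)
  fams <- c(rep(list(c("f1", "f2")), 19), rep(list("f1"), 9))
  prof <- buildSiteProfile(unionDF(character(0)), effectDF(pos, families = fams))
  s <- overlapStatistics(prof)
  expect_equal(s$pct_multi_family, 68)
  expect_equal(s$unrounded$pct_multi_family, 100 * 19 / 28, tolerance = 1e-12)
  # every mutated position carries PAM+NAM here
  expect_equal(s$pct_dual_modality, 100)
  # all single-family -> 0; PAM-only -> 0
  p0 <- buildSiteProfile(unionDF(character(0)),
                         effectDF(pos, families = list("f1"),
                                  modalities = list("PAM")))
  s0 <- overlapStatistics(p0)
  expect_equal(s0$pct_multi_family, 0)
  expect_equal(s0$pct_dual_modality, 0)
  expect_error(overlapStatistics(buildSiteProfile(unionDF(character(0)),
                                                  effectDF(character(0)))),
               "empty")
})

test_that("statistics ignore record duplication (distinct-entity counting)", {
  tab <- rbind(mutRecord(), mutRecord(generic = "6x53", seq_index = 18L,
                                      modality = "PAM", fold_effect = 9))
  dup <- rbind(tab, tab, tab)
  p1 <- buildSiteProfile(unionDF(character(0)), effectPositions(tab))
  p2 <- buildSiteProfile(unionDF(character(0)), effectPositions(dup))
  expect_equal(overlapStatistics(p1), overlapStatistics(p2))
  expect_equal(profileTable(p1)$n_ligands, profileTable(p2)$n_ligands)
})

test_that("outside-site positions get glycine and rarity flags", {
  records <- rbind(
    # Gly->Val with a large effect at a non-site position
    mutRecord(generic = "4x42", seq_index = 8L, wt_aa = "G", mut_aa = "V",
              fold_effect = 55, receptor_id = "r1"),
    # same generic position, non-Gly wild type elsewhere, no effect
    mutRecord(generic = "4x42", seq_index = 8L, wt_aa = "V", mut_aa = "I",
              fold_effect = NA, qualitative = "no_effect",
              receptor_id = "r2"),
    # widely supported position inside the site
    mutRecord(generic = "6x50", fold_effect = 20))
  em <- effectPositions(records)
  cls <- classifyOutsideSite(em, siteSet = "6x50", records)
  expect_equal(cls$generic, "4x42")
  expect_true(cls$wildtype_glycine)
  expect_true(cls$single_ligand_single_receptor)
  # a multi-ligand, multi-receptor outside position is not flagged rare
  rec2 <- rbind(
    mutRecord(generic = "5x37", seq_index = 20L, ligand_id = "L1",
              receptor_id = "r1", fold_effect = 8),
    mutRecord(generic = "5x37", seq_index = 20L, ligand_id = "L2",
              receptor_id = "r2", fold_effect = 9),
    mutRecord(generic = "5x37", seq_index = 20L, ligand_id = "L3",
              receptor_id = "r2", fold_effect = 7))
  cls2 <- classifyOutsideSite(effectPositions(rec2), "6x50", rec2)
  expect_false(cls2$single_ligand_single_receptor)
  expect_false(cls2$wildtype_glycine)
  # membrane-facing flag appears only when an orientation is supplied
  expect_true(is.na(cls$membrane_facing[1]))
  cls3 <- classifyOutsideSite(em, "6x50", records,
                              membraneFacing = c("1x46", "4x42"))
  expect_true(cls3$membrane_facing)
})

test_that("receptor-unique evidence shows up in the selectivity column", {
  prof <- buildSiteProfile(unionDF("2x56", receptors = "r1"),
                           effectDF("7x41", receptors = "r9"))
  sel <- selectivityColumn(prof)
  expect_true(all(sel$receptor_unique))
  prof2 <- buildSiteProfile(unionDF("2x56", receptors = c("r1", "r2")),
                            effectDF(character(0)))
  expect_false(selectivityColumn(prof2)$receptor_unique)
})
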