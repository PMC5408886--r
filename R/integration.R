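## Merge structural contacts and mutagenesis evidence into the common-site
## profile, its Venn partition, hotspots, overlap statistics and the
## classification of effect positions lying outside the site.

#' Round half away from zero
#'
#' Display rounding for percentages (base `round` rounds half to even).
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
roundHalfUp <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

## SiteProfile --------------------------------------------------------------

#' SiteProfile: merged per-position evidence for the allosteric site
#'
#' One row per generic position in the union of structural contacts and
#' passing mutational evidence.  Family evidence combines both sources:
#' a structure contributes its receptor's family.
#'
#' @slot table data.frame with columns `generic, in_structure, in_mutation,
#'   n_structures, n_ligands` and list-columns `structures,
#'   struct_receptors, mut_receptors, mut_families, families, modalities`.
#' @export
setClass("SiteProfile", representation(table = "data.frame"))

setValidity("SiteProfile", function(object) {
  t <- object@table
  if (nrow(t) && !all(t$in_structure | t$in_mutation))
    return("every profiled position needs structural or mutational evidence")
  if (anyDuplicated(t$generic)) return("duplicated generic position")
  TRUE
})

#' @export
setMethod("sitePositions", "SiteProfile",
          function(object) object@table$generic)


#' @export
setMethod("profileTable", "SiteProfile", function(object) object@table)

setMethod("show", "SiteProfile", function(object) {
  t <- object@table
  cat(sprintf(
    "SiteProfile: %d positions (%d structural, %d mutational, %d both)\n",
    nrow(t), sum(t$in_structure), sum(t$in_mutation),
    sum(t$in_structure & t$in_mutation)))
})

#' Build the common-site profile
#'
#' Takes the union of the structural contact positions (from
#' [unionContacts()]) and the passing mutational positions (from
#' [effectPositions()]) and merges their evidence per position.
#'
#' @param contactUnion data.frame from [unionContacts()].
#' @param effectMap data.frame from [effectPositions()].
#' @param familyMap named character vector mapping receptor_id to family
#'   (used to credit structures to their receptor's family); optional.
#' @return a [SiteProfile-class].
#' @export
buildSiteProfile <- function(contactUnion, effectMap, familyMap = NULL) {
  pos <- sortGeneric(union(contactUnion$generic, effectMap$generic))
  ci <- match(pos, contactUnion$generic)
  ei <- match(pos, effectMap$generic)
  getl <- function(tab, col, i)
    lapply(i, function(k) if (is.na(k)) character(0) else tab[[col]][[k]])
  structures <- getl(contactUnion, "structures", ci)
  structReceptors <- getl(contactUnion, "receptors", ci)
  mutReceptors <- getl(effectMap, "receptors", ei)
  mutFamilies <- getl(effectMap, "families", ei)
  structFamilies <- lapply(structReceptors, function(r) {
    if (is.null(familyMap)) character(0)
    else sort(unique(unname(familyMap[r[r %in% names(familyMap)]])))
  })
  families <- mapply(function(a, b) sort(unique(c(a, b))),
                     mutFamilies, structFamilies, SIMPLIFY = FALSE)
  tab <- data.frame(
    generic = pos,
    in_structure = !is.na(ci),
    in_mutation = !is.na(ei),
    n_structures = ifelse(is.na(ci), 0L, contactUnion$n_structures[ci]),
    n_ligands = ifelse(is.na(ei), 0L, effectMap$n_ligands[ei]),
    structures = I(structures),
    struct_receptors = I(structReceptors),
    mut_receptors = I(mutReceptors),
    mut_families = I(mutFamilies),
    families = I(families),
    modalities = I(getl(effectMap, "modalities", ei)),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  new("SiteProfile", table = tab)
}

#' Venn partition of a site profile by evidence type
#'
#' @param profile a [SiteProfile-class].
#' @return list with disjoint character vectors `structure_only`,
#'   `mutation_only`, `both` whose union is the full position set.
#' @export
vennPartition <- function(profile) {
  t <- profileTable(profile)
  list(structure_only = t$generic[t$in_structure & !t$in_mutation],
       mutation_only = t$generic[!t$in_structure & t$in_mutation],
       both = t$generic[t$in_structure & t$in_mutation])
}

#' Modulator-binding hotspots
#'
#' Positions whose passing mutational evidence spans at least
#' `minFamilies` distinct receptor families (structural support is not
#' required).
#'
#' @param profile a [SiteProfile-class].
#' @param minFamilies minimum number of families; default 3.
#' @return character vector of generic positions.
#' @export
hotspotPositions <- function(profile, minFamilies = 3L) {
  if (minFamilies < 1L) stop("minFamilies must be >= 1")
  t <- profileTable(profile)
  nf <- vapply(t$mut_families, length, 0L)
  t$generic[t$in_mutation & nf >= minFamilies]
}

#' Overlap statistics of the site profile
#'
#' * multi-family: share of positions whose combined (structural +
#'   mutational) family evidence covers at least two families.  Because the
#'   natural denominator is ambiguous, both variants are reported: over all
#'   profiled positions and over mutation-supported positions only.
#' * dual modality: share of mutation-supported positions with passing
#'   evidence for both a PAM and a NAM (allosteric agonists are excluded
#'   from this statistic).
#'
#' Percentages are rounded half-up to integers for display; unrounded
#' values are returned alongside.
#'
#' @param profile a [SiteProfile-class].
#' @return list with `pct_multi_family`, `pct_multi_family_mutated`,
#'   `pct_dual_modality` (integers) and an `unrounded` sublist.
#' @export
overlapStatistics <- function(profile) {
  t <- profileTable(profile)
  if (!nrow(t)) stop("overlap statistics are undefined on an empty profile")
  nf <- vapply(t$families, length, 0L)
  multi <- nf >= 2L
  mut <- t$in_mutation
  dual <- vapply(t$modalities, function(m) all(c("PAM", "NAM") %in% m), TRUE)
  u <- list(
    pct_multi_family = 100 * sum(multi) / nrow(t),
    pct_multi_family_mutated =
      if (any(mut)) 100 * sum(multi & mut) / sum(mut) else NA_real_,
    pct_dual_modality =
      if (any(mut)) 100 * sum(dual & mut) / sum(mut) else NA_real_)
  c(lapply(u, roundHalfUp), list(unrounded = u))
}

#' Classify effect positions outside the common site
#'
#' Every mutational effect position absent from the site set is annotated
#' with flags that point at likely indirect mechanisms:
#' * `single_ligand_single_receptor`: effect reported for exactly one
#'   modulator on one receptor (weak/rare effects).
#' * `wildtype_glycine`: the mutated wild-type residue is Gly in some
#'   receptor with passing evidence there (backbone-flexibility positions).
#' * `adjacent_to_site`: within the supplied structural neighbour list of a
#'   site position (only computed when `neighborList` is given).
#' * `membrane_facing`: from an orientation annotation (only computed when
#'   `membraneFacing` is given).
#'
#' @param effectMap data.frame from [effectPositions()].
#' @param siteSet character vector of common-site generic positions.
#' @param records the mutation records (for wild-type residues).
#' @param threshold fold threshold used for effect calling.
#' @param neighborList optional named list: generic position to character
#'   vector of spatial neighbours.
#' @param membraneFacing optional character vector of membrane-facing
#'   generic positions.
#' @return data.frame with one row per outside position and logical flag
#'   columns.
#' @export
classifyOutsideSite <- function(effectMap, siteSet, records,
                                threshold = 5.0, neighborList = NULL,
                                membraneFacing = NULL) {
  out <- effectMap[!effectMap$generic %in% siteSet, , drop = FALSE]
  if (!nrow(out))
    return(data.frame(generic = character(0),
                      single_ligand_single_receptor = logical(0),
                      wildtype_glycine = logical(0),
                      adjacent_to_site = logical(0),
                      membrane_facing = logical(0)))
  called <- callEffect(records, threshold)
  pass <- called[called$passes, , drop = FALSE]
  glyAt <- vapply(out$generic, function(g)
    any(pass$generic == g & pass$wt_aa == "G"), TRUE)
  res <- data.frame(
    generic = out$generic,
    single_ligand_single_receptor = out$n_ligands == 1L & out$n_receptors == 1L,
    wildtype_glycine = unname(glyAt),
    adjacent_to_site = if (is.null(neighborList)) NA else
      vapply(out$generic, function(g)
        any(unlist(neighborList[[g]]) %in% siteSet), TRUE),
    membrane_facing = if (is.null(membraneFacing)) NA else
      out$generic %in% membraneFacing,
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Per-position selectivity column
#'
#' Marks positions whose whole body of evidence (structures + mutations)
#' is confined to a single receptor -- receptor-unique sub-pockets such as
#' a site extension fall out here.
#'
#' @param profile a [SiteProfile-class].
#' @return data.frame with `generic`, `n_receptors_total`,
#'   `receptor_unique`.
#' @export
selectivityColumn <- function(profile) {
  t <- profileTable(profile)
  recs <- mapply(function(a, b) unique(c(a, b)),
                 t$struct_receptors, t$mut_receptors, SIMPLIFY = FALSE)
  data.frame(generic = t$generic,
             n_receptors_total = vapply(recs, length, 0L),
             receptor_unique = vapply(recs, length, 0L) == 1L,
             stringsAsFactors = FALSE)
}

#' Write a site profile to CSV
#'
#' List-columns are flattened to semicolon-joined strings.
#' @param profile a [SiteProfile-class].
#' @param path output CSV.
#' @export
writeSiteProfile <- function(profile, path) {
  t <- profileTable(profile)
  flat <- t
  for (col in names(flat))
    if (is.list(flat[[col]]))
      flat[[col]] <- vapply(flat[[col]], paste, "", collapse = ";")
  write.csv(flat, path, row.names = FALSE)
  invisible(flat)
}
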