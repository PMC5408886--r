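## End-to-end pipeline: structures -> contacts, mutations -> effects,
## integration, trees, conservation; consolidated report bundle on disk.

#' Run the full analysis and write the report bundle
#'
#' Executes every stage on one input bundle: per-structure contact
#' extraction and union, mutation effect calling and per-position
#' summaries, the merged site profile with Venn partition, hotspots and
#' overlap statistics, conservation of the site columns, and UPGMA trees
#' (with family-coherence checks) for the full TMD alignment and for the
#' site columns.  Deterministic on fixed inputs.
#'
#' Inputs can be given as a study list from [makeStudy()] or as file
#' paths (the formats written by [makeStudy()]: a structures CSV with
#' `structure_id, receptor_id, chain, chain_offset, het_code, path`, a
#' mutation CSV, annotation CSV + FASTA, and a family CSV).
#'
#' @param study a list from [makeStudy()], or `NULL` when file paths are
#'   given.
#' @param structuresCsv,mutationsCsv,annotationsCsv,fastaPath,familiesCsv
#'   input files (ignored when `study` is given).
#' @param outDir output directory for the report bundle; `NULL` skips
#'   writing and only returns results.
#' @param cutoff contact cutoff in Angstrom.
#' @param threshold fold-change threshold.
#' @param minFamilies hotspot family threshold.
#' @param distanceModel `"poisson"` or `"p_distance"` for the trees.
#' @return list with `contacts` (per-structure [ContactSet-class]s),
#'   `contactUnion`, `effectMap`, `conflicts`, `profile`
#'   ([SiteProfile-class]), `venn`, `hotspots`, `statistics`,
#'   `outside` (classification of effect positions off the site),
#'   `selectivity`, `conservation`, `tmdTree`, `siteTree`,
#'   `coherence` (list with `tmd` and `site`), `parameters`.
#' @export
runPipeline <- function(study = NULL,
                        structuresCsv = NULL, mutationsCsv = NULL,
                        annotationsCsv = NULL, fastaPath = NULL,
                        familiesCsv = NULL,
                        outDir = NULL,
                        cutoff = 5.0, threshold = 5.0, minFamilies = 3L,
                        distanceModel = c("poisson", "p_distance")) {
  distanceModel <- match.arg(distanceModel)
  stage <- function(name, expr)
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))

  if (!is.null(study)) {
    anns <- study$receptorSet$annotations
    famMap <- study$receptorSet$familyMap
    aln <- study$receptorSet$alignment
    structTab <- study$structures
    records <- study$mutationTable
  } else {
    anns <- stage("annotations", readAnnotations(annotationsCsv, fastaPath))
    famTab <- stage("families", read.csv(familiesCsv, stringsAsFactors = FALSE))
    famMap <- setNames(famTab$family, famTab$receptor_id)
    aln <- Biostrings::readAAStringSet(fastaPath)
    names(aln) <- sub("\\s.*$", "", names(aln))
    structTab <- stage("structures-config",
                       read.csv(structuresCsv, stringsAsFactors = FALSE))
    records <- stage("mutations", readMutationTable(mutationsCsv))
  }

  contacts <- stage("contacts", lapply(seq_len(nrow(structTab)), function(k) {
    s <- structTab[k, ]
    atoms <- readStructure(s$path, setNames(s$chain_offset, s$chain))
    contactPositions(atoms, list(het_code = s$het_code),
                     anns[[s$receptor_id]], cutoff = cutoff,
                     structureId = s$structure_id, chains = s$chain)
  }))
  names(contacts) <- structTab$structure_id
  contactUnion <- stage("contact-union", unionContacts(contacts))

  effectMap <- stage("effects", effectPositions(records, threshold))
  conflicts <- stage("effects", conflictReport(records, threshold))

  profile <- stage("integration",
                   buildSiteProfile(contactUnion, effectMap, famMap))
  venn <- vennPartition(profile)
  hotspots <- hotspotPositions(profile, minFamilies)
  statistics <- overlapStatistics(profile)
  outside <- classifyOutsideSite(effectMap, sitePositions(profile),
                                 records, threshold)
  selectivity <- selectivityColumn(profile)

  site <- sitePositions(profile)
  conservation <- stage("conservation", conservationReport(anns, site))

  tmdAln <- setNames(as.character(aln), names(aln))
  siteAln <- stage("site-alignment", siteAlignment(anns, site))
  tmdTree <- stage("tree-tmd", upgma(distanceMatrix(tmdAln, distanceModel)))
  siteTree <- stage("tree-site", upgma(distanceMatrix(siteAln, distanceModel)))
  coherence <- list(tmd = familyCoherence(tmdTree, famMap),
                    site = familyCoherence(siteTree, famMap))

  parameters <- list(cutoff = cutoff, threshold = threshold,
                     minFamilies = minFamilies,
                     distanceModel = distanceModel)
  result <- list(contacts = contacts, contactUnion = contactUnion,
                 effectMap = effectMap, conflicts = conflicts,
                 profile = profile, venn = venn, hotspots = hotspots,
                 statistics = statistics, outside = outside,
                 selectivity = selectivity, conservation = conservation,
                 tmdTree = tmdTree, siteTree = siteTree,
                 coherence = coherence, parameters = parameters)
  if (!is.null(outDir)) writeReportBundle(result, outDir)
  result
}

#' Write the consolidated report bundle
#'
#' @param result a [runPipeline()] result.
#' @param outDir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
writeReportBundle <- function(result, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outDir, f)
  for (cs in result$contacts)
    writeContactSet(cs, p(sprintf("contacts_%s.csv", cs@structureId)))
  flatUnion <- result$contactUnion
  for (col in c("structures", "receptors"))
    flatUnion[[col]] <- vapply(flatUnion[[col]], paste, "", collapse = ";")
  write.csv(flatUnion, p("contact_union.csv"), row.names = FALSE)
  flatEff <- result$effectMap
  for (col in c("receptors", "families", "ligands", "modalities"))
    flatEff[[col]] <- vapply(flatEff[[col]], paste, "", collapse = ";")
  write.csv(flatEff, p("effect_positions.csv"), row.names = FALSE)
  writeSiteProfile(result$profile, p("site_profile.csv"))
  write.csv(result$outside, p("outside_site.csv"), row.names = FALSE)
  write.csv(result$conservation, p("conservation.csv"), row.names = FALSE)
  summary <- list(
    n_site_positions = length(sitePositions(result$profile)),
    venn = lapply(result$venn, identity),
    venn_sizes = lapply(result$venn, length),
    hotspots = result$hotspots,
    statistics = result$statistics[c("pct_multi_family",
                                     "pct_multi_family_mutated",
                                     "pct_dual_modality")],
    parameters = result$parameters)
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  jsonlite::write_json(lapply(result$coherence, as.list),
                       p("family_coherence.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  ape::write.tree(result$tmdTree, p("tmd_tree.nwk"))
  ape::write.tree(result$siteTree, p("site_tree.nwk"))
  log <- list(package = "allosite",
              version = as.character(utils::packageVersion("allosite")),
              parameters = result$parameters,
              n_conflicting_records = nrow(result$conflicts))
  jsonlite::write_json(log, p("run_log.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(outDir)
}

#' Simulate a study and run the pipeline on it
#'
#' Closed-loop convenience wrapper: generate a synthetic study with a
#' planted site, run [runPipeline()] on it, and attach the ground truth.
#'
#' @param spec a [syntheticSpec()].
#' @param dir study directory (default: temporary).
#' @param outDir report directory or `NULL`.
#' @param ... further arguments to [runPipeline()].
#' @return the [runPipeline()] result plus `study` (with its planted
#'   truth) and `recovered` (the profiled position set).
#' @export
simulateStudy <- function(spec = syntheticSpec(), dir = tempfile("study_"),
                          outDir = NULL, ...) {
  study <- makeStudy(spec, dir)
  res <- runPipeline(study = study, outDir = outDir,
                     cutoff = spec$cutoff, threshold = spec$threshold, ...)
  res$study <- study
  res$recovered <- sitePositions(res$profile)
  res
}
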