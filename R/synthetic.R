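## Synthetic study generator.
##
## Emulates the full input bundle of the analysis -- receptor sequences in
## family blocks with segment annotations, modulator-complex structures,
## and a curated mutation table -- with a planted allosteric site, so every
## pipeline stage can be validated against known ground truth.  Geometry is
## idealized (3.6 residues/turn, 1.5 A rise, one pseudo side-chain atom per
## residue); controllable distances, not physical realism, are the goal.

## fixed segment architecture: TM1-7 span generic x28..x58 (31 residues,
## anchor x50), ECL2 spans 45x46..45x54 (anchor = the conserved Cys 45x50),
## 3-residue linkers between segments and at both ends.
.TM_LEN <- 31L
.TM_LO <- 28L
.ECL2_LEN <- 9L
.ECL2_LO <- 46L
.LINK <- 3L

.segmentLayout <- function() {
  segs <- list(c(1, .TM_LEN), c(2, .TM_LEN), c(3, .TM_LEN), c(4, .TM_LEN),
               c(45, .ECL2_LEN), c(5, .TM_LEN), c(6, .TM_LEN), c(7, .TM_LEN))
  start <- .LINK + 1L
  rows <- lapply(segs, function(s) {
    lo <- if (s[1] == 45) .ECL2_LO else .TM_LO
    r <- data.frame(segment = s[1], seq_start = start,
                    seq_end = start + s[2] - 1L,
                    anchor_seq_index = start + (50L - lo))
    start <<- start + s[2] + .LINK
    r
  })
  list(segments = do.call(rbind, rows), seqLen = start - 1L)
}

.AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

## run expr under a fixed seed without disturbing the caller's RNG stream
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Default planted site used by the study-scale generator
#'
#' Twenty-eight positions between TM2/3/5/6/7 and ECL2, laid out like the
#' class C modulator pocket (central TM6 positions, the sole ECL2 contact
#' one position after the anchor, and flanking TM3/5/7 rings).
#' @return character vector of generic positions.
#' @export
defaultSitePositions <- function() {
  sortGeneric(c("2x52", "2x56",
                "3x32", "3x33", "3x36", "3x40", "3x44",
                "45x52",
                "5x40", "5x43", "5x44", "5x47",
                "6x42", "6x46", "6x50", "6x53", "6x57",
                "7x33", "7x37", "7x40", "7x41", "7x44",
                "2x49", "3x29", "5x51", "6x38", "7x29", "7x48"))
}

#' Specification of a synthetic study
#'
#' Defaults describe the study conditions emulated throughout: 22 receptors
#' in five family blocks (8/2/3/2/7, mirroring the class C layout of mGlu,
#' GABA-B, taste 1, CaS-group and orphan receptors), a 28-position planted
#' site, four modulator complexes over two receptors, a 70-modulator ligand
#' pool and roughly 1700 mutation records.
#'
#' @param seed integer master seed; every generator derives its stream
#'   from it.
#' @param families named integer vector of family sizes.
#' @param nReceptors,nFamilies used only when `families` is not given:
#'   receptors are split into near-equal family blocks.
#' @param withinFamilyP,betweenFamilyP per-column substitution
#'   probabilities of the family-block sequence process (member vs family
#'   ancestor, ancestor vs root).
#' @param sitePositions planted site (generic positions; must be mappable
#'   under the fixed segment layout).
#' @param cutoff contact cutoff in Angstrom.
#' @param margin ligand atoms are placed within `cutoff - margin` of every
#'   planted side chain and kept at least `cutoff + margin` from all other
#'   residues.
#' @param ligandJitter uniform inward placement jitter in Angstrom
#'   (must not exceed `margin`).
#' @param evidenceMix named probabilities that a planted position carries
#'   `both`, `structure`(-only) or `mutation`(-only) evidence.
#' @param nStructures number of complexes; the first three sit on the
#'   first receptor and the rest on the second (mirroring 3+1 entries over
#'   two receptors) unless `structureReceptors` is given.
#' @param structureReceptors optional character vector of receptor ids,
#'   one per structure.
#' @param nLigands size of the modulator pool.
#' @param modalityMix named probabilities for PAM / NAM / agonist ligands.
#' @param foldMeanLog,foldSdLog log-normal parameters of passing fold
#'   effects (defaults centre folds near 15 with a 3-75 bulk, matching the
#'   few-fold to >55-fold span of reported effects).
#' @param passProb probability that a non-guaranteed planted record passes.
#' @param abolishedProb probability a passing record is reported as
#'   qualitative "abolished" instead of a fold.
#' @param famSpread binomial probability controlling how many families
#'   report each planted position.
#' @param threshold fold-change inclusion threshold.
#' @param backgroundRecords number of sub-threshold records at non-site
#'   positions.
#' @return validated spec (list, class `"syntheticSpec"`).
#' @export
syntheticSpec <- function(seed = 1L,
                          families = NULL,
                          nReceptors = 22L, nFamilies = 5L,
                          withinFamilyP = 0.08, betweenFamilyP = 0.35,
                          sitePositions = defaultSitePositions(),
                          cutoff = 5.0, margin = 0.5, ligandJitter = 0.3,
                          evidenceMix = c(both = 0.6, structure = 0.2,
                                          mutation = 0.2),
                          nStructures = 4L, structureReceptors = NULL,
                          nLigands = 70L,
                          modalityMix = c(PAM = 0.45, NAM = 0.45,
                                          agonist = 0.10),
                          foldMeanLog = log(15), foldSdLog = 1,
                          passProb = 0.9, abolishedProb = 0.1,
                          famSpread = 0.35,
                          threshold = 5.0,
                          backgroundRecords = 800L) {
  if (is.null(families)) {
    if (identical(as.integer(nReceptors), 22L) &&
        identical(as.integer(nFamilies), 5L)) {
      families <- c(mGlu = 8L, GABAB = 2L, TAS1R = 3L, CaS = 2L, orphan = 7L)
    } else {
      sizes <- diff(floor(seq(0, nReceptors, length.out = nFamilies + 1)))
      families <- setNames(as.integer(sizes), paste0("fam", seq_len(nFamilies)))
    }
  }
  spec <- list(seed = as.integer(seed), families = families,
               withinFamilyP = withinFamilyP, betweenFamilyP = betweenFamilyP,
               sitePositions = sortGeneric(sitePositions),
               cutoff = cutoff, margin = margin, ligandJitter = ligandJitter,
               evidenceMix = evidenceMix, nStructures = as.integer(nStructures),
               structureReceptors = structureReceptors,
               nLigands = as.integer(nLigands), modalityMix = modalityMix,
               foldMeanLog = foldMeanLog, foldSdLog = foldSdLog,
               passProb = passProb, abolishedProb = abolishedProb,
               famSpread = famSpread, threshold = threshold,
               backgroundRecords = as.integer(backgroundRecords))
  class(spec) <- "syntheticSpec"
  validateSyntheticSpec(spec)
}

#' Validate a synthetic-study spec
#' @param spec a `syntheticSpec`.
#' @return the spec, invisibly-checked; errors on inconsistency.
#' @export
validateSyntheticSpec <- function(spec) {
  stopifnot(sum(spec$families) >= 2L, all(spec$families >= 1L),
            spec$withinFamilyP >= 0, spec$withinFamilyP <= 1,
            spec$betweenFamilyP >= 0, spec$betweenFamilyP <= 1,
            spec$cutoff > 0, spec$margin >= 0,
            spec$ligandJitter >= 0,
            spec$ligandJitter <= spec$margin || spec$ligandJitter == 0,
            abs(sum(spec$evidenceMix) - 1) < 1e-9,
            abs(sum(spec$modalityMix) - 1) < 1e-9,
            spec$passProb >= 0, spec$passProb <= 1,
            spec$threshold > 0)
  ## planted positions must be mappable under the fixed layout
  lay <- .segmentLayout()
  p <- parseGeneric(spec$sitePositions)
  m <- match(p$segment, lay$segments$segment)
  if (any(is.na(m)))
    stop("site position(s) in unknown segment: ",
         paste(spec$sitePositions[is.na(m)], collapse = ", "))
  i <- lay$segments$anchor_seq_index[m] + (p$index - 50L)
  bad <- i < lay$segments$seq_start[m] | i > lay$segments$seq_end[m]
  if (any(bad))
    stop("site position(s) outside segment bounds: ",
         paste(spec$sitePositions[bad], collapse = ", "))
  spec
}

#' Generate the receptor set: alignment, annotations, family map
#'
#' Sequences follow a family-block process: a random root sequence, family
#' ancestors substituted per column with `betweenFamilyP`, and members
#' substituted from their ancestor with `withinFamilyP`, so within-family
#' mismatch proportions sit below between-family ones.  The disulphide
#' cysteines (3x29 and the ECL2 anchor 45x50) are fixed to Cys in every
#' receptor.  All receptors share the segment layout, so the alignment is
#' gapless; deterministic under the spec seed.
#'
#' @param spec a [syntheticSpec()].
#' @return list with `alignment` (`AAStringSet`), `annotations` (named
#'   list of [ReceptorAnnotation-class]), `familyMap` (named character).
#' @export
makeReceptorSet <- function(spec) {
  lay <- .segmentLayout()
  n <- lay$seqLen
  .withSeed(spec$seed, {
    root <- sample(.AA, n, replace = TRUE)
    seqs <- list()
    fam <- character(0)
    for (f in names(spec$families)) {
      anc <- root
      flip <- runif(n) < spec$betweenFamilyP
      anc[flip] <- vapply(which(flip), function(i)
        sample(setdiff(.AA, anc[i]), 1L), "")
      for (k in seq_len(spec$families[[f]])) {
        s <- anc
        flip <- runif(n) < spec$withinFamilyP
        if (any(flip))
          s[flip] <- vapply(which(flip), function(i)
            sample(setdiff(.AA, s[i]), 1L), "")
        id <- paste0(f, "_", k)
        seqs[[id]] <- s
        fam[id] <- f
      }
    }
    ## conserved disulphide cysteines
    segs <- lay$segments
    cys <- c(segs$anchor_seq_index[segs$segment == 45],
             segs$anchor_seq_index[segs$segment == 3] - 21L)  # 45x50, 3x29
    seqs <- lapply(seqs, function(s) { s[cys] <- "C"; s })
    strs <- vapply(seqs, paste, "", collapse = "")
    anns <- setNames(lapply(names(strs), function(id)
      ReceptorAnnotation(id, strs[[id]], segs)), names(strs))
    list(alignment = Biostrings::AAStringSet(strs),
         annotations = anns, familyMap = fam)
  })
}

## idealized coordinates (CA + one pseudo side-chain atom "CB" per residue;
## planted residues point a 7 A side chain into the bundle core, all others
## point outward, which keeps ligand atoms radially separated from every
## non-planted atom)
.BUNDLE_R <- 14; .HELIX_R <- 2.3; .RISE <- 1.5; .SIDE_IN <- 7; .SIDE_OUT <- 1.5

.receptorCoords <- function(ann, planted) {
  segs <- segments(ann)
  plantedSeq <- genericToSeq(ann, planted)
  rows <- list()
  for (k in seq_len(nrow(segs))) {
    sg <- segs[k, ]
    idx <- sg$seq_start:sg$seq_end
    L <- length(idx)
    if (sg$segment == 45) {           # extracellular arc above the bundle
      psi <- seq(2 * pi * 3.5 / 7 - 0.5, 2 * pi * 3.5 / 7 + 0.5,
                 length.out = L)
      ca <- cbind(.BUNDLE_R * cos(psi), .BUNDLE_R * sin(psi),
                  .RISE * (.TM_LEN / 2) + 4 + 0.3 * seq_len(L))
    } else {
      phi <- 2 * pi * (sg$segment - 1) / 7
      dirz <- if (sg$segment %% 2 == 1) 1 else -1
      t <- seq_len(L) - (L + 1) / 2
      wob <- (100 * pi / 180) * seq_len(L) + phi
      ca <- cbind(.BUNDLE_R * cos(phi) + .HELIX_R * cos(wob),
                  .BUNDLE_R * sin(phi) + .HELIX_R * sin(wob),
                  .RISE * t * dirz)
    }
    r <- sqrt(ca[, 1]^2 + ca[, 2]^2)
    u <- ca[, 1:2] / r
    isPlanted <- idx %in% plantedSeq
    ext <- ifelse(isPlanted, -.SIDE_IN, .SIDE_OUT)
    cb <- cbind(ca[, 1] + ext * u[, 1], ca[, 2] + ext * u[, 2], ca[, 3])
    rows[[k]] <- data.frame(seq_index = rep(idx, 2L),
                            elety = rep(c("CA", "CB"), each = L),
                            x = c(ca[, 1], cb[, 1]), y = c(ca[, 2], cb[, 2]),
                            z = c(ca[, 3], cb[, 3]), planted = rep(isPlanted, 2L))
  }
  out <- do.call(rbind, rows)
  out[order(out$seq_index, out$elety), , drop = FALSE]
}

#' Write a synthetic receptor-modulator complex in PDB format
#'
#' Builds an idealized seven-helix bundle (plus an ECL2 arc) for the
#' receptor, with one pseudo side-chain atom per residue, and places one
#' ligand atom within `cutoff - margin` of every planted position's side
#' chain while guaranteeing at least `cutoff + margin` clearance from all
#' other residues (verified after placement; violation raises a
#' generation error).  `margin = 0` with `jitter = 0` puts ligand atoms
#' exactly at the cutoff.
#'
#' @param spec a [syntheticSpec()].
#' @param ann the receptor's [ReceptorAnnotation-class].
#' @param planted generic positions to place in contact.
#' @param path output PDB path.
#' @param structureId id written into the header.
#' @param chain receptor chain id.
#' @param chainOffset author numbering = sequence numbering - offset.
#' @param seed stream seed; defaults to the spec seed.
#' @return invisibly, a list with `path`, `planted`, and the coordinate
#'   table used.
#' @export
makeComplex <- function(spec, ann, planted = spec$sitePositions, path,
                        structureId = "SYN1", chain = "A", chainOffset = 0L,
                        seed = spec$seed) {
  planted <- sortGeneric(planted)
  if (any(is.na(genericToSeq(ann, planted))))
    stop("planted position(s) not mappable on ", receptorId(ann))
  .withSeed(seed + 7919L, {
    co <- .receptorCoords(ann, planted)
    ## quantize to PDB coordinate precision up front: distances are then
    ## computed on exactly what the file will contain
    co[, c("x", "y", "z")] <- round(co[, c("x", "y", "z")], 3)
    cb <- co[co$elety == "CB" & co$planted, , drop = FALSE]
    ## half a coordinate grid step inside the target keeps the placement on
    ## the inclusive side of the cutoff after rounding
    d <- spec$cutoff - spec$margin - 0.002 -
      runif(nrow(cb), 0, min(spec$ligandJitter, spec$margin + 1e-12))
    r <- sqrt(cb$x^2 + cb$y^2)
    lig <- data.frame(x = round(cb$x - d * cb$x / r, 3),
                      y = round(cb$y - d * cb$y / r, 3),
                      z = cb$z)
    ## placement guarantees
    other <- co[!co$planted, , drop = FALSE]
    if (nrow(lig) && nrow(other)) {
      d2 <- outer(lig$x, other$x, "-")^2 + outer(lig$y, other$y, "-")^2 +
        outer(lig$z, other$z, "-")^2
      if (min(d2) < (spec$cutoff + spec$margin)^2 - 1e-9)
        stop("geometric infeasibility: ligand atom within ",
             "cutoff + margin of a non-planted residue")
    }
    aa1 <- strsplit(receptorSequence(ann), "")[[1]]
    resid3 <- bio3d::aa123(aa1[co$seq_index])
    nr <- nrow(co); nl <- nrow(lig)
    bio3d::write.pdb(
      file = path,
      xyz = c(t(as.matrix(rbind(co[, c("x", "y", "z")],
                                lig[, c("x", "y", "z")])))),
      type = c(rep("ATOM", nr), rep("HETATM", nl)),
      resno = c(co$seq_index - as.integer(chainOffset), 900L + seq_len(nl)),
      resid = c(resid3, rep("LIG", nl)),
      eleno = seq_len(nr + nl),
      elety = c(co$elety, rep("C1", nl)),
      chain = c(rep(chain, nr), rep("X", nl)),
      o = rep(1, nr + nl), b = rep(0, nr + nl),
      elesy = rep("C", nr + nl))
    invisible(list(path = path, planted = planted, coords = co, ligand = lig))
  })
}

## truncated log-normal above the threshold via inverse CDF
.rPassingFold <- function(n, meanlog, sdlog, threshold) {
  lo <- stats::plnorm(threshold, meanlog, sdlog)
  stats::qlnorm(runif(n, lo, 1), meanlog, sdlog)
}

#' Generate the curated mutation table
#'
#' Each planted position is reported by one or more families (the count
#' driven by `famSpread`), with records drawn against a shared modulator
#' pool; at least one guaranteed passing record per planted position, the
#' rest passing with `passProb` (passing folds are log-normal truncated
#' above the threshold, a fraction reported as qualitative "abolished").
#' Background records at non-site positions never pass: folds at most the
#' threshold, or "no_effect".  Deterministic under the spec seed.
#'
#' @param spec a [syntheticSpec()].
#' @param receptorSet output of [makeReceptorSet()].
#' @param planted generic positions to plant mutational evidence at.
#' @param seed stream seed; defaults to the spec seed.
#' @param guarantee when `TRUE` (default) the first record of every
#'   planted position is forced to pass, so the planted set is always
#'   recoverable; `FALSE` leaves every record to the `passProb` coin,
#'   useful for calibration checks.
#' @return data.frame of mutation records (valid under
#'   [validateMutationTable()]); `attr(, "ligandPool")` documents the
#'   modulator pool.
#' @export
makeMutationTable <- function(spec, receptorSet,
                              planted = spec$sitePositions,
                              seed = spec$seed, guarantee = TRUE) {
  anns <- receptorSet$annotations
  famMap <- receptorSet$familyMap
  planted <- sortGeneric(planted)
  .withSeed(seed + 104729L, {
    pool <- data.frame(
      ligand_id = sprintf("AM%03d", seq_len(spec$nLigands)),
      modality = sample(names(spec$modalityMix), spec$nLigands,
                        replace = TRUE, prob = spec$modalityMix),
      stringsAsFactors = FALSE)
    fams <- names(spec$families)
    recsOf <- split(names(famMap), unname(famMap))

    oneRecord <- function(rec, pos, lig, mustPass) {
      ann <- anns[[rec]]
      i <- genericToSeq(ann, pos)
      if (is.na(i)) return(NULL)
      wt <- substring(receptorSequence(ann), i, i)
      passing <- mustPass || runif(1) < spec$passProb
      abol <- passing && runif(1) < spec$abolishedProb
      fold <- if (abol) NA_real_
        else if (passing)
          .rPassingFold(1, spec$foldMeanLog, spec$foldSdLog, spec$threshold)
        else runif(1, 1, spec$threshold)
      qual <- if (abol) "abolished"
        else if (!passing && runif(1) < 0.3) "no_effect" else "none"
      if (qual == "no_effect") fold <- NA_real_
      data.frame(receptor_id = rec, family = famMap[[rec]], seq_index = i,
                 generic = pos, wt_aa = wt,
                 mut_aa = sample(setdiff(.AA, wt), 1L),
                 ligand_id = lig$ligand_id, modality = lig$modality,
                 assay = sample(.ASSAYS, 1L),
                 fold_effect = fold, qualitative = qual,
                 reference = sprintf("synthetic:%s", pos),
                 stringsAsFactors = FALSE)
    }

    rows <- list()
    for (pos in planted) {
      nf <- 1L + rbinom(1L, length(fams) - 1L, spec$famSpread)
      chosen <- sample(fams, nf)
      first <- guarantee
      for (f in chosen) {
        recs <- sample(recsOf[[f]], min(length(recsOf[[f]]),
                                        sample(1:3, 1L)))
        for (rec in recs) {
          nl <- sample(2:5, 1L)
          ligs <- pool[sample(nrow(pool), nl), , drop = FALSE]
          for (q in seq_len(nl)) {
            rows[[length(rows) + 1L]] <-
              oneRecord(rec, pos, ligs[q, ], mustPass = first)
            first <- FALSE
          }
        }
      }
    }

    ## sub-threshold background away from the site
    lay <- .segmentLayout()
    allPos <- unlist(lapply(seq_len(nrow(lay$segments)), function(k) {
      sg <- lay$segments[k, ]
      lo <- 50L - (sg$anchor_seq_index - sg$seq_start)
      genericPosition(sg$segment, lo:(lo + sg$seq_end - sg$seq_start))
    }))
    bgPos <- setdiff(allPos, planted)
    for (b in seq_len(spec$backgroundRecords)) {
      pos <- sample(bgPos, 1L)
      rec <- sample(names(famMap), 1L)
      lig <- pool[sample(nrow(pool), 1L), , drop = FALSE]
      r <- oneRecord(rec, pos, lig, mustPass = FALSE)
      if (is.null(r)) next
      if (r$qualitative == "abolished" ||
          (!is.na(r$fold_effect) && r$fold_effect > spec$threshold)) {
        r$qualitative <- "none"
        r$fold_effect <- runif(1, 1, spec$threshold)
      }
      rows[[length(rows) + 1L]] <- r
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    structure(out, ligandPool = pool)
  })
}

#' Generate a complete synthetic study
#'
#' Draws the receptor set, assigns each planted site position structural
#' and/or mutational evidence (per `evidenceMix`, with every position
#' guaranteed at least one evidence type), writes the modulator complexes
#' and the mutation table, and records the ground truth.
#'
#' @param spec a [syntheticSpec()].
#' @param dir directory for the PDB/FASTA/CSV artifacts; created if
#'   needed.
#' @return list with `spec`, `dir`, `receptorSet`, `structures`
#'   (data.frame: structure_id, receptor_id, chain, chain_offset,
#'   het_code, path, and list-column `planted`), `mutationTable`,
#'   `mutationPositions`, `structurePositions`, `planted` (the full site),
#'   `evidence` (named class per position).
#' @export
makeStudy <- function(spec, dir = tempfile("allosite_study_")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rs <- makeReceptorSet(spec)
  site <- spec$sitePositions
  recIds <- names(rs$familyMap)
  structRec <- spec$structureReceptors
  if (is.null(structRec)) {
    first2 <- recIds[seq_len(min(2L, length(recIds)))]
    structRec <- rep(first2, c(min(3L, spec$nStructures),
                               max(0L, spec$nStructures - 3L)))[
                                 seq_len(spec$nStructures)]
  }
  .withSeed(spec$seed + 15485863L, {
    evidence <- sample(names(spec$evidenceMix), length(site), replace = TRUE,
                       prob = spec$evidenceMix)
    names(evidence) <- site
    structPos <- site[evidence %in% c("both", "structure")]
    mutPos <- site[evidence %in% c("both", "mutation")]
    ## per-structure subsets covering all structural positions
    perStruct <- lapply(seq_along(structRec), function(k)
      structPos[runif(length(structPos)) < 0.85])
    uncovered <- setdiff(structPos, unlist(perStruct))
    for (p in uncovered) {
      k <- sample(length(perStruct), 1L)
      perStruct[[k]] <- c(perStruct[[k]], p)
    }
    perStruct <- lapply(perStruct, sortGeneric)
    structures <- data.frame(
      structure_id = sprintf("SYN%d", seq_along(structRec)),
      receptor_id = structRec, chain = "A", chain_offset = 0L,
      het_code = "LIG",
      path = file.path(dir, sprintf("SYN%d.pdb", seq_along(structRec))),
      stringsAsFactors = FALSE)
    structures$planted <- I(perStruct)
    for (k in seq_len(nrow(structures)))
      makeComplex(spec, rs$annotations[[structures$receptor_id[k]]],
                  perStruct[[k]], structures$path[k],
                  structureId = structures$structure_id[k],
                  chainOffset = structures$chain_offset[k],
                  seed = spec$seed + k)
    mut <- makeMutationTable(spec, rs, mutPos)

    writeAnnotations(rs$annotations, file.path(dir, "annotations.csv"),
                     file.path(dir, "receptors.fasta"))
    write.csv(data.frame(receptor_id = names(rs$familyMap),
                         family = unname(rs$familyMap)),
              file.path(dir, "families.csv"), row.names = FALSE)
    writeMutationTable(mut, file.path(dir, "mutations.csv"))
    write.csv(structures[, setdiff(names(structures), "planted")],
              file.path(dir, "structures.csv"), row.names = FALSE)

    list(spec = spec, dir = dir, receptorSet = rs, structures = structures,
         mutationTable = mut, mutationPositions = sortGeneric(mutPos),
         structurePositions = sortGeneric(structPos),
         planted = site, evidence = evidence)
  })
}
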