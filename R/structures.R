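## Structure parsing and the distance-rule contact extractor.
##
## A residue belongs to the allosteric contact set of a complex when its
## C-alpha or any side-chain heavy atom lies within the cutoff (default
## 5 Angstrom, inclusive) of any modulator atom.  Backbone N, C, O (and OXT)
## are never tested; Gly is testable through its C-alpha only.

.MAINCHAIN_NONCA <- c("N", "C", "O", "OXT")

#' Read a PDB complex into an atom table
#'
#' Parses ATOM/HETATM records (via bio3d), drops hydrogens, resolves
#' alternate locations by keeping the highest-occupancy copy of each atom
#' (ties broken towards altloc "A"), and attaches a sequence index computed
#' from author residue numbering through a per-chain constant offset
#' (`seq_index = resno + offset`).  Insertion codes are not supported.
#'
#' @param path PDB file.
#' @param chainOffsets named numeric vector: author-to-sequence numbering
#'   offset per receptor chain.  Chains absent from the vector (e.g. the
#'   ligand chain) get no sequence index.
#' @return data.frame with columns `type, chain, resno, seq_index, resid,
#'   elety, elesy, x, y, z, o, alt`.
#' @export
readStructure <- function(path, chainOffsets = c(A = 0)) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  if (any(!is.na(a$insert) & a$insert != ""))
    stop("insertion codes are not supported")
  elesy <- a$elesy
  guess <- is.na(elesy) | elesy == ""
  if (any(guess))  # infer element from the atom name when the column is blank
    elesy[guess] <- sub("^[0-9]*([A-Za-z]).*$", "\\1", a$elety[guess])
  keep <- toupper(elesy) != "H"
  a <- a[keep, , drop = FALSE]
  elesy <- toupper(elesy[keep])
  alt <- ifelse(is.na(a$alt) | a$alt == "", "A", a$alt)
  atoms <- data.frame(type = a$type, chain = a$chain, resno = a$resno,
                      resid = a$resid, elety = a$elety, elesy = elesy,
                      x = a$x, y = a$y, z = a$z,
                      o = ifelse(is.na(a$o), 1, a$o), alt = alt,
                      stringsAsFactors = FALSE)
  ## altloc resolution: within each (chain, resno, atom name) keep the
  ## highest-occupancy record; occupancy ties fall to the smallest altloc.
  ord <- order(atoms$chain, atoms$resno, atoms$elety, -atoms$o, atoms$alt)
  atoms <- atoms[ord, , drop = FALSE]
  key <- paste(atoms$chain, atoms$resno, atoms$elety, sep = "\r")
  atoms <- atoms[!duplicated(key), , drop = FALSE]
  offs <- chainOffsets
  bad <- setdiff(names(offs), unique(atoms$chain))
  if (length(bad))
    stop("offset table names unknown chain(s): ", paste(bad, collapse = ", "))
  m <- match(atoms$chain, names(offs))
  atoms$seq_index <- ifelse(is.na(m) | atoms$type != "ATOM",
                            NA_integer_,
                            as.integer(atoms$resno + unname(offs)[m]))
  rownames(atoms) <- NULL
  atoms
}

## ContactSet ---------------------------------------------------------------

#' ContactSet: generic positions in contact with a modulator
#'
#' @slot structureId identifier of the complex (e.g. a PDB code).
#' @slot receptorId receptor the contacts are expressed on.
#' @slot cutoff distance cutoff in Angstrom (inclusive).
#' @slot contacts data.frame with `generic, seq_index, resno, chain,
#'   min_dist, atom` (the receptor atom realizing the minimum distance).
#' @slot unmapped data.frame of in-contact residues that have no generic
#'   position under the receptor's annotation (reported, never dropped).
#' @export
setClass("ContactSet",
  representation(structureId = "character", receptorId = "character",
                 cutoff = "numeric", contacts = "data.frame",
                 unmapped = "data.frame"))

setValidity("ContactSet", function(object) {
  if (length(object@cutoff) != 1L || object@cutoff <= 0)
    return("cutoff must be a single positive number")
  if (anyDuplicated(object@contacts$generic))
    return("duplicated generic position in contact table")
  TRUE
})


#' @export
setMethod("sitePositions", "ContactSet",
          function(object) sortGeneric(object@contacts$generic))


#' @export
setMethod("contactTable", "ContactSet", function(object) object@contacts)

setMethod("show", "ContactSet", function(object) {
  cat(sprintf("ContactSet %s on %s: %d positions within %.1f A",
              object@structureId, object@receptorId,
              nrow(object@contacts), object@cutoff))
  if (nrow(object@unmapped)) cat(sprintf(" (+%d unmapped)", nrow(object@unmapped)))
  cat("\n")
})

#' Extract modulator-contact residues from a complex
#'
#' Applies the distance rule: a receptor residue is in contact when the
#' minimum distance between its tested atoms (C-alpha plus side-chain heavy
#' atoms; backbone N/C/O/OXT excluded) and any modulator atom is less than
#' or equal to `cutoff`.  Distances are computed on unrounded coordinates
#' and the boundary is inclusive.  In-contact residues that cannot be
#' mapped to a generic position are collected in the `unmapped` slot and
#' signalled with a warning.
#'
#' @param atoms atom table from [readStructure()].
#' @param ligand list with `het_code` (3-letter residue name of the
#'   modulator) and optionally `chain`.
#' @param ann the receptor's [ReceptorAnnotation-class].
#' @param cutoff contact cutoff in Angstrom; default 5.
#' @param structureId label stored in the result.
#' @param chains receptor chains to scan; default: all chains with a
#'   sequence index.
#' @return a [ContactSet-class].
#' @export
contactPositions <- function(atoms, ligand, ann, cutoff = 5.0,
                             structureId = "structure", chains = NULL) {
  stopifnot(is.list(ligand), !is.null(ligand$het_code), cutoff > 0)
  lig <- atoms$type == "HETATM" & atoms$resid == ligand$het_code
  if (!is.null(ligand$chain)) lig <- lig & atoms$chain %in% ligand$chain
  if (!any(lig)) stop("ligand ", ligand$het_code, " not found in structure")
  lxyz <- as.matrix(atoms[lig, c("x", "y", "z")])

  rec <- atoms$type == "ATOM" & !is.na(atoms$seq_index)
  if (!is.null(chains)) rec <- rec & atoms$chain %in% chains
  tested <- rec & !(atoms$elety %in% .MAINCHAIN_NONCA)
  ta <- atoms[tested, , drop = FALSE]
  if (!nrow(ta)) stop("no testable receptor atoms found")
  txyz <- as.matrix(ta[, c("x", "y", "z")])

  ## all-pairs squared distances, tested atoms x ligand atoms
  d2 <- outer(rowSums(txyz^2), rowSums(lxyz^2), "+") - 2 * txyz %*% t(lxyz)
  dmin <- sqrt(pmax(apply(d2, 1, min), 0))

  key <- paste(ta$chain, ta$seq_index, sep = "\r")
  best <- vapply(split(seq_along(dmin), key),
                 function(i) i[which.min(dmin[i])], integer(1))
  res <- data.frame(chain = ta$chain[best], seq_index = ta$seq_index[best],
                    resno = ta$resno[best], atom = ta$elety[best],
                    min_dist = dmin[best], stringsAsFactors = FALSE)
  res <- res[res$min_dist <= cutoff, , drop = FALSE]
  res$generic <- assignGeneric(ann, res$seq_index)

  unmapped <- res[is.na(res$generic), , drop = FALSE]
  if (nrow(unmapped))
    warning(sprintf("%d in-contact residue(s) have no generic position (%s)",
                    nrow(unmapped),
                    paste(unique(unmapped$seq_index), collapse = ",")))
  res <- res[!is.na(res$generic), , drop = FALSE]
  ## two protomers: per-chain contacts union to one position set, keeping
  ## the overall minimum distance
  res <- res[order(res$generic, res$min_dist), , drop = FALSE]
  res <- res[!duplicated(res$generic), , drop = FALSE]
  res <- res[, c("generic", "seq_index", "resno", "chain", "min_dist", "atom")]
  rownames(res) <- NULL
  new("ContactSet", structureId = structureId, receptorId = receptorId(ann),
      cutoff = cutoff, contacts = res,
      unmapped = unmapped[, setdiff(names(unmapped), "generic"), drop = FALSE])
}

#' Union of contact sets across structures
#'
#' @param contactSets list of [ContactSet-class] objects sharing one cutoff.
#' @return data.frame with one row per generic position: `generic,
#'   n_structures, structures, receptors, min_dist`; `structures` and
#'   `receptors` are list-columns recording provenance.
#' @export
unionContacts <- function(contactSets) {
  stopifnot(length(contactSets) >= 1L,
            all(vapply(contactSets, is, TRUE, "ContactSet")))
  cuts <- vapply(contactSets, function(cs) cs@cutoff, 0)
  if (length(unique(cuts)) != 1L)
    stop("contact sets computed at different cutoffs cannot be unioned")
  rows <- do.call(rbind, lapply(contactSets, function(cs) {
    if (!nrow(cs@contacts)) return(NULL)
    data.frame(generic = cs@contacts$generic,
               structure = cs@structureId, receptor = cs@receptorId,
               min_dist = cs@contacts$min_dist, stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    return(data.frame(generic = character(0), n_structures = integer(0),
                      structures = I(list()), receptors = I(list()),
                      min_dist = numeric(0)))
  sp <- split(rows, rows$generic)
  out <- data.frame(generic = names(sp),
                    n_structures = vapply(sp, function(g)
                      length(unique(g$structure)), 0L),
                    structures = I(lapply(sp, function(g) sort(unique(g$structure)))),
                    receptors = I(lapply(sp, function(g) sort(unique(g$receptor)))),
                    min_dist = vapply(sp, function(g) min(g$min_dist), 0),
                    stringsAsFactors = FALSE)
  out <- out[match(sortGeneric(out$generic), out$generic), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a contact set to CSV
#'
#' @param cs a [ContactSet-class].
#' @param path output CSV.
#' @export
writeContactSet <- function(cs, path) {
  tab <- cbind(structure_id = cs@structureId, receptor_id = cs@receptorId,
               cutoff = cs@cutoff, cs@contacts)
  write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
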