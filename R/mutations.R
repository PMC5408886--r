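## Curated single-point mutagenesis records and the >5-fold effect rule.
##
## One record is one mutant x one modulator measurement.  fold_effect is a
## direction-agnostic magnitude (>= 1); a record may instead carry a
## qualitative outcome ("abolished" or "no_effect").  A position is called
## a potential modulator contact when any of its measurements shows a
## greater-than-threshold fold change (strict) or abolished the response.

.MUTATION_COLS <- c("receptor_id", "family", "seq_index", "generic",
                    "wt_aa", "mut_aa", "ligand_id", "modality", "assay",
                    "fold_effect", "qualitative", "reference")
.MODALITIES <- c("PAM", "NAM", "agonist", "other")
.ASSAYS <- c("binding", "function")

#' Validate mutation records
#'
#' @param tab data.frame in the mutation-table layout.
#' @return list with `records` (valid rows) and `rejected` (rows failing an
#'   invariant, with a `reject_reason` column).
#' @export
validateMutationTable <- function(tab) {
  missing <- setdiff(.MUTATION_COLS, names(tab))
  if (length(missing))
    stop("mutation table missing column(s): ", paste(missing, collapse = ", "))
  tab <- tab[, .MUTATION_COLS, drop = FALSE]
  tab$seq_index <- as.integer(tab$seq_index)
  tab$fold_effect <- suppressWarnings(as.numeric(tab$fold_effect))
  tab$qualitative <- as.character(tab$qualitative)
  tab$generic <- as.character(tab$generic)
  tab$qualitative[is.na(tab$qualitative)] <- "none"
  tab$qualitative[tab$qualitative == ""] <- "none"

  reason <- rep(NA_character_, nrow(tab))
  bad <- function(cond, why) reason <<- ifelse(is.na(reason) & cond, why, reason)
  bad(tab$wt_aa == tab$mut_aa, "wt_aa equals mut_aa")
  bad(!tab$modality %in% .MODALITIES, "unknown modality")
  bad(!tab$assay %in% .ASSAYS, "unknown assay")
  bad(!tab$qualitative %in% c("none", "abolished", "no_effect"),
      "unknown qualitative value")
  bad(!is.na(tab$fold_effect) & tab$fold_effect < 1,
      "fold_effect below 1 (store magnitudes)")
  ## exactly one of fold_effect / qualitative must be informative
  hasFold <- !is.na(tab$fold_effect)
  hasQual <- tab$qualitative %in% c("abolished", "no_effect")
  bad(!hasFold & !hasQual, "neither fold_effect nor qualitative given")
  bad(hasFold & hasQual, "both fold_effect and qualitative given")
  bad(grepl("x", tab$generic) & !grepl(.GENERIC_RE, tab$generic),
      "malformed generic position")

  ok <- is.na(reason)
  rejected <- tab[!ok, , drop = FALSE]
  if (nrow(rejected)) rejected$reject_reason <- reason[!ok]
  list(records = tab[ok, , drop = FALSE], rejected = rejected)
}

#' Read a mutation table from CSV
#'
#' Invalid rows are not fatal: they are collected in the `rejected`
#' attribute (with reasons) and a warning summarises the count.
#'
#' @param path CSV with header
#'   `receptor_id,family,seq_index,generic,wt_aa,mut_aa,ligand_id,modality,assay,fold_effect,qualitative,reference`.
#' @return data.frame of valid records; `attr(, "rejected")` holds the rest.
#' @export
readMutationTable <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  v <- validateMutationTable(tab)
  if (nrow(v$rejected))
    warning(nrow(v$rejected), " invalid mutation record(s) rejected")
  structure(v$records, rejected = v$rejected)
}

#' Write a mutation table to CSV
#' @param records mutation records data.frame.
#' @param path output CSV.
#' @export
writeMutationTable <- function(records, path) {
  write.csv(records[, .MUTATION_COLS, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' Call the effect of each mutation record
#'
#' A record passes when `fold_effect > threshold` (strictly) or the
#' response was abolished; a fold of exactly the threshold fails.
#' "no_effect" never passes at any threshold.
#'
#' @param records mutation records data.frame.
#' @param threshold fold-change threshold; default 5.
#' @return the records with two added columns: `passes` (logical) and
#'   `reason` (one of `fold_gt_threshold`, `abolished`, `below_threshold`,
#'   `no_effect`).
#' @export
callEffect <- function(records, threshold = 5.0) {
  stopifnot(threshold > 0)
  fold <- records$fold_effect
  qual <- records$qualitative
  reason <- ifelse(qual == "abolished", "abolished",
            ifelse(qual == "no_effect", "no_effect",
            ifelse(!is.na(fold) & fold > threshold,
                   "fold_gt_threshold", "below_threshold")))
  records$passes <- reason %in% c("fold_gt_threshold", "abolished")
  records$reason <- reason
  records
}

#' Summarise passing evidence per generic position
#'
#' Only passing calls contribute.  Counting is by distinct entity: two
#' assays of the same ligand at a position count one ligand.
#'
#' @param records mutation records data.frame.
#' @param threshold fold-change threshold passed to [callEffect()].
#' @return data.frame keyed by `generic` with `n_receptors, n_families,
#'   n_ligands` and list-columns `receptors, families, ligands, modalities`.
#' @export
effectPositions <- function(records, threshold = 5.0) {
  called <- callEffect(records, threshold)
  hit <- called[called$passes & !is.na(called$generic) & called$generic != "",
                , drop = FALSE]
  if (!nrow(hit))
    return(data.frame(generic = character(0), n_receptors = integer(0),
                      n_families = integer(0), n_ligands = integer(0),
                      receptors = I(list()), families = I(list()),
                      ligands = I(list()), modalities = I(list())))
  sp <- split(hit, hit$generic)
  out <- data.frame(
    generic = names(sp),
    n_receptors = vapply(sp, function(g) length(unique(g$receptor_id)), 0L),
    n_families = vapply(sp, function(g) length(unique(g$family)), 0L),
    n_ligands = vapply(sp, function(g) length(unique(g$ligand_id)), 0L),
    receptors = I(lapply(sp, function(g) sort(unique(g$receptor_id)))),
    families = I(lapply(sp, function(g) sort(unique(g$family)))),
    ligands = I(lapply(sp, function(g) sort(unique(g$ligand_id)))),
    modalities = I(lapply(sp, function(g) sort(unique(g$modality)))),
    stringsAsFactors = FALSE)
  out <- out[match(sortGeneric(out$generic), out$generic), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Report conflicting duplicate measurements
#'
#' Finds mutant x ligand combinations reported more than once with
#' disagreeing calls (one passing, one not); such conflicts are kept in the
#' data and surfaced here rather than silently reconciled.
#'
#' @param records mutation records data.frame.
#' @param threshold fold-change threshold.
#' @return data.frame of conflicting records (possibly empty).
#' @export
conflictReport <- function(records, threshold = 5.0) {
  called <- callEffect(records, threshold)
  key <- paste(called$receptor_id, called$seq_index, called$mut_aa,
               called$ligand_id, sep = "\r")
  sp <- split(seq_len(nrow(called)), key)
  idx <- unlist(sp[vapply(sp, function(i)
    length(unique(called$passes[i])) > 1L, TRUE)], use.names = FALSE)
  out <- called[sort(idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}
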