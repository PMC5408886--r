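## Physicochemical column conservation across receptors at site positions.

#' Default physicochemical property scheme
#'
#' Maps each standard amino acid to one or more side-chain property
#' classes.  His is counted as aromatic (imidazole ring) as well as polar
#' and positive; Tyr is aromatic and polar.  The scheme is a plain named
#' list and can be replaced wholesale.
#'
#' @return named list: one-letter code to character vector of classes from
#'   `aromatic, aliphatic, polar, positive, negative, small, gly, pro`.
#' @export
propertyScheme <- function() {
  list(A = c("aliphatic", "small"),
       C = c("polar", "small"),
       D = "negative",
       E = "negative",
       F = "aromatic",
       G = c("gly", "small"),
       H = c("aromatic", "polar", "positive"),
       I = "aliphatic",
       K = "positive",
       L = "aliphatic",
       M = "aliphatic",
       N = "polar",
       P = "pro",
       Q = "polar",
       R = "positive",
       S = c("polar", "small"),
       T = c("polar", "small"),
       V = "aliphatic",
       W = "aromatic",
       Y = c("aromatic", "polar"))
}

#' Gather the alignment column for a generic position
#'
#' Looks the position up per receptor through its annotation
#' ([genericToSeq()]); receptors whose annotated segment does not reach the
#' position are recorded as gaps.
#'
#' @param anns named list of [ReceptorAnnotation-class] objects.
#' @param pos one generic position.
#' @param scheme property scheme, see [propertyScheme()].
#' @return list with `generic`, `residues` (named character, `-` for
#'   gaps) and `class_fractions` (over non-gap entries).
#' @export
columnForPosition <- function(anns, pos, scheme = propertyScheme()) {
  stopifnot(length(pos) == 1L)
  res <- vapply(anns, function(a) {
    r <- residueAt(a, pos)
    if (is.na(r)) "-" else r
  }, "")
  if (all(res == "-"))
    stop("position ", pos, " is mappable in no receptor")
  nong <- res[res != "-"]
  classes <- sort(unique(unlist(scheme)))
  frac <- vapply(classes, function(cl)
    mean(vapply(nong, function(r) cl %in% scheme[[r]], TRUE)), 0)
  list(generic = pos, residues = res, class_fractions = frac)
}

#' Property conservation of a column
#'
#' Percentage of receptors whose residue at the position belongs to the
#' class.  With `denominator = "nongap"` receptors lacking the position
#' are excluded; with `"all"` they count as non-matching.  The displayed
#' figure is rounded half-up to an integer; the unrounded value is kept.
#'
#' @param col a column profile from [columnForPosition()].
#' @param cls one property class.
#' @param scheme property scheme.
#' @param denominator `"nongap"` or `"all"`.
#' @return list with `percent` (unrounded) and `display` (integer).
#' @export
propertyConservation <- function(col, cls, scheme = propertyScheme(),
                                 denominator = c("nongap", "all")) {
  denominator <- match.arg(denominator)
  res <- col$residues
  nong <- res[res != "-"]
  if (!length(nong)) stop("all-gap column: conservation undefined")
  hit <- sum(vapply(nong, function(r) cls %in% scheme[[r]], TRUE))
  den <- if (denominator == "nongap") length(nong) else length(res)
  pct <- 100 * hit / den
  list(percent = pct, display = roundHalfUp(pct))
}

#' Conservation report over a set of positions
#'
#' @param anns named list of [ReceptorAnnotation-class] objects.
#' @param positions generic positions to profile.
#' @param scheme property scheme.
#' @return data.frame, one row per position: residues, non-gap count, and
#'   the unrounded percentage of each class under both denominators
#'   (`pct_<class>` over non-gap receptors, `pct_<class>_all` over all).
#' @export
conservationReport <- function(anns, positions, scheme = propertyScheme()) {
  classes <- sort(unique(unlist(scheme)))
  rows <- lapply(positions, function(p) {
    col <- columnForPosition(anns, p, scheme)
    nong <- sum(col$residues != "-")
    v <- setNames(100 * col$class_fractions[classes], paste0("pct_", classes))
    vAll <- setNames(v * nong / length(col$residues),
                     paste0("pct_", classes, "_all"))
    cbind(data.frame(generic = p,
                     residues = paste(col$residues, collapse = ""),
                     n_nongap = nong, stringsAsFactors = FALSE),
          as.data.frame(as.list(c(v, vAll))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise identity over site columns
#'
#' @param seqA,seqB equal-length strings of residues at a common column
#'   set (gaps `-` where a receptor lacks the position).
#' @return percentage identity over columns that are non-gap in both.
#' @export
siteSimilarity <- function(seqA, seqB) {
  a <- strsplit(toupper(seqA), "")[[1]]
  b <- strsplit(toupper(seqB), "")[[1]]
  if (length(a) != length(b)) stop("column sets differ in length")
  if (!length(a)) stop("empty column set")
  keep <- a != "-" & b != "-"
  if (!any(keep)) stop("no columns comparable in both receptors")
  100 * sum(a[keep] == b[keep]) / sum(keep)
}

#' Extract the site-column alignment
#'
#' Builds, per receptor, the string of residues at the given generic
#' positions (gap where unmapped) -- the input for the site tree and for
#' [siteSimilarity()].
#'
#' @param anns named list of [ReceptorAnnotation-class] objects.
#' @param positions generic positions (ordered with [sortGeneric()]).
#' @return named character vector of equal-length sequences.
#' @export
siteAlignment <- function(anns, positions) {
  positions <- sortGeneric(positions)
  vapply(anns, function(a) {
    r <- residueAt(a, positions)
    paste(ifelse(is.na(r), "-", r), collapse = "")
  }, "")
}
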