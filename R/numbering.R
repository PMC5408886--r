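#' @import methods
#' @importFrom stats setNames rnorm runif rbinom
#' @importFrom utils read.csv write.csv
NULL

## Generic residue positions ------------------------------------------------
##
## A generic position labels a residue by its segment (TM1..TM7 -> codes 1..7,
## loops by two-digit codes, e.g. ECL2 = 45) and an index relative to the
## segment's most conserved residue, which carries index 50.  The canonical
## string form is "<segment>x<index>", e.g. "6x50" or "45x52".

.GENERIC_RE <- "^([0-9]{1,2})x([0-9]{1,2})$"

#' Build canonical generic-position strings
#'
#' @param segment integer segment code(s): 1-7 for TM1-TM7, two-digit codes
#'   for loops (ECL2 = 45).
#' @param index integer index/indices in 1-99 (50 marks the segment anchor).
#' @return character vector of canonical `"<segment>x<index>"` labels.
#' @examples
#' genericPosition(6, 50)
#' genericPosition(45, 52)
#' @export
genericPosition <- function(segment, index) {
  segment <- as.integer(segment)
  index <- as.integer(index)
  if (any(is.na(segment)) || any(is.na(index)))
    stop("segment and index must be integers")
  if (any(index < 1L | index > 99L))
    stop("generic index must be in 1-99")
  if (any(segment < 1L | segment > 99L))
    stop("segment code must be in 1-99")
  paste0(segment, "x", index)
}

#' Parse generic-position strings
#'
#' @param x character vector of `"<segment>x<index>"` labels.
#' @return data.frame with columns `generic`, `segment`, `index`.
#' @examples
#' parseGeneric(c("6x50", "45x52"))
#' @export
parseGeneric <- function(x) {
  x <- as.character(x)
  ok <- grepl(.GENERIC_RE, x)
  if (!all(ok))
    stop("malformed generic position(s): ", paste(x[!ok], collapse = ", "))
  seg <- as.integer(sub(.GENERIC_RE, "\\1", x))
  idx <- as.integer(sub(.GENERIC_RE, "\\2", x))
  if (any(idx < 1L | idx > 99L))
    stop("generic index out of 1-99")
  data.frame(generic = x, segment = seg, index = idx,
             stringsAsFactors = FALSE)
}

#' Order generic positions by (segment, index)
#'
#' @param x character vector of generic positions.
#' @return `x` sorted by segment code, then index.
#' @export
sortGeneric <- function(x) {
  if (length(x) == 0L) return(character(0))
  p <- parseGeneric(x)
  x[order(p$segment, p$index)]
}

## ReceptorAnnotation -------------------------------------------------------

#' ReceptorAnnotation: segment bounds and anchors for one receptor
#'
#' Holds the amino-acid sequence of one receptor together with the segment
#' table that drives generic numbering: each row gives a segment code, its
#' 1-based inclusive sequence range, and the anchor residue whose generic
#' index is 50.  Segments must not overlap and each has exactly one anchor.
#'
#' @slot receptorId single receptor identifier.
#' @slot sequence one-letter amino-acid string.
#' @slot segments data.frame with columns `segment` (integer code),
#'   `seq_start`, `seq_end`, `anchor_seq_index` (all 1-based inclusive).
#' @export
setClass("ReceptorAnnotation",
  representation(receptorId = "character",
                 sequence = "character",
                 segments = "data.frame"))

setValidity("ReceptorAnnotation", function(object) {
  msg <- character(0)
  if (length(object@receptorId) != 1L) msg <- c(msg, "receptorId must be length 1")
  if (length(object@sequence) != 1L) msg <- c(msg, "sequence must be length 1")
  seg <- object@segments
  need <- c("segment", "seq_start", "seq_end", "anchor_seq_index")
  if (!all(need %in% names(seg)))
    return(paste("segments must have columns", paste(need, collapse = ", ")))
  n <- nchar(object@sequence)
  if (nrow(seg)) {
    if (any(seg$seq_start > seg$seq_end)) msg <- c(msg, "seq_start > seq_end")
    if (any(seg$seq_start < 1L) || any(seg$seq_end > n))
      msg <- c(msg, "segment outside sequence bounds")
    if (any(seg$anchor_seq_index < seg$seq_start |
            seg$anchor_seq_index > seg$seq_end))
      msg <- c(msg, "anchor outside its segment")
    if (anyDuplicated(seg$segment)) msg <- c(msg, "duplicated segment code")
    o <- order(seg$seq_start)
    if (any(seg$seq_start[o][-1] <= seg$seq_end[o][-nrow(seg)]))
      msg <- c(msg, "segments overlap")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ReceptorAnnotation
#'
#' @param receptorId receptor identifier.
#' @param sequence one-letter amino-acid string.
#' @param segments data.frame with columns `segment`, `seq_start`,
#'   `seq_end`, `anchor_seq_index`.
#' @return a [ReceptorAnnotation-class] object.
#' @export
ReceptorAnnotation <- function(receptorId, sequence, segments) {
  segments <- as.data.frame(segments)
  segments$segment <- as.integer(segments$segment)
  segments$seq_start <- as.integer(segments$seq_start)
  segments$seq_end <- as.integer(segments$seq_end)
  segments$anchor_seq_index <- as.integer(segments$anchor_seq_index)
  new("ReceptorAnnotation", receptorId = as.character(receptorId),
      sequence = toupper(as.character(sequence)), segments = segments)
}


#' @export
setMethod("receptorId", "ReceptorAnnotation", function(object) object@receptorId)


#' @export
setMethod("segments", "ReceptorAnnotation", function(object) object@segments)


#' @export
setMethod("receptorSequence", "ReceptorAnnotation", function(object) object@sequence)

setMethod("show", "ReceptorAnnotation", function(object) {
  cat("ReceptorAnnotation:", object@receptorId,
      sprintf("(%d aa, %d segments)\n",
              nchar(object@sequence), nrow(object@segments)))
})

#' Map a sequence position to its generic position
#'
#' A residue inside an annotated segment gets generic index
#' `50 + (seq_index - anchor_seq_index)`; loop indices below 50 count
#' backwards from the anchor with the same arithmetic (e.g. the residue
#' before the conserved ECL2 Cys 45x50 is 45x49).  Residues outside every
#' annotated segment have no generic position.
#'
#' @param ann a [ReceptorAnnotation-class].
#' @param seqIndex 1-based sequence position(s).
#' @return character vector of generic positions, `NA` where the residue
#'   falls in no annotated segment.
#' @examples
#' ann <- ReceptorAnnotation("r1", strrep("A", 30),
#'   data.frame(segment = 6, seq_start = 5, seq_end = 25, anchor_seq_index = 15))
#' assignGeneric(ann, 18)  # "6x53"
#' @export
assignGeneric <- function(ann, seqIndex) {
  stopifnot(is(ann, "ReceptorAnnotation"))
  seqIndex <- as.integer(seqIndex)
  n <- nchar(ann@sequence)
  if (any(is.na(seqIndex)) || any(seqIndex < 1L | seqIndex > n))
    stop("seqIndex outside sequence bounds (1-", n, ")")
  seg <- ann@segments
  out <- rep(NA_character_, length(seqIndex))
  for (k in seq_len(nrow(seg))) {
    hit <- seqIndex >= seg$seq_start[k] & seqIndex <= seg$seq_end[k]
    if (any(hit)) {
      idx <- 50L + (seqIndex[hit] - seg$anchor_seq_index[k])
      if (any(idx < 1L | idx > 99L))
        stop("annotation inconsistency: generic index outside 1-99 in segment ",
             seg$segment[k])
      out[hit] <- genericPosition(seg$segment[k], idx)
    }
  }
  out
}

#' Map a generic position back to a sequence position
#'
#' Inverse of [assignGeneric()] on the annotated range: returns `NA` when
#' the receptor has no such segment or its segment does not extend to the
#' requested index (e.g. 45x54 on a receptor whose ECL2 ends at 45x53).
#'
#' @param ann a [ReceptorAnnotation-class].
#' @param pos character vector of generic positions.
#' @return integer vector of 1-based sequence positions (`NA` where
#'   unmapped).
#' @export
genericToSeq <- function(ann, pos) {
  stopifnot(is(ann, "ReceptorAnnotation"))
  p <- parseGeneric(pos)
  seg <- ann@segments
  out <- rep(NA_integer_, nrow(p))
  m <- match(p$segment, seg$segment)
  has <- !is.na(m)
  if (any(has)) {
    i <- seg$anchor_seq_index[m[has]] + (p$index[has] - 50L)
    inside <- i >= seg$seq_start[m[has]] & i <= seg$seq_end[m[has]]
    out[has][inside] <- i[inside]
  }
  out
}

#' Residue letter at a generic position
#'
#' @param ann a [ReceptorAnnotation-class].
#' @param pos generic position(s).
#' @return one-letter code(s), `NA` where the position is unmapped.
#' @export
residueAt <- function(ann, pos) {
  i <- genericToSeq(ann, pos)
  out <- rep(NA_character_, length(i))
  ok <- !is.na(i)
  if (any(ok))
    out[ok] <- substring(ann@sequence, i[ok], i[ok])
  out
}

#' Read receptor annotations from CSV + FASTA
#'
#' The CSV must have columns `receptor_id, segment, seq_start, seq_end,
#' anchor_seq_index`; sequences come from a FASTA whose record names match
#' `receptor_id` (gaps in the FASTA are dropped, so aligned files work).
#'
#' @param csvPath path to the segment table.
#' @param fastaPath path to the receptor sequences.
#' @return named list of [ReceptorAnnotation-class] objects.
#' @export
readAnnotations <- function(csvPath, fastaPath) {
  tab <- read.csv(csvPath, stringsAsFactors = FALSE)
  need <- c("receptor_id", "segment", "seq_start", "seq_end", "anchor_seq_index")
  if (!all(need %in% names(tab)))
    stop("annotation table must have columns ", paste(need, collapse = ", "))
  seqs <- Biostrings::readAAStringSet(fastaPath)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  ids <- unique(tab$receptor_id)
  missing <- setdiff(ids, names(seqs))
  if (length(missing))
    stop("no FASTA record for receptor(s): ", paste(missing, collapse = ", "))
  setNames(lapply(ids, function(id) {
    s <- gsub("-", "", as.character(seqs[[id]]), fixed = TRUE)
    ReceptorAnnotation(id, s,
                       tab[tab$receptor_id == id, need[-1], drop = FALSE])
  }), ids)
}

#' Write receptor annotations to CSV + FASTA
#'
#' @param anns named list of [ReceptorAnnotation-class] objects.
#' @param csvPath,fastaPath output paths.
#' @return invisibly, the segment table written.
#' @export
writeAnnotations <- function(anns, csvPath, fastaPath) {
  tab <- do.call(rbind, lapply(anns, function(a)
    cbind(receptor_id = a@receptorId, a@segments)))
  write.csv(tab, csvPath, row.names = FALSE)
  seqs <- Biostrings::AAStringSet(vapply(anns, receptorSequence, ""))
  names(seqs) <- vapply(anns, receptorId, "")
  Biostrings::writeXStringSet(seqs, fastaPath)
  invisible(tab)
}
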