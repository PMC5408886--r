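## Protein distance matrices and UPGMA trees.
##
## Distances are alignment-based: columns gapped in either sequence are
## excluded, p = mismatches / compared columns; the Poisson correction
## -ln(1 - p) is available for multiple hits.  Trees are built by UPGMA
## (average linkage weighted by cluster size) with a deterministic
## lexicographic tie rule, and returned as rooted ultrametric ape "phylo"
## objects whose node heights equal merge distance / 2.

.P_CAP <- 0.95

#' Pairwise distance between two aligned sequences
#'
#' @param seqA,seqB equal-length aligned amino-acid strings (gaps `-` or
#'   `.`).
#' @param model `"p_distance"` (raw mismatch fraction) or `"poisson"`
#'   (`-ln(1-p)`, multiple-hit corrected).
#' @param cap proportions above this are capped (with a warning) before
#'   the Poisson transform to avoid infinite distances; default 0.95.
#' @return nonnegative distance.
#' @examples
#' pairwiseDistance("ACDEFGHIKL", "ACDEFGHIKV", model = "poisson")
#' @export
pairwiseDistance <- function(seqA, seqB,
                             model = c("p_distance", "poisson"),
                             cap = .P_CAP) {
  model <- match.arg(model)
  a <- strsplit(toupper(seqA), "")[[1]]
  b <- strsplit(toupper(seqB), "")[[1]]
  if (length(a) != length(b))
    stop("sequences must be aligned to equal length")
  keep <- !(a %in% c("-", ".")) & !(b %in% c("-", "."))
  if (!any(keep))
    stop("no comparable columns: distance undefined")
  p <- sum(a[keep] != b[keep]) / sum(keep)
  if (model == "p_distance") return(p)
  if (p >= cap) {
    warning(sprintf("proportion %.3f capped at %.2f for Poisson correction",
                    p, cap))
    p <- cap
  }
  -log(1 - p)
}

#' Distance matrix over an alignment
#'
#' @param aln named character vector or `Biostrings::AAStringSet` of
#'   equal-length aligned sequences.
#' @param model distance model, see [pairwiseDistance()].
#' @return symmetric labelled matrix with zero diagonal.
#' @export
distanceMatrix <- function(aln, model = c("p_distance", "poisson")) {
  model <- match.arg(model)
  if (is(aln, "XStringSet")) aln <- setNames(as.character(aln), names(aln))
  n <- length(aln)
  if (is.null(names(aln)) || anyDuplicated(names(aln)))
    stop("alignment needs unique sequence names")
  d <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      d[i, j] <- d[j, i] <- pairwiseDistance(aln[[i]], aln[[j]], model)
  d
}

.checkDistanceMatrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("distance matrix must be square")
  if (is.null(rownames(d)) || !identical(rownames(d), colnames(d)))
    stop("distance matrix must carry matching row/column labels")
  if (any(!is.finite(d)) || any(d < 0)) stop("distances must be finite and >= 0")
  if (any(abs(d - t(d)) > 1e-12)) stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("diagonal must be zero")
  invisible(d)
}

#' UPGMA tree from a distance matrix
#'
#' Iteratively merges the closest pair of clusters; the distance from a
#' merged cluster to any other is the size-weighted arithmetic average of
#' its parts' distances, so every cluster-cluster distance equals the mean
#' over all member pairs of the input matrix.  Node height is half the
#' merge distance, giving an ultrametric rooted tree.  Ties on the minimum
#' distance are broken towards the lexicographically smallest pair of
#' cluster labels (a cluster is labelled by its alphabetically first
#' taxon), so output is deterministic and independent of input order.
#'
#' @param d labelled symmetric distance matrix (>= 2 taxa).
#' @return a rooted ultrametric `ape::phylo` tree.
#' @examples
#' d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' tr <- upgma(d)
#' @export
upgma <- function(d) {
  .checkDistanceMatrix(d)
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 taxa")
  taxa <- rownames(d)

  D <- d
  active <- seq_len(n)              # indices into bookkeeping vectors
  size <- rep(1L, n)
  label <- taxa                     # alphabetically first member taxon
  node <- -seq_len(n)               # hclust convention: negatives = leaves
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    m <- length(active)
    ## locate the minimum over pairs of active clusters
    dmin <- Inf
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      v <- D[active[i], active[j]]
      if (v < dmin) dmin <- v
    }
    ## tie rule: smallest (sorted) label pair among the minima
    bi <- bj <- 0L; bkey <- NULL
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      if (D[active[i], active[j]] != dmin) next
      key <- sort(c(label[active[i]], label[active[j]]))
      if (is.null(bkey) || key[1] < bkey[1] ||
          (key[1] == bkey[1] && key[2] < bkey[2])) {
        bkey <- key; bi <- active[i]; bj <- active[j]
      }
    }
    merge[step, ] <- sort(c(node[bi], node[bj]))
    height[step] <- dmin
    ## fold bj into bi with size-weighted averages
    for (k in setdiff(active, c(bi, bj))) {
      v <- (size[bi] * D[bi, k] + size[bj] * D[bj, k]) / (size[bi] + size[bj])
      D[bi, k] <- D[k, bi] <- v
    }
    size[bi] <- size[bi] + size[bj]
    label[bi] <- min(label[bi], label[bj])
    node[bi] <- step
    active <- setdiff(active, bj)
  }

  hc <- structure(list(merge = merge, height = height,
                       order = .hclustOrder(merge, n), labels = taxa,
                       method = "average", call = match.call(),
                       dist.method = "user"),
                  class = "hclust")
  ape::as.phylo(hc)
}

## leaf order for the hclust object (left-to-right traversal of merges)
.hclustOrder <- function(merge, n) {
  expand <- function(k)
    if (k < 0L) -k else c(expand(merge[k, 1L]), expand(merge[k, 2L]))
  expand(nrow(merge))
}

#' Height of every leaf below the root
#'
#' Convenience for ultrametricity checks.
#' @param tree an `ape::phylo`.
#' @return named numeric vector of root-to-tip path lengths.
#' @export
leafDepths <- function(tree) {
  d <- ape::node.depth.edgelength(tree)
  setNames(d[seq_along(tree$tip.label)], tree$tip.label)
}

#' Family coherence (monophyly) in a rooted tree
#'
#' A family is coherent when some subtree's leaf set equals exactly the
#' family's member set; singleton families are trivially coherent.
#'
#' @param tree a rooted `ape::phylo`.
#' @param familyMap named character vector mapping every tip label to a
#'   family.
#' @return named logical vector, one entry per family.
#' @export
familyCoherence <- function(tree, familyMap) {
  tips <- tree$tip.label
  missing <- setdiff(tips, names(familyMap))
  if (length(missing))
    stop("no family for leaf/leaves: ", paste(missing, collapse = ", "))
  clades <- lapply(ape::prop.part(tree), function(i) sort(tips[i]))
  fams <- split(tips, unname(familyMap[tips]))
  vapply(fams, function(members) {
    members <- sort(members)
    length(members) == 1L ||
      any(vapply(clades, identical, TRUE, y = members))
  }, TRUE)
}

#' Write / read a labelled distance matrix as CSV
#'
#' @param d labelled symmetric matrix.
#' @param path CSV path.
#' @name distanceMatrixIO
#' @export
writeDistanceMatrix <- function(d, path) {
  .checkDistanceMatrix(d)
  write.csv(d, path, row.names = TRUE)
  invisible(path)
}

#' @rdname distanceMatrixIO
#' @export
readDistanceMatrix <- function(path) {
  d <- as.matrix(read.csv(path, row.names = 1, check.names = FALSE))
  .checkDistanceMatrix(d)
  d
}
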