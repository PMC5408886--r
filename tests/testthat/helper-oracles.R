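# Independent oracles.  These deliberately share no code with the package
# paths they check: plain loops, distances from the original matrix, etc.

# brute-force contact scan: loop over every receptor/ligand atom pair,
# then apply the C-alpha/side-chain restriction on the collected minima
bruteContacts <- function(atoms, hetCode, ann, cutoff) {
  lig <- atoms[atoms$type == "HETATM" & atoms$resid == hetCode, ]
  rec <- atoms[atoms$type == "ATOM" & !is.na(atoms$seq_index), ]
  hits <- character(0)
  for (si in unique(rec$seq_index)) {
    ra <- rec[rec$seq_index == si, ]
    best <- Inf
    for (i in seq_len(nrow(ra))) {
      if (ra$elety[i] %in% c("N", "C", "O", "OXT")) next
      for (j in seq_len(nrow(lig))) {
        d <- sqrt((ra$x[i] - lig$x[j])^2 + (ra$y[i] - lig$y[j])^2 +
                    (ra$z[i] - lig$z[j])^2)
        if (d < best) best <- d
      }
    }
    if (best <= cutoff) hits <- c(hits, assignGeneric(ann, si))
  }
  sortGeneric(unique(hits[!is.na(hits)]))
}

# naive UPGMA: cluster-cluster distances recomputed every step as the
# plain mean over all member pairs of the ORIGINAL matrix; same
# lexicographic tie rule; emits newick directly
naiveUpgma <- function(d) {
  taxa <- rownames(d)
  cl <- lapply(taxa, function(t) list(members = t, height = 0, nwk = t))
  repeat {
    m <- length(cl)
    if (m == 1L) break
    best <- NULL
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      dd <- mean(d[cl[[i]]$members, cl[[j]]$members])
      key <- sort(c(min(cl[[i]]$members), min(cl[[j]]$members)))
      if (is.null(best) || dd < best$d - 1e-15 ||
          (abs(dd - best$d) <= 1e-15 &&
           (key[1] < best$key[1] ||
            (key[1] == best$key[1] && key[2] < best$key[2])))) {
        best <- list(i = i, j = j, d = dd, key = key)
      }
    }
    h <- best$d / 2
    a <- cl[[best$i]]; b <- cl[[best$j]]
    merged <- list(members = c(a$members, b$members), height = h,
                   nwk = sprintf("(%s:%.10f,%s:%.10f)", a$nwk, h - a$height,
                                 b$nwk, h - b$height))
    cl <- c(cl[-c(best$i, best$j)], list(merged))
  }
  ape::read.tree(text = paste0(cl[[1]]$nwk, ";"))
}

# per-column mismatch proportion by direct scan
bruteP <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- 0L; mm <- 0L
  for (i in seq_along(av)) {
    if (av[i] %in% c("-", ".") || bv[i] %in% c("-", ".")) next
    n <- n + 1L
    if (av[i] != bv[i]) mm <- mm + 1L
  }
  mm / n
}

# topology + height comparison of two rooted trees
treesMatch <- function(t1, t2, tol = 1e-9) {
  if (!setequal(t1$tip.label, t2$tip.label)) return(FALSE)
  p1 <- lapply(ape::prop.part(t1), function(i) sort(t1$tip.label[i]))
  p2 <- lapply(ape::prop.part(t2), function(i) sort(t2$tip.label[i]))
  if (length(p1) != length(p2)) return(FALSE)
  idx <- match(vapply(p1, paste, "", collapse = "|"),
               vapply(p2, paste, "", collapse = "|"))
  if (any(is.na(idx))) return(FALSE)
  d1 <- ape::node.depth.edgelength(t1)
  d2 <- ape::node.depth.edgelength(t2)
  h1 <- max(d1) - d1[length(t1$tip.label) + seq_along(p1)]
  h2 <- max(d2) - d2[length(t2$tip.label) + seq_along(p2)]
  all(abs(h1 - h2[idx]) < tol)
}

# random distance matrix with labels
randomDistMatrix <- function(n) {
  labs <- paste0("t", sample(100:999, n))
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- runif(1, 0.1, 2)
  d
}

# block-structured distances: tight within-family, loose between
blockDistMatrix <- function(sizes, within = 0.05, between = 0.8) {
  fam <- rep(names(sizes), sizes)
  labs <- paste0(fam, "_", unlist(lapply(sizes, seq_len)))
  n <- length(labs)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    base <- if (fam[i] == fam[j]) within else between
    d[i, j] <- d[j, i] <- base + runif(1, 0, base / 10)
  }
  list(d = d, familyMap = setNames(fam, labs))
}
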