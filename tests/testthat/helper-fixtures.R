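# Shared fixtures: tiny annotations, hand-written PDB text, and small
# generator shortcuts.  Everything is built in code at test time.

# one-segment annotation: TM6 spanning generic 6x40..6x60 on a 30-residue
# sequence, anchor (6x50) at sequence position 15
tm6Annotation <- function(id = "r1", seq = NULL) {
  if (is.null(seq)) seq <- strrep("A", 30)
  ReceptorAnnotation(id, seq,
    data.frame(segment = 6L, seq_start = 5L, seq_end = 25L,
               anchor_seq_index = 15L))
}

# ECL2 annotation anchored at a Cys, generic 45x46..45x53
ecl2Annotation <- function(id = "r1") {
  seq <- paste0(strrep("A", 9), "C", strrep("G", 10))  # Cys at 10
  ReceptorAnnotation(id, seq,
    data.frame(segment = 45L, seq_start = 6L, seq_end = 13L,
               anchor_seq_index = 10L))
}

# random multi-segment annotation for property-style loops
randomAnnotation <- function(id = "rnd", nSeg = 3) {
  segs <- list(); start <- sample(2:5, 1)
  for (k in seq_len(nSeg)) {
    len <- sample(6:20, 1)
    segs[[k]] <- data.frame(segment = k, seq_start = start,
                            seq_end = start + len - 1L,
                            anchor_seq_index = start + sample(seq_len(len), 1) - 1L)
    start <- start + len + sample(1:4, 1)
  }
  segTab <- do.call(rbind, segs)
  seq <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                      start + 3, replace = TRUE), collapse = "")
  ReceptorAnnotation(id, seq, segTab)
}

# fixed-width PDB ATOM/HETATM line
pdbLine <- function(type, serial, name, alt, resid, chain, resno,
                    x, y, z, occ = 1, b = 0, element = "C") {
  name4 <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, name4, alt, resid, chain, resno, x, y, z, occ, b,
          element)
}

writePdbFixture <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# atom table in the readStructure layout, for direct contactPositions calls
atomRow <- function(type, chain, resno, resid, elety, x, y, z,
                    seq_index = resno, elesy = "C") {
  data.frame(type = type, chain = chain, resno = resno, resid = resid,
             elety = elety, elesy = elesy, x = x, y = y, z = z,
             o = 1, alt = "A",
             seq_index = if (type == "ATOM") seq_index else NA_integer_,
             stringsAsFactors = FALSE)
}

# one valid mutation record with overridable fields
mutRecord <- function(...) {
  rec <- data.frame(receptor_id = "r1", family = "famA", seq_index = 15L,
                    generic = "6x50", wt_aa = "W", mut_aa = "A",
                    ligand_id = "L1", modality = "NAM", assay = "binding",
                    fold_effect = 10, qualitative = "none",
                    reference = "test", stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) rec[[nm]] <- over[[nm]]
  rec
}

smallSpec <- function(seed = 1, ...) {
  syntheticSpec(seed = seed, nReceptors = 6, nFamilies = 3,
                sitePositions = c("3x32", "45x52", "6x50", "6x53", "7x40"),
                backgroundRecords = 60, ...)
}
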