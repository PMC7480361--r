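# Fixture builders and independent oracles shared across test files.

STD_RESIDUES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                  "K", "M", "F", "P", "S", "T", "W", "Y", "V")

randomPeptides <- function(n, minLen = 1, maxLen = 30) {
  vapply(seq_len(n), function(i) {
    len <- sample(minLen:maxLen, 1)
    paste(sample(STD_RESIDUES, len, replace = TRUE), collapse = "")
  }, character(1))
}

# independent mass oracle: repeated per-character lookup, no vectorized sum;
# fixed carbamidomethylation of cysteine applied like the search settings
oracleMass <- function(sequence) {
  tab <- utils::read.delim(lactopepFile("residue_masses.tsv"),
                           comment.char = "#")
  mods <- utils::read.delim(lactopepFile("modifications.tsv"),
                            comment.char = "#")
  cam <- mods$delta_mass[mods$name == "Carbamidomethyl"]
  total <- tab$mass[tab$residue == "water"]
  for (ch in strsplit(sequence, "")[[1]]) {
    total <- total + tab$mass[tab$residue == ch]
    if (ch == "C") total <- total + cam
  }
  total
}

makeSampleSet <- function(...) {
  # rows as lists: list(strain, replicate, sequence, intensity, mass, hint)
  rows <- list(...)
  rec <- do.call(rbind, lapply(rows, function(r)
    data.frame(strain = r[[1]], replicate = r[[2]], sequence = r[[3]],
               intensity = if (length(r) >= 4) r[[4]] else 1,
               observed_mass = if (length(r) >= 5) r[[5]] else 500,
               protein_hint = if (length(r) >= 6) r[[6]] else NA_character_)))
  SampleSet(rec)
}

# brute-force nested-loop consensus oracle
oracleConsensus <- function(s, minReplicates) {
  rec <- records(s)
  out <- list()
  for (st in strainNames(s)) {
    kept <- character(0)
    r <- rec[rec$strain == st, ]
    for (p in unique(r$sequence)) {
      reps <- 0L
      for (rep_i in seq_len(replicateCounts(s)[[st]])) {
        found <- FALSE
        for (k in seq_len(nrow(r)))
          if (r$sequence[k] == p && r$replicate[k] == rep_i) found <- TRUE
        if (found) reps <- reps + 1L
      }
      if (reps >= minReplicates) kept <- c(kept, p)
    }
    out[[st]] <- sort(unique(kept))
  }
  out
}

# exhaustive membership-pattern oracle for set overlaps
oracleOverlaps <- function(sets) {
  elements <- unique(unlist(sets))
  counts <- list()
  for (e in elements) {
    pat <- paste(names(sets)[vapply(sets, function(s) e %in% s,
                                    logical(1))], collapse = "&")
    counts[[pat]] <- (counts[[pat]] %||% 0L) + 1L
  }
  counts
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# bundled published per-strain bioactive peptide table
publishedStrainPeptides <- function() {
  utils::read.delim(lactopepFile("strain_bioactive_peptides.tsv"),
                    comment.char = "#", stringsAsFactors = FALSE)
}

bundledCuratedDB <- function() {
  curateEntries(mergeSources(readBioactiveSources(
    lactopepFile("bioactive_sources_synthetic.tsv"))))
}
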