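#' @import methods
NULL

.IDENT_COLUMNS <- c("strain", "replicate", "sequence", "mods",
                    "observed_mass", "intensity", "protein_hint")

#' SampleSet: peptide-spectrum matches grouped by strain and replicate
#'
#' A `SampleSet` holds one identification record (PSM) per row, each assigned
#' to exactly one (strain, replicate) pair, together with the declared number
#' of biological replicates per strain. Replicate indices are contiguous from
#' 1; a replicate may contribute zero records (e.g. after dropout).
#'
#' @slot records data.frame with columns `strain`, `replicate`, `sequence`,
#'   `mods` (semicolon-joined `Name@pos` tokens, `""` for none),
#'   `observed_mass` (Da, > 0), `intensity` (arbitrary units, >= 0) and
#'   `protein_hint` (accession or `NA`).
#' @slot replicateCount named integer, declared replicates per strain.
#'
#' @export
setClass("SampleSet",
  representation(records = "data.frame", replicateCount = "integer"))

setValidity("SampleSet", function(object) {
  rec <- object@records
  missing <- setdiff(.IDENT_COLUMNS, names(rec))
  if (length(missing))
    return(paste("missing record columns:", paste(missing, collapse = ", ")))
  if (nrow(rec) == 0L) return(TRUE)
  if (any(!nzchar(rec$sequence))) return("empty peptide sequence")
  if (any(rec$intensity < 0)) return("negative intensity")
  if (any(rec$observed_mass <= 0)) return("non-positive observed mass")
  if (any(rec$replicate < 1L) || any(rec$replicate != round(rec$replicate)))
    return("replicate indices must be positive integers")
  rc <- object@replicateCount
  if (is.null(names(rc)) || !all(unique(rec$strain) %in% names(rc)))
    return("replicateCount must be named for every strain present")
  bad <- rec$replicate > rc[rec$strain]
  if (any(bad))
    return("record replicate index exceeds declared replicate count")
  TRUE
})

#' Construct a SampleSet from identification records
#'
#' @param records data.frame of identification records; see
#'   [readIdentTable()] for the canonical column set. Missing `mods` or
#'   `protein_hint` columns are filled with `""` / `NA`.
#' @param replicateCount optional named integer vector of declared replicates
#'   per strain; defaults to the maximum replicate index observed per strain.
#' @return A [SampleSet-class] object.
#' @examples
#' rec <- data.frame(strain = "wt", replicate = c(1, 2), sequence = "KVLPVPQ",
#'                   observed_mass = 779.49, intensity = 1e5)
#' SampleSet(rec)
#' @export
SampleSet <- function(records, replicateCount = NULL) {
  records <- as.data.frame(records)
  if (is.null(records$mods)) records$mods <- character(nrow(records))
  if (is.null(records$protein_hint))
    records$protein_hint <- rep(NA_character_, nrow(records))
  records$mods[is.na(records$mods)] <- ""
  records$strain <- as.character(records$strain)
  records$sequence <- as.character(records$sequence)
  records$replicate <- as.integer(records$replicate)
  records <- records[, .IDENT_COLUMNS]
  rownames(records) <- NULL
  if (is.null(replicateCount)) {
    replicateCount <- if (nrow(records))
      vapply(split(records$replicate, records$strain), max, integer(1))
    else
      integer(0)
  }
  new("SampleSet", records = records,
      replicateCount = structure(as.integer(replicateCount),
                                 names = names(replicateCount)))
}

setMethod("show", "SampleSet", function(object) {
  rec <- object@records
  cat("SampleSet with", nrow(rec), "identification records (PSMs)\n")
  for (s in names(object@replicateCount)) {
    n <- sum(rec$strain == s)
    cat(sprintf("  %s: %d PSMs, %d unique peptides, %d replicates\n",
                s, n, length(unique(rec$sequence[rec$strain == s])),
                object@replicateCount[[s]]))
  }
  invisible(NULL)
})

#' ResidueProfile: per-residue coverage of a substrate protein
#'
#' Peptigram-style coverage tracks on a single protein: for every residue
#' position, the number of located peptide occurrences covering it and the
#' sum of their mean intensities. Positions covered by no peptide carry zero
#' in both tracks.
#'
#' @slot accession protein accession the profile refers to.
#' @slot counts integer vector, one entry per residue position.
#' @slot intensitySum numeric vector, same length as `counts`.
#'
#' @export
setClass("ResidueProfile",
  representation(accession = "character", counts = "integer",
                 intensitySum = "numeric"))

setValidity("ResidueProfile", function(object) {
  if (length(object@counts) != length(object@intensitySum))
    return("counts and intensitySum must have equal length")
  if (any(object@counts < 0)) return("negative counts")
  if (any(object@intensitySum < 0)) return("negative intensity sums")
  if (any(object@counts == 0L & object@intensitySum > 0))
    return("positions with zero count must have zero intensity sum")
  TRUE
})

setMethod("show", "ResidueProfile", function(object) {
  n <- length(object@counts)
  cat(sprintf("ResidueProfile for %s (%d residues): %d covered, %d gaps\n",
              object@accession, n, sum(object@counts > 0),
              nrow(coverageGaps(object))))
  invisible(NULL)
})

#' CuratedDB: curated bioactive-peptide database
#'
#' Entries deduplicated by sequence, every one of which passes the four
#' curation exclusion rules (a literature reference exists, the activity is
#' not hypothetical/predicted only, no sequence discrepancy between database
#' and literature, and more than a bitter taste is recorded). Provenance
#' records how many entries each source contributed and how many each
#' exclusion rule removed.
#'
#' @slot entries data.frame with columns `sequence`, `parent`,
#'   `fragment_start`, `fragment_end`, `activities` / `references` /
#'   `source_db` (semicolon-joined), the four evidence flags, and
#'   `alt_fragments`.
#' @slot provenance list with `input_n`, `retained_n`, `excluded_by_rule`,
#'   `per_source`.
#'
#' @export
setClass("CuratedDB",
  representation(entries = "data.frame", provenance = "list"))

setValidity("CuratedDB", function(object) {
  e <- object@entries
  if (anyDuplicated(e$sequence)) return("entries must be unique by sequence")
  if (nrow(e) &&
      any(!e$has_reference | e$predicted_only | e$sequence_discrepancy |
          e$bitter_only))
    return("entries failing a curation rule are not allowed in a CuratedDB")
  if (nrow(e) && any(!nzchar(e$activities) & !e$bitter_only))
    return("entries must carry at least one activity")
  TRUE
})

setMethod("show", "CuratedDB", function(object) {
  p <- object@provenance
  cat(sprintf("CuratedDB: %d bioactive peptides (from %d merged entries)\n",
              nrow(object@entries), p$input_n))
  ex <- p$excluded_by_rule
  cat("  excluded -", paste(sprintf("%s: %d", names(ex), ex), collapse = ", "),
      "\n")
  invisible(NULL)
})

#' Genotype: a peptidase deletion strain
#'
#' @slot name strain label.
#' @slot deleted character vector of deleted peptidase genes; must be a
#'   subset of the genes known to [peptidaseRules()]. `pepM` is essential
#'   and can never be deleted.
#'
#' @export
setClass("Genotype",
  representation(name = "character", deleted = "character"))

setValidity("Genotype", function(object) {
  if (length(object@name) != 1L || !nzchar(object@name))
    return("name must be a single non-empty string")
  if ("pepM" %in% object@deleted)
    return("pepM is essential and cannot be deleted")
  unknown <- setdiff(object@deleted, peptidaseRules()$gene)
  if (length(unknown))
    return(paste("unknown peptidase gene(s):", paste(unknown, collapse = ", ")))
  TRUE
})

#' Construct a Genotype
#'
#' @param name strain label (must be unique within a panel).
#' @param deleted character vector of deleted peptidase gene names.
#' @return A [Genotype-class] object.
#' @examples
#' Genotype("MGdpepXPQ", c("pepX", "pepP", "pepQ"))
#' @export
Genotype <- function(name, deleted = character(0)) {
  new("Genotype", name = name, deleted = unique(as.character(deleted)))
}

setMethod("show", "Genotype", function(object) {
  cat(sprintf("Genotype %s: %s\n", object@name,
              if (length(object@deleted))
                paste0("Δ", paste(object@deleted, collapse = ",Δ"))
              else "wild type"))
  invisible(NULL)
})

#' DigestConfig: parameters of the in-silico proteolysis simulator
#'
#' Holds the substrate and every stochastic parameter of the simulated
#' casein utilization pathway: PrtP primary digestion, Opp length-window
#' transport, intracellular peptidase rounds, the MS detection mass window,
#' log-normal intensities, replicate structure, dropout and mass noise.
#'
#' @slot substrate precursor protein sequence (one-letter codes).
#' @slot accession substrate accession label.
#' @slot signalPeptideLen residues removed before digestion (15 for the
#'   beta-casein precursor).
#' @slot prtpCleaveProb per-bond base cleavage probability of the primary
#'   proteinase.
#' @slot prtpWeights named per-residue multipliers on `prtpCleaveProb` for
#'   the residue N-terminal to the bond.
#' @slot oppWindow inclusive peptide-length window of the oligopeptide
#'   permease, default 4..18 residues.
#' @slot molecules number of substrate molecules digested independently by
#'   the primary proteinase (controls peptidome depth).
#' @slot detectionWindow inclusive monoisotopic-mass window (Da) of the MS
#'   detector, default 170..2000.
#' @slot rounds maximum number of intracellular peptidase rounds.
#' @slot intensityMeanlog,intensitySdlog log-normal parameters of the
#'   peptide-level latent intensity shared across replicates.
#' @slot replicateNoiseSd sdlog of multiplicative per-replicate intensity
#'   noise.
#' @slot replicateCount biological replicates per strain, default 3.
#' @slot dropoutProb per-replicate probability that a peptide is not
#'   detected.
#' @slot ppmNoiseSd standard deviation (ppm) of the observed-mass error.
#' @slot seed master RNG seed; per-strain streams are derived from it.
#'
#' @export
setClass("DigestConfig",
  representation(substrate = "character", accession = "character",
    signalPeptideLen = "integer", prtpCleaveProb = "numeric",
    prtpWeights = "numeric", oppWindow = "integer", molecules = "integer",
    detectionWindow = "numeric", rounds = "integer",
    intensityMeanlog = "numeric", intensitySdlog = "numeric",
    replicateNoiseSd = "numeric", replicateCount = "integer",
    dropoutProb = "numeric", ppmNoiseSd = "numeric", seed = "integer"))

setValidity("DigestConfig", function(object) {
  if (!nzchar(object@substrate)) return("substrate sequence is empty")
  if (nchar(object@substrate) <= object@signalPeptideLen)
    return("substrate must be longer than the signal peptide")
  if (object@prtpCleaveProb < 0 || object@prtpCleaveProb > 1)
    return("prtpCleaveProb must be in [0, 1]")
  if (any(object@prtpWeights < 0)) return("prtpWeights must be >= 0")
  if (length(object@oppWindow) != 2L || diff(object@oppWindow) < 0)
    return("oppWindow must be a nonempty [lo, hi] interval")
  if (length(object@detectionWindow) != 2L || diff(object@detectionWindow) < 0)
    return("detectionWindow must be a nonempty [lo, hi] interval")
  if (object@rounds < 1L) return("rounds must be >= 1")
  if (object@molecules < 1L) return("molecules must be >= 1")
  if (object@dropoutProb < 0 || object@dropoutProb > 1)
    return("dropoutProb must be in [0, 1]")
  if (object@replicateCount < 1L) return("replicateCount must be >= 1")
  if (object@ppmNoiseSd < 0) return("ppmNoiseSd must be >= 0")
  TRUE
})

setMethod("show", "DigestConfig", function(object) {
  cat(sprintf(paste0("DigestConfig: %s (%d aa, signal peptide %d aa)\n",
      "  PrtP p=%.3g, Opp window %d-%d aa, detection %g-%g Da, %d rounds\n",
      "  %d replicates, dropout %.2g, mass noise %.3g ppm, seed %d\n"),
    object@accession, nchar(object@substrate), object@signalPeptideLen,
    object@prtpCleaveProb, object@oppWindow[1], object@oppWindow[2],
    object@detectionWindow[1], object@detectionWindow[2], object@rounds,
    object@replicateCount, object@dropoutProb, object@ppmNoiseSd,
    object@seed))
  invisible(NULL)
})
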