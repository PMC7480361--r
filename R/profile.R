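# Peptide localization on substrate proteins and per-residue coverage
# profiles with gap detection.

.protein_seq <- function(protein) {
  if (is.data.frame(protein)) {
    stopifnot(nrow(protein) == 1L, "sequence" %in% names(protein))
    protein$sequence
  } else {
    stopifnot(is.character(protein), length(protein) == 1L)
    protein
  }
}

.protein_acc <- function(protein, default = "protein") {
  if (is.data.frame(protein) && "accession" %in% names(protein))
    protein$accession
  else default
}

#' Locate a peptide on a substrate protein
#'
#' Returns every exact substring occurrence of the peptide on the protein as
#' 1-based inclusive `[start, end]` coordinates on the precursor, in
#' ascending start order. Overlapping occurrences are all reported. Absence
#' is a valid result (zero rows). With `collapseIL = TRUE`, isoleucine and
#' leucine are treated as indistinguishable (both mapped to L) before
#' matching; the default keeps them distinct.
#'
#' @param peptide peptide sequence.
#' @param protein protein sequence, or a one-row data.frame as returned by
#'   [readFastaProteins()].
#' @param collapseIL treat I and L as the same letter.
#' @return data.frame with columns `start` and `end`.
#' @examples
#' locatePeptide("YPFPGPIPN", betaCasein())  # (75, 83)
#' locatePeptide("AGA", "AGAGA")             # (1,3) and (3,5)
#' @export
locatePeptide <- function(peptide, protein, collapseIL = FALSE) {
  stopifnot(nzchar(peptide))
  subject <- .protein_seq(protein)
  stopifnot(nzchar(subject))
  if (collapseIL) {
    peptide <- chartr("I", "L", peptide)
    subject <- chartr("I", "L", subject)
  }
  hits <- Biostrings::matchPattern(peptide, Biostrings::AAString(subject))
  data.frame(start = BiocGenerics::start(hits),
             end = BiocGenerics::end(hits))
}

#' Build a per-residue coverage profile
#'
#' For every residue position of the protein, counts the peptide occurrences
#' covering it and sums their mean intensities (Peptigram semantics: bar
#' height is the count, color the intensity sum). A peptide matching at
#' several positions contributes at each of them. Peptides that do not
#' locate on the protein are skipped and reported in the `skipped`
#' attribute.
#'
#' @param peptides character vector of peptide sequences.
#' @param protein protein sequence or one-row data.frame.
#' @param intensities optional numeric vector of mean intensities parallel
#'   to `peptides`; defaults to zeros (count-only profile).
#' @param collapseIL passed to [locatePeptide()].
#' @return A [ResidueProfile-class]; attribute `skipped` lists unlocatable
#'   peptides.
#' @export
buildProfile <- function(peptides, protein, intensities = NULL,
                         collapseIL = FALSE) {
  seqstr <- .protein_seq(protein)
  n <- nchar(seqstr)
  if (is.null(intensities)) intensities <- numeric(length(peptides))
  stopifnot(length(intensities) == length(peptides), all(intensities >= 0))
  counts <- integer(n)
  isum <- numeric(n)
  skipped <- character(0)
  for (i in seq_along(peptides)) {
    loc <- locatePeptide(peptides[i], seqstr, collapseIL = collapseIL)
    if (!nrow(loc)) {
      skipped <- c(skipped, peptides[i])
      next
    }
    for (k in seq_len(nrow(loc))) {
      idx <- loc$start[k]:loc$end[k]
      counts[idx] <- counts[idx] + 1L
      isum[idx] <- isum[idx] + intensities[i]
    }
  }
  prof <- new("ResidueProfile", accession = .protein_acc(protein),
              counts = counts, intensitySum = isum)
  attr(prof, "skipped") <- skipped
  prof
}

#' Maximal uncovered regions of a profile
#'
#' Returns the maximal runs of zero-count positions as 1-based inclusive
#' intervals in ascending order; adjacent runs are merged by construction.
#' A fully covered protein yields zero rows. Gaps and covered segments
#' partition the protein.
#'
#' @param profile a [ResidueProfile-class].
#' @return data.frame with columns `start` and `end`.
#' @export
coverageGaps <- function(profile) {
  stopifnot(is(profile, "ResidueProfile"))
  r <- rle(profileCounts(profile) == 0L)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

#' Export strain profiles as a long table
#'
#' One row per (strain, residue position) with the count and intensity-sum
#' tracks. All profiles must be on the same protein (equal accession and
#' length). When `path` is given the table is written as TSV.
#'
#' @param profiles named list of [ResidueProfile-class] objects.
#' @param path optional output TSV path.
#' @return data.frame with columns `strain`, `accession`, `position`,
#'   `count`, `intensity_sum` (invisibly when written to `path`).
#' @seealso [readProfileTable()]
#' @export
profileExport <- function(profiles, path = NULL) {
  if (length(profiles) < 1L) stop("at least one profile is required")
  if (is.null(names(profiles)) || any(!nzchar(names(profiles))))
    stop("profiles must be named by strain")
  lens <- vapply(profiles, function(p) length(profileCounts(p)), integer(1))
  accs <- vapply(profiles, accession, character(1))
  if (length(unique(lens)) != 1L || length(unique(accs)) != 1L)
    stop("all profiles must be on the same protein")
  out <- do.call(rbind, lapply(names(profiles), function(st) {
    p <- profiles[[st]]
    data.frame(strain = st, accession = accession(p),
               position = seq_along(profileCounts(p)),
               count = profileCounts(p),
               intensity_sum = profileIntensity(p))
  }))
  rownames(out) <- NULL
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Read a profile track table written by [profileExport()]
#'
#' @param path TSV path.
#' @return Named list of [ResidueProfile-class] objects, one per strain.
#' @export
readProfileTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("strain", "accession", "position", "count", "intensity_sum")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  out <- lapply(split(tab, tab$strain), function(d) {
    d <- d[order(d$position), , drop = FALSE]
    new("ResidueProfile", accession = d$accession[1],
        counts = as.integer(d$count), intensitySum = d$intensity_sum)
  })
  out[unique(tab$strain)]
}
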