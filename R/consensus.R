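# Replicate-consensus filtering, count summaries, presence/absence and
# set-overlap arithmetic.

.mod_key <- function(sequence, mods) {
  # canonical (sequence, modification multiset) identity key
  vapply(seq_along(sequence), function(i) {
    m <- parseModSpec(mods[i])
    if (!nrow(m)) return(sequence[i])
    ord <- order(m$position, m$name)
    paste0(sequence[i], "|",
           paste(sprintf("%s@%d", m$name[ord], m$position[ord]),
                 collapse = ";"))
  }, character(1))
}

#' Replicate-consensus peptides per strain
#'
#' Applies the consensus rule of the workflow: a unique peptide is retained
#' for a strain iff it is observed (at least one PSM) in at least
#' `minReplicates` distinct biological replicates of that strain. By default
#' peptide identity for counting is the pair (sequence, modification
#' multiset); set `distinguishMods = FALSE` to collapse to the bare
#' sequence. The returned sets are deduplicated bare sequences.
#'
#' @param s a [SampleSet-class].
#' @param minReplicates minimum number of distinct replicates, between 1 and
#'   the strain's replicate count (default 2, the "at least twice among
#'   triplicates" rule).
#' @param distinguishMods whether modified forms count as distinct peptides.
#' @param strains strains to evaluate; default all. Unknown strains are an
#'   error.
#' @return Named list of character vectors (sorted unique sequences).
#' @examples
#' rec <- data.frame(strain = "wt", replicate = c(1, 3, 2),
#'                   sequence = c("KVLPVPQ", "KVLPVPQ", "AVPYPQR"),
#'                   observed_mass = 1, intensity = 1)
#' consensusPeptides(SampleSet(rec, c(wt = 3)))
#' @export
consensusPeptides <- function(s, minReplicates = 2, distinguishMods = TRUE,
                              strains = NULL) {
  stopifnot(is(s, "SampleSet"))
  if (is.null(strains)) strains <- strainNames(s)
  unknown <- setdiff(strains, strainNames(s))
  if (length(unknown))
    stop("unknown strain(s): ", paste(unknown, collapse = ", "))
  rc <- replicateCounts(s)
  if (minReplicates < 1 || any(minReplicates > rc[strains]))
    stop("minReplicates must be in 1..replicate count for every strain")
  rec <- records(s)
  out <- lapply(strains, function(st) {
    r <- rec[rec$strain == st, , drop = FALSE]
    if (!nrow(r)) return(character(0))
    key <- .mod_key(r$sequence, if (distinguishMods) r$mods
                                else rep("", nrow(r)))
    nrep <- vapply(split(r$replicate, key),
                   function(x) length(unique(x)), integer(1))
    keep <- names(nrep)[nrep >= minReplicates]
    sort(unique(r$sequence[key %in% keep]))
  })
  names(out) <- strains
  out
}

#' Per-strain PSM, unique-peptide and unique-protein counts
#'
#' PSMs are identification records; unique peptides are distinct sequences;
#' unique proteins are distinct `protein_hint` accessions. Records without a
#' protein hint are excluded from the protein count and reported in
#' `no_hint`.
#'
#' @param s a [SampleSet-class].
#' @return data.frame with columns `strain`, `psm`, `peptides`, `proteins`,
#'   `no_hint`.
#' @export
countSummary <- function(s) {
  stopifnot(is(s, "SampleSet"))
  rec <- records(s)
  strains <- strainNames(s)
  do.call(rbind, lapply(strains, function(st) {
    r <- rec[rec$strain == st, , drop = FALSE]
    hint <- r$protein_hint[!is.na(r$protein_hint) & nzchar(r$protein_hint)]
    data.frame(strain = st, psm = nrow(r),
               peptides = length(unique(r$sequence)),
               proteins = length(unique(hint)),
               no_hint = nrow(r) - length(hint))
  }))
}

#' Mean relative intensity of a peptide within a strain
#'
#' Per replicate, PSM intensities of the peptide are averaged; the reported
#' value is the arithmetic mean over replicates. By default only replicates
#' where the peptide was observed contribute (absent replicates do not count
#' as zeros); `zeroFill = TRUE` divides by the declared replicate count
#' instead.
#'
#' @param s a [SampleSet-class].
#' @param strain strain label.
#' @param peptide peptide sequence.
#' @param zeroFill treat unobserved replicates as zero intensity.
#' @return A single numeric value.
#' @export
meanRelativeIntensity <- function(s, strain, peptide, zeroFill = FALSE) {
  stopifnot(is(s, "SampleSet"))
  if (!(strain %in% strainNames(s))) stop("unknown strain: ", strain)
  rec <- records(s)
  r <- rec[rec$strain == strain & rec$sequence == peptide, , drop = FALSE]
  if (!nrow(r))
    stop("peptide ", peptide, " not observed in strain ", strain)
  per_rep <- vapply(split(r$intensity, r$replicate), mean, numeric(1))
  if (zeroFill) sum(per_rep) / replicateCounts(s)[[strain]]
  else mean(per_rep)
}

.jaccard_dist <- function(mat) {
  # pairwise Jaccard distance between the columns of a binary matrix
  n <- ncol(mat)
  d <- matrix(0, n, n, dimnames = list(colnames(mat), colnames(mat)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    inter <- sum(mat[, i] & mat[, j])
    uni <- sum(mat[, i] | mat[, j])
    d[i, j] <- if (uni == 0) 0 else 1 - inter / uni
  }
  stats::as.dist(d)
}

#' Presence/absence matrix of consensus peptides across strains
#'
#' Rows are the union of peptides over all sets, columns the strains; cell
#' (p, s) is 1 iff peptide p is in strain s's set. With `cluster = TRUE`,
#' row and column orders from average-linkage hierarchical clustering on
#' Jaccard distances are attached as attributes `row_order` / `col_order`
#' (labels are sorted beforehand, making ties deterministic).
#'
#' @param sets named list of character vectors (e.g. from
#'   [consensusPeptides()]).
#' @param cluster attach hierarchical-clustering orders.
#' @return Binary integer matrix.
#' @export
presenceAbsenceMatrix <- function(sets, cluster = FALSE) {
  if (length(sets) < 1L) stop("at least one strain set is required")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be named")
  peptides <- sort(unique(unlist(sets, use.names = FALSE)))
  mat <- vapply(sets[sort(names(sets))],
                function(x) as.integer(peptides %in% x),
                integer(length(peptides)))
  if (length(peptides) == 0L)
    mat <- matrix(integer(0), 0L, length(sets),
                  dimnames = list(NULL, sort(names(sets))))
  if (!is.matrix(mat)) mat <- matrix(mat, nrow = length(peptides),
                                     dimnames = list(peptides, sort(names(sets))))
  rownames(mat) <- peptides
  if (cluster && nrow(mat) > 1L) {
    attr(mat, "row_order") <-
      stats::hclust(.jaccard_dist(t(mat)), method = "average")$order
    if (ncol(mat) > 1L)
      attr(mat, "col_order") <-
        stats::hclust(.jaccard_dist(mat), method = "average")$order
  }
  mat
}

#' Venn-partition counts of named sets
#'
#' For 1 to 5 named sets, counts every non-empty membership pattern of the
#' Venn partition (elements belonging to exactly that combination of sets).
#' Counts sum to the size of the union.
#'
#' @param sets named list of 1-5 character vectors.
#' @return data.frame with columns `pattern` (set names joined by `&`) and
#'   `count`, one row per non-empty region.
#' @examples
#' setOverlaps(list(A = c("x", "y"), B = c("y", "z")))
#' @export
setOverlaps <- function(sets) {
  if (length(sets) < 1L) stop("at least one set is required")
  if (length(sets) > 5L)
    stop("set_overlaps supports at most 5 sets (got ", length(sets), ")")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be named")
  sets <- lapply(sets, unique)
  elements <- unique(unlist(sets, use.names = FALSE))
  pattern <- vapply(elements, function(e)
    paste(names(sets)[vapply(sets, function(s) e %in% s, logical(1))],
          collapse = "&"), character(1))
  tab <- table(pattern)
  out <- data.frame(pattern = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[order(out$pattern), , drop = FALSE]
}
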