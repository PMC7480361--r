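# Bioactive-peptide knowledge base: multi-source merging, curation
# exclusion rules, UpSet-style activity intersections, and matching of
# identified peptides.

.ACTIVITY_VOCAB <- c("ACE-I", "DPP-IV-I", "Immuno", "AntiM", "AntiO",
                     "PEP-I", "Opioid")

.split_semi <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  trimws(strsplit(x, ";", fixed = TRUE)[[1]])
}

.join_semi <- function(x) paste(sort(unique(x)), collapse = ";")

.check_activities <- function(acts) {
  bad <- acts[!(acts %in% .ACTIVITY_VOCAB | startsWith(acts, "other:"))]
  if (length(bad))
    stop("activity label(s) outside the controlled vocabulary: ",
         paste(unique(bad), collapse = ", "),
         " (use one of ", paste(.ACTIVITY_VOCAB, collapse = ", "),
         " or 'other:<text>')")
  invisible(NULL)
}

.BIOACTIVE_COLS <- c("sequence", "parent", "fragment_start", "fragment_end",
                     "activities", "references", "source", "has_reference",
                     "predicted_only", "sequence_discrepancy", "bitter_only")

#' Read a bioactive-peptide source table
#'
#' One row per (peptide, source) with semicolon-joined activities and
#' references and the four curation evidence flags. Activities must come
#' from the controlled vocabulary (`ACE-I`, `DPP-IV-I`, `Immuno`, `AntiM`,
#' `AntiO`, `PEP-I`, `Opioid`) or use the `other:<text>` escape hatch; an
#' entry may have no activity only when `bitter_only` is set.
#'
#' @param path TSV path.
#' @return data.frame of source entries.
#' @examples
#' src <- readBioactiveSources(lactopepFile("bioactive_sources_synthetic.tsv"))
#' @export
readBioactiveSources <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  missing <- setdiff(.BIOACTIVE_COLS, names(tab))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  for (fl in c("has_reference", "predicted_only", "sequence_discrepancy",
               "bitter_only"))
    tab[[fl]] <- as.logical(tab[[fl]])
  if (any(is.na(tab$sequence) | !nzchar(tab$sequence)))
    stop("entries must have a non-empty sequence")
  empty_act <- is.na(tab$activities) | !nzchar(tab$activities)
  if (any(empty_act & !tab$bitter_only))
    stop("entries without activities must be flagged bitter_only")
  .check_activities(unlist(lapply(tab$activities[!empty_act], .split_semi)))
  tab$references[is.na(tab$references)] <- ""
  tab
}

#' Merge bioactive-peptide source lists
#'
#' Concatenates one or more source tables and merges entries with identical
#' sequences: activities, references and source names are unioned, and
#' evidence flags are combined so a flag is set only if it holds across all
#' merged evidence — `has_reference` is TRUE if any source provides one,
#' `predicted_only`/`bitter_only` remain TRUE only if every source says so,
#' while a documented `sequence_discrepancy` from any source taints the
#' merged entry. Conflicting fragment coordinates keep the first-seen pair
#' in the numeric columns, preserve the alternatives in `alt_fragments`, and
#' raise a warning.
#'
#' @param ... data.frames as returned by [readBioactiveSources()].
#' @return Deduplicated-by-sequence data.frame with the source column
#'   renamed `source_db` and an `alt_fragments` column.
#' @export
mergeSources <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1L && is.list(tabs[[1]]) && !is.data.frame(tabs[[1]]))
    tabs <- tabs[[1]]
  all <- do.call(rbind, lapply(tabs, function(t) {
    if ("source_db" %in% names(t) && !("source" %in% names(t)))
      names(t)[names(t) == "source_db"] <- "source"
    if (is.null(t$alt_fragments)) t$alt_fragments <- ""
    t[, c(.BIOACTIVE_COLS, "alt_fragments")]
  }))
  merged <- lapply(split(all, all$sequence), function(g) {
    frag <- unique(stats::na.omit(
      g[, c("fragment_start", "fragment_end")]))
    if (nrow(frag) > 1L)
      warning("conflicting fragment coordinates for ", g$sequence[1],
              "; keeping first, alternatives recorded", call. = FALSE)
    alt <- if (nrow(frag) > 1L)
      paste(sprintf("%d-%d", frag$fragment_start[-1], frag$fragment_end[-1]),
            collapse = ";")
    else ""
    alt <- .join_semi(c(.split_semi(alt),
                        unlist(lapply(g$alt_fragments, .split_semi))))
    data.frame(
      sequence = g$sequence[1],
      parent = g$parent[1],
      fragment_start = if (nrow(frag)) frag$fragment_start[1] else NA_integer_,
      fragment_end = if (nrow(frag)) frag$fragment_end[1] else NA_integer_,
      activities = .join_semi(unlist(lapply(g$activities, .split_semi))),
      references = .join_semi(unlist(lapply(g$references, .split_semi))),
      source_db = .join_semi(unlist(lapply(g$source, .split_semi))),
      has_reference = any(g$has_reference),
      predicted_only = all(g$predicted_only),
      sequence_discrepancy = any(g$sequence_discrepancy),
      bitter_only = all(g$bitter_only),
      alt_fragments = alt,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, merged)
  rownames(out) <- NULL
  out[order(out$sequence), , drop = FALSE]
}

#' Curate a merged bioactive-peptide list
#'
#' Applies the four exclusion rules: an entry is removed iff (i) no
#' literature reference is provided, (ii) the activity is hypothetical or
#' predicted only, (iii) there is a discrepancy between the sequence in the
#' reference literature and the database, or (iv) only a bitter taste was
#' recorded. Provenance counts the input size, survivors, per-rule
#' exclusions (an entry violating several rules is counted under each) and
#' entries per source.
#'
#' @param merged data.frame from [mergeSources()] (or a single source table,
#'   which is merged first).
#' @return A [CuratedDB-class].
#' @export
curateEntries <- function(merged) {
  if (!("source_db" %in% names(merged))) merged <- mergeSources(merged)
  excl <- c(no_reference = sum(!merged$has_reference),
            predicted_only = sum(merged$predicted_only),
            sequence_discrepancy = sum(merged$sequence_discrepancy),
            bitter_only = sum(merged$bitter_only))
  keep <- merged$has_reference & !merged$predicted_only &
    !merged$sequence_discrepancy & !merged$bitter_only
  srcs <- unlist(lapply(merged$source_db, .split_semi))
  prov <- list(input_n = nrow(merged), retained_n = sum(keep),
               excluded_by_rule = excl,
               per_source = table(srcs))
  ent <- merged[keep, , drop = FALSE]
  rownames(ent) <- NULL
  new("CuratedDB", entries = ent, provenance = prov)
}

#' UpSet-style activity intersection counts
#'
#' For a curated database: the set size of each activity (number of entries
#' carrying it), the exclusive intersection size of each observed activity
#' pattern (entries whose activity set equals exactly that pattern; UpSet
#' semantics), and the number of multi-activity entries. Exclusive
#' intersection sizes sum to the number of entries, and each activity's set
#' size equals the sum over patterns containing it.
#'
#' @param db a [CuratedDB-class].
#' @return list with `set_sizes` (data.frame `activity`, `size`),
#'   `intersections` (data.frame `pattern`, `size`; activities joined by
#'   `&` in vocabulary order) and `multi_activity` (integer).
#' @export
activityIntersections <- function(db) {
  stopifnot(is(db, "CuratedDB"))
  acts <- lapply(entries(db)$activities, .split_semi)
  vocab <- c(.ACTIVITY_VOCAB,
             sort(unique(unlist(acts)[startsWith(unlist(acts), "other:")])))
  .check_activities(unlist(acts))
  set_sizes <- data.frame(
    activity = vocab,
    size = vapply(vocab, function(a)
      sum(vapply(acts, function(x) a %in% x, logical(1))), integer(1)),
    row.names = NULL)
  set_sizes <- set_sizes[set_sizes$size > 0, , drop = FALSE]
  pattern <- vapply(acts, function(x)
    paste(vocab[vocab %in% x], collapse = "&"), character(1))
  tab <- table(pattern)
  intersections <- data.frame(pattern = names(tab),
                              size = as.integer(tab), row.names = NULL)
  list(set_sizes = set_sizes,
       intersections = intersections[order(-intersections$size,
                                           intersections$pattern), ,
                                     drop = FALSE],
       multi_activity = sum(lengths(acts) >= 2L))
}

#' Match identified peptides against a curated database
#'
#' In `exact` mode an identified peptide matches iff its bare sequence
#' equals a database entry sequence. In `substring` mode a peptide also
#' matches entries whose sequence it contains (the identified peptide
#' carries a known bioactive core); exact mode is the default. Matches are
#' sorted by fragment start (missing coordinates last).
#'
#' @param sets named list of per-strain peptide-sequence vectors (e.g. from
#'   [consensusPeptides()]).
#' @param db a [CuratedDB-class].
#' @param mode `"exact"` or `"substring"`.
#' @return Named list (per strain) of data.frames with columns `sequence`,
#'   `matched_entry`, `fragment_start`, `fragment_end`, `activities`,
#'   `references`.
#' @export
matchPeptides <- function(sets, db, mode = c("exact", "substring")) {
  mode <- match.arg(mode)
  stopifnot(is(db, "CuratedDB"))
  ent <- entries(db)
  out <- lapply(sets, function(peps) {
    peps <- unique(peps)
    rows <- NULL
    for (p in peps) {
      hit <- if (mode == "exact") which(ent$sequence == p)
             else which(vapply(ent$sequence, function(e)
               grepl(e, p, fixed = TRUE), logical(1)))
      if (length(hit))
        rows <- rbind(rows, data.frame(
          sequence = p, matched_entry = ent$sequence[hit],
          fragment_start = ent$fragment_start[hit],
          fragment_end = ent$fragment_end[hit],
          activities = ent$activities[hit],
          references = ent$references[hit]))
    }
    if (is.null(rows))
      rows <- data.frame(sequence = character(0),
                         matched_entry = character(0),
                         fragment_start = integer(0),
                         fragment_end = integer(0),
                         activities = character(0),
                         references = character(0))
    rows <- rows[order(rows$fragment_start, rows$sequence,
                       na.last = TRUE), , drop = FALSE]
    rownames(rows) <- NULL
    rows
  })
  names(out) <- names(sets)
  out
}

.fmt_ppm <- function(x) {
  ifelse(is.na(x), "—",
         format(signif(x, 2), trim = TRUE, scientific = FALSE))
}

#' Per-strain bioactive-peptide report
#'
#' Builds the standard report table: per strain, one row per matched
#' bioactive peptide with the recomputed theoretical monoisotopic mass, the
#' fragment location on the substrate precursor, per-replicate ppm mass
#' errors (an em dash marks replicates where the peptide was not detected),
#' activities and references. A strain without matches yields a single
#' `"None"` row. Matched peptides that cannot be located on the substrate
#' get an empty fragment and a warning.
#'
#' @param matches output of [matchPeptides()].
#' @param sampleSet optional [SampleSet-class] providing per-replicate
#'   observed masses for the ppm columns.
#' @param protein substrate protein (sequence or one-row data.frame) for
#'   localization; default the bundled beta-casein precursor.
#' @return data.frame with columns `strain`, `sequence`, `fragment`,
#'   `theoretical_mass`, `mass_error_ppm`, `activities`, `references`.
#' @export
bioactiveReport <- function(matches, sampleSet = NULL,
                            protein = betaCasein()) {
  rows <- NULL
  for (st in names(matches)) {
    m <- matches[[st]]
    if (!nrow(m)) {
      rows <- rbind(rows, data.frame(
        strain = st, sequence = "None", fragment = "",
        theoretical_mass = NA_real_, mass_error_ppm = "",
        activities = "", references = ""))
      next
    }
    for (i in seq_len(nrow(m))) {
      p <- m$sequence[i]
      loc <- locatePeptide(p, protein)
      if (!nrow(loc)) {
        warning("matched peptide ", p, " does not locate on ",
                .protein_acc(protein), call. = FALSE)
        frag <- ""
      } else frag <- sprintf("%d-%d", loc$start[1], loc$end[1])
      theo <- monoisotopicMass(p)
      ppm <- ""
      if (!is.null(sampleSet) && st %in% strainNames(sampleSet)) {
        rec <- records(sampleSet)
        r <- rec[rec$strain == st & rec$sequence == p, , drop = FALSE]
        per_rep <- rep(NA_real_, replicateCounts(sampleSet)[[st]])
        if (nrow(r)) {
          obs <- vapply(split(r$observed_mass, r$replicate), mean,
                        numeric(1))
          per_rep[as.integer(names(obs))] <- ppmError(obs, theo)
        }
        ppm <- paste(.fmt_ppm(per_rep), collapse = "/")
      }
      rows <- rbind(rows, data.frame(
        strain = st, sequence = p, fragment = frag,
        theoretical_mass = theo, mass_error_ppm = ppm,
        activities = m$activities[i], references = m$references[i]))
    }
  }
  rownames(rows) <- NULL
  rows
}
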