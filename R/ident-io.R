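# Reading and writing identification tables and protein FASTA.

.PEAKS_COLMAP <- c(strain = "Sample", replicate = "Replicate",
                   sequence = "Peptide", mods = "PTM",
                   observed_mass = "Mass", intensity = "Area",
                   protein_hint = "Accession")

#' Read a peptide-identification table
#'
#' Parses a table of peptide-spectrum matches into a [SampleSet-class].
#' The canonical dialect is a TSV with header columns `strain`, `replicate`,
#' `sequence`, `mods`, `observed_mass`, `intensity`, `protein_hint`
#' (the last two of `mods`/`protein_hint` optional). The `peaks` dialect is
#' a CSV export in the style of a commercial search platform; its column
#' names are mapped via `colMap`.
#'
#' Rows violating record invariants (empty sequence, non-positive mass,
#' negative or unparseable intensity/mass, bad replicate index) are rejected
#' with a warning naming the row numbers; parsing fails only on a missing
#' mandatory column.
#'
#' @param path file path.
#' @param dialect `"canonical"` (TSV) or `"peaks"` (CSV).
#' @param colMap named character vector mapping canonical column names to
#'   file column names (used by the `peaks` dialect).
#' @return A [SampleSet-class].
#' @seealso [writeIdentTable()]
#' @export
readIdentTable <- function(path, dialect = c("canonical", "peaks"),
                           colMap = .PEAKS_COLMAP) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- if (dialect == "canonical")
    utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  else
    utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (dialect == "peaks") {
    missing <- setdiff(colMap[c("strain", "replicate", "sequence",
                                "observed_mass", "intensity")], names(raw))
    if (length(missing))
      stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
    cols <- lapply(names(colMap), function(canon) {
      src <- colMap[[canon]]
      if (src %in% names(raw)) raw[[src]]
      else if (canon == "mods") character(nrow(raw))
      else rep(NA_character_, nrow(raw))
    })
    names(cols) <- names(colMap)
    raw <- as.data.frame(cols, stringsAsFactors = FALSE)
  } else {
    mandatory <- c("strain", "replicate", "sequence", "observed_mass",
                   "intensity")
    missing <- setdiff(mandatory, names(raw))
    if (length(missing))
      stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
    if (is.null(raw$mods)) raw$mods <- ""
    if (is.null(raw$protein_hint)) raw$protein_hint <- NA_character_
  }
  raw$sequence <- toupper(trimws(as.character(raw$sequence)))
  raw$observed_mass <- suppressWarnings(as.numeric(raw$observed_mass))
  raw$intensity <- suppressWarnings(as.numeric(raw$intensity))
  raw$replicate <- suppressWarnings(as.integer(raw$replicate))
  bad <- is.na(raw$observed_mass) | raw$observed_mass <= 0 |
    is.na(raw$intensity) | raw$intensity < 0 |
    is.na(raw$replicate) | raw$replicate < 1L |
    is.na(raw$sequence) | !nzchar(raw$sequence)
  if (any(bad)) {
    warning(sum(bad), " row(s) rejected (invalid mass, intensity, ",
            "replicate or sequence): rows ",
            paste(utils::head(which(bad), 10L), collapse = ", "),
            if (sum(bad) > 10L) ", ...")
    raw <- raw[!bad, , drop = FALSE]
  }
  SampleSet(raw)
}

#' Write a SampleSet as a canonical identification TSV
#'
#' @param s a [SampleSet-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeIdentTable <- function(s, path) {
  stopifnot(is(s, "SampleSet"))
  utils::write.table(records(s), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read substrate protein sequences from FASTA
#'
#' Accessions are the first whitespace-delimited token of each header; the
#' remainder becomes the description. Sequences are uppercased and must be
#' non-empty over the standard 20-letter alphabet.
#'
#' @param path FASTA file path.
#' @return data.frame with columns `accession`, `description`, `sequence`.
#' @examples
#' bc <- readFastaProteins(lactopepFile("P02666_betacasein.fasta"))
#' nchar(bc$sequence)  # 224
#' @export
readFastaProteins <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("no FASTA records in ", path)
  headers <- names(aa)
  accession <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  sequence <- toupper(gsub("\\s", "", as.character(aa)))
  if (any(!nzchar(sequence))) stop("FASTA record with empty sequence")
  bad <- grepl(sprintf("[^%s]", paste(names(residueMasses()), collapse = "")),
               sequence)
  if (any(bad))
    stop("non-standard residue letters in record(s): ",
         paste(accession[bad], collapse = ", "))
  data.frame(accession = accession, description = description,
             sequence = sequence, stringsAsFactors = FALSE)
}

#' The bundled beta-casein precursor
#'
#' Convenience accessor for the bovine beta-casein precursor P02666
#' (224 residues; the N-terminal 15 residues are the signal peptide, so the
#' mature chain spans precursor positions 16-224).
#'
#' @return One-row data.frame as returned by [readFastaProteins()].
#' @export
betaCasein <- function() {
  readFastaProteins(.extdata("P02666_betacasein.fasta"))[1L, , drop = FALSE]
}
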