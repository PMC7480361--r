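# Monoisotopic peptide mass, ppm mass error and tolerance checks.

.lactopep_cache <- new.env(parent = emptyenv())

.extdata <- function(name) {
  path <- system.file("extdata", name, package = "lactopep")
  if (!nzchar(path)) stop("bundled data file not found: ", name)
  path
}

#' Bundled data file paths
#'
#' Returns the path of a plain-text data file shipped with the package
#' (residue masses, modification registry, hydropathy and pKa tables, the
#' P02666 beta-casein precursor FASTA, the synthetic bioactive-peptide source
#' database and the published per-strain bioactive peptide table).
#'
#' @param name file name, e.g. `"residue_masses.tsv"`; with no argument,
#'   lists the available files.
#' @return A file path, or a character vector of file names.
#' @examples
#' lactopepFile()
#' lactopepFile("residue_masses.tsv")
#' @export
lactopepFile <- function(name = NULL) {
  if (is.null(name))
    return(dir(system.file("extdata", package = "lactopep")))
  .extdata(name)
}

#' Monoisotopic residue mass table
#'
#' Reads the bundled table of monoisotopic residue masses (Da) for the 20
#' standard amino acids. The attribute `"water"` carries the monoisotopic
#' mass of H2O, added once per peptide. An alternative table with the same
#' layout can be supplied via `path`.
#'
#' @param path optional path to a two-column TSV (`residue`, `mass`)
#'   including a `water` row.
#' @return Named numeric vector of 20 residue masses with attribute `water`.
#' @examples
#' residueMasses()[["G"]]
#' @export
residueMasses <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.lactopep_cache$residue_masses))
      return(.lactopep_cache$residue_masses)
    path <- .extdata("residue_masses.tsv")
    cache <- TRUE
  } else cache <- FALSE
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  masses <- structure(tab$mass, names = tab$residue)
  water <- masses[["water"]]
  masses <- masses[names(masses) != "water"]
  if (length(masses) != 20L)
    stop("residue mass table must contain exactly the 20 standard residues")
  if (any(masses <= 0) || water <= 0) stop("residue masses must be positive")
  attr(masses, "water") <- water
  if (cache) .lactopep_cache$residue_masses <- masses
  masses
}

#' Modification registry
#'
#' Reads the bundled modification registry: carbamidomethylation of cysteine
#' (fixed), oxidation of methionine and phosphorylation of serine (variable),
#' with Unimod-standard monoisotopic mass deltas. Fixed modifications are
#' applied automatically to every target residue; variable modifications
#' contribute only where declared on a peptide.
#'
#' @param path optional path to a TSV with columns `name`, `delta_mass`,
#'   `targets` (residue letters, no separator) and `mode`
#'   (`fixed`/`variable`).
#' @return data.frame with one row per modification.
#' @export
modificationRegistry <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.lactopep_cache$mod_registry))
      return(.lactopep_cache$mod_registry)
    path <- .extdata("modifications.tsv")
    cache <- TRUE
  } else cache <- FALSE
  reg <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("name", "delta_mass", "targets", "mode") %in% names(reg)))
  if (any(!nzchar(reg$targets))) stop("modification target set must be non-empty")
  if (!all(reg$mode %in% c("fixed", "variable")))
    stop("modification mode must be 'fixed' or 'variable'")
  if (cache) .lactopep_cache$mod_registry <- reg
  reg
}

.split_residues <- function(sequence) strsplit(sequence, "", fixed = TRUE)

.check_residues <- function(chars, massTable, sequence) {
  bad <- which(!(chars %in% names(massTable)))
  if (length(bad))
    stop(sprintf("unknown residue '%s' at position %d in '%s'",
                 chars[bad[1]], bad[1], sequence), call. = FALSE)
  invisible(NULL)
}

#' Parse a modification specification string
#'
#' Positioned modifications on a peptide are written as semicolon-joined
#' `Name@position` tokens, e.g. `"Oxidation@3;Phospho@5"`. Positions are
#' 1-based on the peptide.
#'
#' @param spec a single string (`""`, `NA` and `NULL` mean no modifications).
#' @return data.frame with columns `name` and `position`.
#' @examples
#' parseModSpec("Oxidation@3;Phospho@5")
#' @export
parseModSpec <- function(spec) {
  if (is.null(spec) || length(spec) == 0L || is.na(spec) || !nzchar(spec))
    return(data.frame(name = character(0), position = integer(0)))
  tokens <- strsplit(spec, ";", fixed = TRUE)[[1]]
  tokens <- trimws(tokens[nzchar(trimws(tokens))])
  parts <- strsplit(tokens, "@", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop("malformed modification token; expected 'Name@position'")
  data.frame(name = vapply(parts, `[`, "", 1L),
             position = as.integer(vapply(parts, `[`, "", 2L)))
}

.mass_one <- function(sequence, mods, massTable, registry, water) {
  if (is.na(sequence) || !nzchar(sequence))
    stop("peptide sequence must be non-empty", call. = FALSE)
  chars <- .split_residues(sequence)[[1]]
  .check_residues(chars, massTable, sequence)
  m <- sum(massTable[chars]) + water
  # fixed modifications: every target residue, unconditionally
  fixed <- registry[registry$mode == "fixed", , drop = FALSE]
  for (i in seq_len(nrow(fixed))) {
    targets <- .split_residues(fixed$targets[i])[[1]]
    m <- m + fixed$delta_mass[i] * sum(chars %in% targets)
  }
  if (is.character(mods)) mods <- parseModSpec(mods)
  if (!is.null(mods) && nrow(mods)) {
    idx <- match(mods$name, registry$name)
    if (anyNA(idx))
      stop("unknown modification: ", mods$name[which(is.na(idx))[1]],
           call. = FALSE)
    if (any(registry$mode[idx] == "fixed"))
      stop("fixed modifications are applied automatically and cannot be declared",
           call. = FALSE)
    if (any(mods$position < 1L | mods$position > length(chars)))
      stop("modification position outside the peptide", call. = FALSE)
    for (k in seq_len(nrow(mods))) {
      targets <- .split_residues(registry$targets[idx[k]])[[1]]
      if (!(chars[mods$position[k]] %in% targets))
        stop(sprintf("modification %s does not target residue '%s' at position %d",
                     mods$name[k], chars[mods$position[k]], mods$position[k]),
             call. = FALSE)
      m <- m + registry$delta_mass[idx[k]]
    }
  }
  m
}

#' Monoisotopic peptide mass
#'
#' Computes the neutral monoisotopic mass of a peptide as the sum of its
#' residue masses plus one water, plus modification mass deltas. Fixed
#' modifications from the registry (carbamidomethyl-C by default) are applied
#' to every target residue; variable modifications must be declared per
#' peptide via `mods`. Nonstandard letters (B, J, O, U, X, Z) are rejected
#' with the offending character and position.
#'
#' @param sequence character vector of peptide sequences (uppercase
#'   one-letter codes).
#' @param mods modifications: `NULL`, a character vector of
#'   [parseModSpec()] strings parallel to `sequence`, or a single
#'   data.frame with columns `name` and `position` (only when `sequence`
#'   has length 1).
#' @param massTable residue mass table, see [residueMasses()].
#' @param registry modification registry, see [modificationRegistry()].
#' @return Numeric vector of monoisotopic masses (Da).
#' @examples
#' monoisotopicMass("YPFPGPIPN")   # 1000.5018 Da
#' monoisotopicMass("KVLPVPQ")     # 779.4905 Da
#' monoisotopicMass("MK", mods = "Oxidation@1")
#' @export
monoisotopicMass <- function(sequence, mods = NULL,
                             massTable = residueMasses(),
                             registry = modificationRegistry()) {
  water <- attr(massTable, "water")
  if (is.data.frame(mods)) {
    if (length(sequence) != 1L)
      stop("a mods data.frame is only supported for a single sequence")
    return(.mass_one(sequence, mods, massTable, registry, water))
  }
  if (is.null(mods)) mods <- rep("", length(sequence))
  if (length(mods) != length(sequence))
    stop("mods must be NULL or parallel to sequence")
  vapply(seq_along(sequence), function(i)
    .mass_one(sequence[i], mods[i], massTable, registry, water), numeric(1))
}

#' Relative mass error in parts per million
#'
#' `10^6 * (observed - theoretical) / theoretical`; the sign is preserved,
#' so an observed mass below the theoretical one gives a negative error.
#'
#' @param observed observed neutral mass (Da).
#' @param theoretical theoretical monoisotopic mass (Da), must be > 0.
#' @return Numeric vector of ppm errors.
#' @examples
#' ppmError(1000.5028, 1000.5018)  # about +1 ppm
#' @export
ppmError <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical mass must be positive")
  1e6 * (observed - theoretical) / theoretical
}

#' Mass-tolerance check
#'
#' TRUE iff the absolute ppm error is within `tol` (inclusive; the default
#' 15 ppm is the precursor tolerance of the identification workflow). The
#' comparison carries a 1e-9 ppm guard so the inclusive bound is robust to
#' floating-point rounding.
#'
#' @inheritParams ppmError
#' @param tol tolerance in ppm, > 0.
#' @return Logical vector.
#' @examples
#' withinTolerance(1000.5028, 1000.5018)
#' @export
withinTolerance <- function(observed, theoretical, tol = 15) {
  if (any(tol <= 0)) stop("tol must be positive")
  abs(ppmError(observed, theoretical)) <= tol + 1e-9
}
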