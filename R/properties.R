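# Physicochemical descriptors of peptide sets: length, proline fraction,
# GRAVY, net charge, aliphatic index, aromatic fraction.

#' Kyte-Doolittle hydropathy scale
#'
#' @param path optional alternative TSV (`residue`, `hydropathy`).
#' @return Named numeric vector over the 20 standard residues.
#' @export
kyteDoolittle <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.lactopep_cache$kd)) return(.lactopep_cache$kd)
    path <- .extdata("kyte_doolittle.tsv")
    cache <- TRUE
  } else cache <- FALSE
  tab <- utils::read.delim(path, comment.char = "#")
  kd <- structure(tab$hydropathy, names = tab$residue)
  if (cache) .lactopep_cache$kd <- kd
  kd
}

#' Ionizable-group pKa set
#'
#' The EMBOSS pKa values used by the net-charge model: amino and carboxyl
#' termini plus the K/R/H (basic) and D/E/C/Y (acidic) side chains.
#'
#' @param path optional alternative TSV (`group`, `pka`, `sign`).
#' @return data.frame with columns `group`, `pka`, `sign`.
#' @export
pkaSet <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.lactopep_cache$pka)) return(.lactopep_cache$pka)
    path <- .extdata("pka_emboss.tsv")
    cache <- TRUE
  } else cache <- FALSE
  tab <- utils::read.delim(path, comment.char = "#")
  if (cache) .lactopep_cache$pka <- tab
  tab
}

.check_standard <- function(sequence) {
  std <- names(residueMasses())
  for (s in sequence) {
    if (is.na(s) || !nzchar(s))
      stop("peptide sequence must be non-empty", call. = FALSE)
    chars <- strsplit(s, "")[[1]]
    .check_residues(chars, stats::setNames(numeric(20), std), s)
  }
  invisible(NULL)
}

#' Proline fraction of a peptide
#'
#' Number of proline residues divided by peptide length, in `[0, 1]`.
#'
#' @param sequence character vector of peptide sequences.
#' @return Numeric vector.
#' @examples
#' prolineFraction("KVLPVPQ")  # 2/7
#' @export
prolineFraction <- function(sequence) {
  .check_standard(sequence)
  vapply(sequence, function(s) {
    chars <- strsplit(s, "")[[1]]
    sum(chars == "P") / length(chars)
  }, numeric(1), USE.NAMES = FALSE)
}

.net_charge <- function(chars, pH, pka) {
  groups <- c("Nterm", "Cterm", chars[chars %in% pka$group])
  idx <- match(groups, pka$group)
  q <- ifelse(pka$sign[idx] > 0,
              1 / (1 + 10^(pH - pka$pka[idx])),     # basic: protonated +1
              -1 / (1 + 10^(pka$pka[idx] - pH)))    # acidic: deprotonated -1
  sum(q)
}

#' Physicochemical properties of peptides
#'
#' Computes, per peptide: length; proline fraction; GRAVY (mean
#' Kyte-Doolittle hydropathy); net charge at `pH` via
#' Henderson-Hasselbalch over the termini and ionizable side chains with the
#' EMBOSS pKa set; aliphatic index
#' (`100 * (fA + 2.9 fV + 3.9 (fI + fL))` over mole fractions); and
#' aromatic fraction (F, W, Y residues over length).
#'
#' @param sequence character vector of peptide sequences (standard
#'   alphabet; nonstandard letters are an error).
#' @param pH pH of the net-charge model, default 7.0.
#' @param pka pKa table, see [pkaSet()].
#' @param kd hydropathy scale, see [kyteDoolittle()].
#' @return data.frame with one row per peptide: `sequence`, `length`,
#'   `proline_fraction`, `gravy`, `net_charge`, `aliphatic_index`,
#'   `aromatic_fraction`.
#' @examples
#' computeProperties("V")$gravy  # 4.2
#' @export
computeProperties <- function(sequence, pH = 7.0, pka = pkaSet(),
                              kd = kyteDoolittle()) {
  .check_standard(sequence)
  rows <- lapply(sequence, function(s) {
    chars <- strsplit(s, "")[[1]]
    n <- length(chars)
    f <- function(r) sum(chars %in% r) / n
    data.frame(sequence = s, length = n,
               proline_fraction = f("P"),
               gravy = mean(kd[chars]),
               net_charge = .net_charge(chars, pH, pka),
               aliphatic_index = 100 * (f("A") + 2.9 * f("V") +
                                        3.9 * (f("I") + f("L"))),
               aromatic_fraction = f(c("F", "W", "Y")))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Property distributions of per-strain peptide sets
#'
#' Summarizes every property of [computeProperties()] per strain (n, mean,
#' median, quartiles) and returns the raw per-peptide values for external
#' plotting (violin panels etc.). Empty strain sets are reported with
#' `n = 0` and `NA` statistics.
#'
#' @param sets named list of peptide-sequence vectors (e.g. from
#'   [consensusPeptides()]).
#' @param pH passed to [computeProperties()].
#' @return list with `summary` (strain x property statistics) and `values`
#'   (long per-peptide table).
#' @export
propertyDistributions <- function(sets, pH = 7.0) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be named by strain")
  props <- c("length", "proline_fraction", "gravy", "net_charge",
             "aliphatic_index", "aromatic_fraction")
  values <- NULL
  summary <- NULL
  for (st in names(sets)) {
    peps <- unique(sets[[st]])
    if (length(peps)) {
      tab <- computeProperties(peps, pH = pH)
      values <- rbind(values, cbind(strain = st, tab))
    }
    for (p in props) {
      v <- if (length(peps)) tab[[p]] else numeric(0)
      q <- if (length(v)) stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
           else rep(NA_real_, 3)
      summary <- rbind(summary, data.frame(
        strain = st, property = p, n = length(v),
        mean = if (length(v)) mean(v) else NA_real_,
        q1 = q[1], median = q[2], q3 = q[3]))
    }
  }
  rownames(summary) <- NULL
  if (!is.null(values)) rownames(values) <- NULL
  list(summary = summary, values = values)
}
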