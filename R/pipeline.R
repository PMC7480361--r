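# End-to-end orchestration: identification tables (real or simulated) ->
# consensus -> counts/overlaps -> profiles -> properties -> curated
# bioactive DB -> matches -> report, with a structured run log.

#' Assemble a pipeline run configuration
#'
#' A flat key-value configuration for [runPipeline()]. When `identTable` is
#' `NULL` the identification tables are simulated for `genotypes` with
#' [simulatePanel()]. Defaults mirror the analysis workflow constants:
#' consensus at 2 of 3 replicates, 15 ppm precursor tolerance, Opp window
#' 4-18 residues, detection window 170-2000 Da.
#'
#' @param outDir output directory (created if missing).
#' @param identTable optional identification-table path.
#' @param dialect identification-table dialect, see [readIdentTable()].
#' @param fasta substrate FASTA path (default: bundled P02666).
#' @param bioactiveDb bioactive source TSV (default: bundled synthetic DB).
#' @param genotypes list of [Genotype-class] for simulation mode.
#' @param minReplicates consensus threshold.
#' @param tolPpm precursor mass tolerance (ppm).
#' @param pH pH for the net-charge model.
#' @param oppWindow,detectionWindow simulator windows.
#' @param matchMode `"exact"` or `"substring"`.
#' @param seed master seed for simulation mode.
#' @return A named list of class `lactopep_config`.
#' @export
runConfig <- function(outDir,
                      identTable = NULL,
                      dialect = "canonical",
                      fasta = lactopepFile("P02666_betacasein.fasta"),
                      bioactiveDb = lactopepFile("bioactive_sources_synthetic.tsv"),
                      genotypes = genotypePanel(),
                      minReplicates = 2,
                      tolPpm = 15,
                      pH = 7.0,
                      oppWindow = c(4, 18),
                      detectionWindow = c(170, 2000),
                      matchMode = "exact",
                      seed = 1) {
  stopifnot(minReplicates >= 1, tolPpm > 0)
  if (!is.null(identTable) && !file.exists(identTable))
    stop("identification table not found: ", identTable)
  for (p in c(fasta, bioactiveDb))
    if (!file.exists(p)) stop("input file not found: ", p)
  structure(list(outDir = outDir, identTable = identTable,
                 dialect = dialect, fasta = fasta,
                 bioactiveDb = bioactiveDb, genotypes = genotypes,
                 minReplicates = minReplicates, tolPpm = tolPpm, pH = pH,
                 oppWindow = oppWindow, detectionWindow = detectionWindow,
                 matchMode = matchMode, seed = seed),
            class = "lactopep_config")
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full peptidomics pipeline
#'
#' Chains the analysis stages and writes every artifact as TSV under the
#' configured output directory: the (simulated) identification table,
#' per-strain count summary, consensus peptide sets, presence/absence
#' matrix, set overlaps (for up to 5 strains), per-residue substrate
#' profiles, physicochemical property distributions, the curated bioactive
#' database with provenance and activity intersections, per-strain matches
#' and the final report. A `run_log.txt` records the parameters actually
#' used and MD5 checksums of the inputs. Artifacts are regenerable from
#' config plus seed alone.
#'
#' @param config a configuration from [runConfig()].
#' @return Invisibly, a list with the in-memory results (`samples`,
#'   `consensus`, `counts`, `overlaps`, `profiles`, `properties`, `db`,
#'   `matches`, `report`, `artifacts`).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "lactopep_config"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  art <- character(0)
  out <- function(name) file.path(config$outDir, name)

  if (is.null(config$identTable)) {
    panel <- simulatePanel(config$genotypes,
                           digestConfig(seed = config$seed,
                                        oppWindow = config$oppWindow,
                                        detectionWindow = config$detectionWindow))
    s <- panel$combined
    art <- c(art, writeIdentTable(s, out("ident_table.tsv")))
  } else {
    s <- readIdentTable(config$identTable, config$dialect)
  }
  protein <- readFastaProteins(config$fasta)[1L, , drop = FALSE]

  counts <- countSummary(s)
  art <- c(art, .write_tsv(counts, out("count_summary.tsv")))

  sets <- consensusPeptides(s, minReplicates = config$minReplicates)
  cons_tab <- do.call(rbind, lapply(names(sets), function(st)
    if (length(sets[[st]])) data.frame(strain = st, sequence = sets[[st]])))
  if (!is.null(cons_tab))
    art <- c(art, .write_tsv(cons_tab, out("consensus_peptides.tsv")))

  pa <- presenceAbsenceMatrix(sets, cluster = length(sets) > 1L)
  pa_tab <- data.frame(sequence = rownames(pa),
                       as.data.frame(unclass(pa[, , drop = FALSE])),
                       check.names = FALSE)
  art <- c(art, .write_tsv(pa_tab, out("presence_absence.tsv")))
  overlaps <- if (length(sets) <= 5L) setOverlaps(sets) else NULL
  if (!is.null(overlaps))
    art <- c(art, .write_tsv(overlaps, out("set_overlaps.tsv")))

  profiles <- lapply(names(sets), function(st) {
    peps <- sets[[st]]
    ints <- vapply(peps, function(p)
      meanRelativeIntensity(s, st, p), numeric(1))
    buildProfile(peps, protein, intensities = unname(ints))
  })
  names(profiles) <- names(sets)
  prof_tab <- profileExport(profiles, out("profiles.tsv"))
  art <- c(art, out("profiles.tsv"))

  props <- propertyDistributions(sets, pH = config$pH)
  art <- c(art, .write_tsv(props$summary, out("property_summary.tsv")))
  if (!is.null(props$values))
    art <- c(art, .write_tsv(props$values, out("property_values.tsv")))

  db <- curateEntries(mergeSources(readBioactiveSources(config$bioactiveDb)))
  art <- c(art, .write_tsv(entries(db), out("curated_db.tsv")))
  inter <- activityIntersections(db)
  art <- c(art, .write_tsv(inter$set_sizes, out("activity_set_sizes.tsv")),
           .write_tsv(inter$intersections, out("activity_intersections.tsv")))

  matches <- matchPeptides(sets, db, mode = config$matchMode)
  report <- bioactiveReport(matches, s, protein)
  art <- c(art, .write_tsv(report, out("bioactive_report.tsv")))

  inputs <- c(config$fasta, config$bioactiveDb, config$identTable)
  log <- c(
    sprintf("lactopep pipeline run %s", format(Sys.time(), "%Y-%m-%d")),
    sprintf("consensus rule: unique peptide in >= %d distinct replicates",
            config$minReplicates),
    sprintf("precursor tolerance: %g ppm", config$tolPpm),
    sprintf("opp window: %d-%d residues", config$oppWindow[1],
            config$oppWindow[2]),
    sprintf("detection window: %g-%g Da", config$detectionWindow[1],
            config$detectionWindow[2]),
    sprintf("match mode: %s", config$matchMode),
    sprintf("seed: %d", config$seed),
    "input checksums:",
    sprintf("  %s  %s", tools::md5sum(inputs), inputs))
  writeLines(log, out("run_log.txt"))
  art <- c(art, out("run_log.txt"))

  invisible(list(samples = s, consensus = sets, counts = counts,
                 overlaps = overlaps, profiles = profiles,
                 properties = props, db = db, matches = matches,
                 report = report, artifacts = art))
}
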