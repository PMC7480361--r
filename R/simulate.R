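# Stochastic in-silico proteolysis: PrtP primary digestion, Opp transport,
# intracellular peptidase rounds shaped by knockout genotypes, MS detection,
# intensities, replicate structure and mass noise.

#' Peptidase cleavage rules of the L. lactis proteolytic system
#'
#' The 15 deletable intracellular peptidases, grouped by cleavage class:
#' endopeptidases cleave internal bonds (C-terminal-residue preference for
#' E, F and P); general aminopeptidases remove the N-terminal residue (but,
#' like all general exopeptidases here, cannot act when residue 2 is
#' proline — the reason the proline-specific enzymes exist); PepA only
#' releases N-terminal D/E; Pcp acts on pyroglutamate-like N-terminal Q;
#' PepX (X-prolyl dipeptidyl aminopeptidase) removes the N-terminal
#' dipeptide when residue 2 is P; PepP (aminopeptidase P) releases the
#' residue before a position-2 proline; PepT decomposes tripeptides and
#' PepV/PepDA/PepDB dipeptides into free amino acids; PepQ (prolidase)
#' hydrolyses X-Pro dipeptides. `p_act` is the per-round Bernoulli firing
#' probability of each rule. PepM is essential and outside the rule set.
#'
#' @param p_act_endo,p_act_exo per-round firing probabilities for
#'   endopeptidases and for all other classes (defaults chosen so that a
#'   finite-round digest leaves a partially degraded peptidome, as in cells
#'   harvested during active casein utilization).
#' @return data.frame with columns `gene`, `class`, `p_act`; attribute
#'   `endo_weights` holds the C-terminal-residue sampling weights of
#'   endopeptidase cleavage.
#' @export
peptidaseRules <- function(p_act_endo = 0.2, p_act_exo = 0.3) {
  rules <- data.frame(
    gene = c("pepO", "pepO2", "pepF1", "pepF2",
             "pepN", "pepC", "pepA", "pcp",
             "pepX", "pepP", "pepT", "pepV", "pepDA", "pepDB", "pepQ"),
    class = c(rep("endopeptidase", 4),
              "aminopeptidase", "aminopeptidase", "aminopeptidase-DE",
              "pyroglutamyl",
              "x-prolyl-dipeptidyl", "aminopeptidase-P", "tripeptidase",
              rep("dipeptidase", 3), "prolidase"),
    stringsAsFactors = FALSE)
  rules$p_act <- ifelse(rules$class == "endopeptidase", p_act_endo,
                        p_act_exo)
  if (any(rules$p_act <= 0 | rules$p_act > 1))
    stop("p_act must be in (0, 1]")
  w <- c(E = 4, F = 4, P = 4)
  weights <- structure(rep(1, 20), names = names(residueMasses()))
  weights[names(w)] <- w
  attr(rules, "endo_weights") <- weights
  rules
}

#' The seven-strain genotype panel of the peptidomics study design
#'
#' Wild type plus six multi-peptidase deletion genotypes: all
#' endopeptidases; all general aminopeptidases (PepM being essential); the
#' proline-specific peptidases; the di-/tripeptidases; and two half-deleted
#' genotypes.
#'
#' @return List of [Genotype-class] objects.
#' @export
genotypePanel <- function() {
  list(
    Genotype("MG1363"),
    Genotype("MGdpepOF2O2", c("pepO", "pepF2", "pepO2")),
    Genotype("MGdpepNXOTCF2O2",
             c("pepN", "pepX", "pepO", "pepT", "pepC", "pepF2", "pepO2")),
    Genotype("MGdpepXPQ", c("pepX", "pepP", "pepQ")),
    Genotype("MGdpepVDATDB", c("pepV", "pepDA", "pepT", "pepDB")),
    Genotype("MGdpepNXOTCVDA",
             c("pepN", "pepX", "pepO", "pepT", "pepC", "pepV", "pepDA")),
    Genotype("MGdpepANCpcp", c("pepA", "pepN", "pepC", "pcp")))
}

#' Construct a DigestConfig
#'
#' Defaults encode the study conditions: the bundled beta-casein precursor
#' with its 15-residue signal peptide, an Opp transport window of 4-18
#' residues, an MS detection window of 170-2000 Da, biological triplicates,
#' and mild PrtP preference for cleaving after Q, E and L.
#'
#' @param substrate precursor sequence (default the bundled P02666
#'   beta-casein precursor).
#' @param accession substrate accession label.
#' @param signalPeptideLen residues removed before digestion.
#' @param prtpCleaveProb per-bond base cleavage probability of PrtP.
#' @param prtpWeights named multipliers for the residue N-terminal to the
#'   bond; unnamed residues default to 1.
#' @param oppWindow inclusive length window of Opp transport.
#' @param molecules number of substrate molecules digested independently.
#' @param detectionWindow inclusive MS mass window (Da).
#' @param rounds maximum peptidase rounds (stops earlier at a fixed point).
#' @param intensityMeanlog,intensitySdlog log-normal parameters of the
#'   peptide-level latent intensity.
#' @param replicateNoiseSd sdlog of per-replicate multiplicative intensity
#'   noise.
#' @param replicateCount biological replicates per strain.
#' @param dropoutProb per-replicate peptide dropout probability.
#' @param ppmNoiseSd observed-mass noise (ppm standard deviation).
#' @param seed master RNG seed.
#' @return A [DigestConfig-class].
#' @export
digestConfig <- function(substrate = betaCasein()$sequence,
                         accession = "P02666",
                         signalPeptideLen = 15,
                         prtpCleaveProb = 0.08,
                         prtpWeights = c(Q = 2.5, E = 2.5, L = 2.5),
                         oppWindow = c(4, 18),
                         molecules = 100,
                         detectionWindow = c(170, 2000),
                         rounds = 4,
                         intensityMeanlog = 14,
                         intensitySdlog = 1.5,
                         replicateNoiseSd = 0.25,
                         replicateCount = 3,
                         dropoutProb = 0.1,
                         ppmNoiseSd = 3,
                         seed = 1) {
  weights <- structure(rep(1, 20), names = names(residueMasses()))
  weights[names(prtpWeights)] <- prtpWeights
  new("DigestConfig", substrate = substrate, accession = accession,
      signalPeptideLen = as.integer(signalPeptideLen),
      prtpCleaveProb = prtpCleaveProb, prtpWeights = weights,
      oppWindow = as.integer(oppWindow), molecules = as.integer(molecules),
      detectionWindow = as.numeric(detectionWindow),
      rounds = as.integer(rounds),
      intensityMeanlog = intensityMeanlog, intensitySdlog = intensitySdlog,
      replicateNoiseSd = replicateNoiseSd,
      replicateCount = as.integer(replicateCount),
      dropoutProb = dropoutProb, ppmNoiseSd = ppmNoiseSd,
      seed = as.integer(seed))
}

.strainSeed <- function(seed, name) {
  codes <- utf8ToInt(name)
  as.integer((seed + sum(codes * seq_along(codes))) %% 2147483647)
}

.peptide_frame <- function(sequence = character(0), start = integer(0),
                           end = integer(0)) {
  data.frame(sequence = sequence, start = as.integer(start),
             end = as.integer(end), stringsAsFactors = FALSE)
}

#' Primary extracellular digestion by PrtP
#'
#' Removes the signal peptide and cleaves each backbone bond of the mature
#' substrate independently with probability
#' `prtpCleaveProb * weight(residue N-terminal to the bond)`, clamped to
#' `[0, 1]`. Every substrate molecule (`molecules` in the config) is
#' digested with independent draws. Fragments are returned N-to-C per
#' molecule, with 1-based precursor coordinates.
#'
#' Uses the current RNG state; seed beforehand for reproducibility (the
#' simulate functions do this from the config seed).
#'
#' @param config a [DigestConfig-class].
#' @return data.frame with columns `sequence`, `start`, `end` (one row per
#'   fragment, molecules concatenated).
#' @export
prtpDigest <- function(config) {
  stopifnot(is(config, "DigestConfig"))
  mature <- substring(config@substrate, config@signalPeptideLen + 1L)
  chars <- strsplit(mature, "")[[1]]
  n <- length(chars)
  p <- pmin(pmax(config@prtpCleaveProb *
                 config@prtpWeights[chars[-n]], 0), 1)
  out <- vector("list", config@molecules)
  for (m in seq_len(config@molecules)) {
    cut <- stats::runif(n - 1L) < p
    bounds <- c(0L, which(cut), n)
    starts <- utils::head(bounds, -1L) + 1L
    ends <- bounds[-1L]
    out[[m]] <- .peptide_frame(
      substring(mature, starts, ends),
      starts + config@signalPeptideLen,
      ends + config@signalPeptideLen)
  }
  do.call(rbind, out)
}

#' Opp transport length filter
#'
#' Retains peptides whose length lies in the inclusive window (default
#' 4-18 residues, the capacity of the lactococcal oligopeptide permease).
#'
#' @param peptides data.frame with a `sequence` column (coordinates
#'   preserved).
#' @param window integer `[lo, hi]`.
#' @return Filtered data.frame.
#' @export
oppFilter <- function(peptides, window = c(4, 18)) {
  stopifnot(length(window) == 2L, window[1] <= window[2])
  len <- nchar(peptides$sequence)
  peptides[len >= window[1] & len <= window[2], , drop = FALSE]
}

.applicability <- function(class, len, res1, res2) {
  switch(class,
    "endopeptidase" = len >= 4L,
    "aminopeptidase" = len >= 2L & res2 != "P",
    "aminopeptidase-DE" = len >= 2L & res1 %in% c("D", "E") & res2 != "P",
    "pyroglutamyl" = len >= 2L & res1 == "Q" & res2 != "P",
    "x-prolyl-dipeptidyl" = len >= 3L & res2 == "P",
    "aminopeptidase-P" = len >= 3L & res2 == "P",
    "tripeptidase" = len == 3L,
    "dipeptidase" = len == 2L & res2 != "P",
    "prolidase" = len == 2L & res2 == "P",
    stop("unknown peptidase class: ", class))
}

#' One round of intracellular peptidase action
#'
#' For every peptide, the rules of the full rule table are evaluated in
#' table order; each rule draws its Bernoulli variate (one uniform matrix
#' per round; draws are consumed also for deleted genes, so RNG streams
#' stay aligned between genotypes as long as the pools coincide), and the
#' first rule that fires, is not deleted and is applicable to the peptide
#' acts on it. Endopeptidase firings additionally consume one bond-choice
#' uniform each, again regardless of deletion. Products re-enter the pool
#' for the next round; fragments shorter than 2 residues (free amino
#' acids) leave the pool. Uses the current RNG state.
#'
#' @param peptides data.frame (`sequence`, `start`, `end`).
#' @param rules rule table from [peptidaseRules()].
#' @param deleted character vector of deleted genes (inactive rules).
#' @return list with `peptides` (the pool after the round) and `events`
#'   (data.frame: `gene`, `parent`, `children` (`+`-joined product
#'   sequences), `bonds`).
#' @export
peptidaseRound <- function(peptides, rules = peptidaseRules(),
                           deleted = character(0)) {
  n <- nrow(peptides)
  empty_events <- data.frame(gene = character(0), parent = character(0),
                             children = character(0), bonds = integer(0))
  if (n == 0L)
    return(list(peptides = .peptide_frame(), events = empty_events))
  endo_weights <- attr(rules, "endo_weights")
  R <- nrow(rules)
  seqs <- peptides$sequence
  len <- nchar(seqs)
  res1 <- substr(seqs, 1L, 1L)
  res2 <- substr(seqs, 2L, 2L)
  U <- matrix(stats::runif(n * R), n, R)
  fires <- sweep(U, 2L, rules$p_act, "<")
  applic <- vapply(seq_len(R), function(r)
    .applicability(rules$class[r], len, res1, res2), logical(n))
  if (n == 1L) applic <- matrix(applic, 1L, R)
  want <- fires & applic
  # endopeptidase bond-choice uniforms: one per wanted endo event, consumed
  # in column-major order whether or not the gene is deleted
  endo_cols <- which(rules$class == "endopeptidase")
  endo_idx <- matrix(0L, n, R)
  endo_mask <- matrix(FALSE, n, R)
  endo_mask[, endo_cols] <- want[, endo_cols, drop = FALSE]
  k <- sum(endo_mask)
  endo_idx[endo_mask] <- seq_len(k)
  V <- stats::runif(k)
  active <- !(rules$gene %in% deleted)
  eligible <- sweep(want, 2L, active, "&")
  first <- integer(n)
  for (i in seq_len(n)) {
    w <- which(eligible[i, ])
    first[i] <- if (length(w)) w[1] else 0L
  }
  keep_seq <- keep_start <- keep_end <- vector("list", n)
  ev_gene <- ev_parent <- ev_children <- character(0)
  ev_bonds <- integer(0)
  for (i in seq_len(n)) {
    r <- first[i]
    if (r == 0L) {
      keep_seq[[i]] <- seqs[i]
      keep_start[[i]] <- peptides$start[i]
      keep_end[[i]] <- peptides$end[i]
      next
    }
    cls <- rules$class[r]
    s <- seqs[i]; a <- peptides$start[i]; b <- peptides$end[i]; m <- len[i]
    if (cls == "endopeptidase") {
      chars <- strsplit(s, "")[[1]]
      w <- endo_weights[chars[2:(m - 2L)]]
      cw <- cumsum(w)
      pos <- min(findInterval(V[endo_idx[i, r]] * cw[length(cw)], cw) + 1L,
                 length(cw))
      j <- (2:(m - 2L))[pos]
      kids <- c(substr(s, 1L, j), substr(s, j + 1L, m))
      keep_seq[[i]] <- kids
      keep_start[[i]] <- c(a, a + j)
      keep_end[[i]] <- c(a + j - 1L, b)
      bonds <- 1L
    } else if (cls == "tripeptidase") {
      kids <- strsplit(s, "")[[1]]
      bonds <- 2L
    } else if (cls %in% c("dipeptidase", "prolidase")) {
      kids <- strsplit(s, "")[[1]]
      bonds <- 1L
    } else if (cls == "x-prolyl-dipeptidyl") {
      kids <- c(substr(s, 1L, 2L), substr(s, 3L, m))
      keep <- if (m - 2L >= 2L) c(TRUE, TRUE) else c(TRUE, FALSE)
      keep_seq[[i]] <- kids[keep]
      keep_start[[i]] <- c(a, a + 2L)[keep]
      keep_end[[i]] <- c(a + 1L, b)[keep]
      bonds <- 1L
    } else { # single-residue-releasing aminopeptidases
      kids <- c(substr(s, 1L, 1L), substr(s, 2L, m))
      if (m - 1L >= 2L) {
        keep_seq[[i]] <- kids[2]
        keep_start[[i]] <- a + 1L
        keep_end[[i]] <- b
      }
      bonds <- 1L
    }
    ev_gene <- c(ev_gene, rules$gene[r])
    ev_parent <- c(ev_parent, s)
    ev_children <- c(ev_children, paste(kids, collapse = "+"))
    ev_bonds <- c(ev_bonds, bonds)
  }
  out <- .peptide_frame(unlist(keep_seq), unlist(keep_start),
                        unlist(keep_end))
  events <- if (length(ev_gene))
    data.frame(gene = ev_gene, parent = ev_parent, children = ev_children,
               bonds = ev_bonds, stringsAsFactors = FALSE)
  else empty_events
  list(peptides = out, events = events)
}

#' Simulate the intracellular peptidome of one strain
#'
#' Runs the full pathway for a genotype: PrtP digestion of `molecules`
#' substrate copies, Opp length filtering, peptidase rounds to a fixed
#' point or the round limit, and MS detection by monoisotopic mass window.
#' Each surviving peptide instance draws a log-normal latent intensity
#' shared across replicates; per replicate it is dropped out with
#' `dropoutProb`, its intensity multiplied by log-normal noise, and its
#' observed mass jittered by Normal(0, `ppmNoiseSd` ppm) relative error.
#' Fully reproducible: the RNG is seeded from the config seed and the
#' strain name.
#'
#' @param genotype a [Genotype-class].
#' @param config a [DigestConfig-class].
#' @return A [SampleSet-class] with attributes `digest_log` (per-round
#'   cleavage events), `peptides` (ground-truth surviving fragments with
#'   precursor coordinates and theoretical masses) and `seed` (the derived
#'   strain seed).
#' @export
simulateStrain <- function(genotype, config = digestConfig()) {
  stopifnot(is(genotype, "Genotype"), is(config, "DigestConfig"))
  seed <- .strainSeed(config@seed, genotype@name)
  set.seed(seed)
  rules <- peptidaseRules()
  pool <- prtpDigest(config)
  pool <- oppFilter(pool, config@oppWindow)
  log <- NULL
  for (round in seq_len(config@rounds)) {
    res <- peptidaseRound(pool, rules, deleted = genotype@deleted)
    pool <- res$peptides
    if (!nrow(res$events)) break
    log <- rbind(log, cbind(round = round, res$events))
  }
  theo <- if (nrow(pool)) monoisotopicMass(pool$sequence) else numeric(0)
  detected <- theo >= config@detectionWindow[1] &
    theo <= config@detectionWindow[2]
  pool <- pool[detected, , drop = FALSE]
  theo <- theo[detected]
  n <- nrow(pool)
  latent <- stats::rlnorm(n, config@intensityMeanlog, config@intensitySdlog)
  recs <- vector("list", config@replicateCount)
  for (rep_i in seq_len(config@replicateCount)) {
    drop <- stats::runif(n) < config@dropoutProb
    noise <- stats::rlnorm(n, 0, config@replicateNoiseSd)
    eps <- stats::rnorm(n, 0, config@ppmNoiseSd * 1e-6)
    keep <- which(!drop)
    recs[[rep_i]] <- data.frame(
      strain = genotype@name, replicate = rep_i,
      sequence = pool$sequence[keep], mods = "",
      observed_mass = theo[keep] * (1 + eps[keep]),
      intensity = latent[keep] * noise[keep],
      protein_hint = config@accession, stringsAsFactors = FALSE)
  }
  ss <- SampleSet(do.call(rbind, recs),
                  stats::setNames(config@replicateCount, genotype@name))
  attr(ss, "digest_log") <- if (is.null(log))
    data.frame(round = integer(0), gene = character(0),
               parent = character(0), children = character(0),
               bonds = integer(0))
  else log
  attr(ss, "peptides") <- cbind(pool, theoretical_mass = theo)
  attr(ss, "seed") <- seed
  ss
}

#' Simulate a panel of strains
#'
#' Runs [simulateStrain()] for every genotype with deterministic per-strain
#' seeds derived from the master seed and strain name, and returns the
#' per-strain sample sets, a combined [SampleSet-class], and the
#' ground-truth digest logs for assertions.
#'
#' @param genotypes list of [Genotype-class] objects with unique names.
#' @param config a [DigestConfig-class].
#' @return list with `sets` (named list of [SampleSet-class]), `combined`
#'   (one [SampleSet-class] over all strains), `log` and `truth` (named
#'   lists of digest logs / ground-truth peptide tables).
#' @export
simulatePanel <- function(genotypes, config = digestConfig()) {
  if (is(genotypes, "Genotype")) genotypes <- list(genotypes)
  nm <- vapply(genotypes, function(g) g@name, character(1))
  if (anyDuplicated(nm))
    stop("duplicate strain name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- lapply(genotypes, simulateStrain, config = config)
  names(sets) <- nm
  combined <- SampleSet(
    do.call(rbind, lapply(sets, records)),
    stats::setNames(rep(config@replicateCount, length(nm)), nm))
  list(sets = sets, combined = combined,
       log = lapply(sets, attr, "digest_log"),
       truth = lapply(sets, attr, "peptides"))
}
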