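smallConfig <- function(...) {
  args <- utils::modifyList(list(molecules = 10, seed = 7), list(...))
  do.call(digestConfig, args)
}

test_that("PrtP digestion spans the degenerate cleavage probabilities", {
  cfg0 <- smallConfig(prtpCleaveProb = 0, molecules = 1)
  set.seed(1)
  frags <- prtpDigest(cfg0)
  expect_equal(nrow(frags), 1L)
  expect_equal(frags$sequence, substring(cfg0@substrate, 16))
  expect_equal(c(frags$start, frags$end), c(16L, 224L))
  cfg1 <- smallConfig(prtpCleaveProb = 1, prtpWeights = numeric(0),
                      molecules = 1)
  set.seed(1)
  all1 <- prtpDigest(cfg1)
  expect_true(all(nchar(all1$sequence) == 1L))
  expect_equal(nrow(all1), 209L)
})

test_that("PrtP fragments reassemble the mature substrate with coordinates", {
  cfg <- smallConfig(molecules = 1)
  set.seed(5)
  frags <- prtpDigest(cfg)
  expect_equal(paste(frags$sequence, collapse = ""),
               substring(cfg@substrate, 16))
  expect_equal(nchar(frags$sequence), frags$end - frags$start + 1L)
  for (i in seq_len(nrow(frags)))
    expect_equal(substring(cfg@substrate, frags$start[i], frags$end[i]),
                 frags$sequence[i])
})

test_that("the Opp filter keeps the inclusive 4-18 residue window", {
  peps <- data.frame(sequence = c("AGC", "AGCW", strrep("A", 18),
                                  strrep("A", 19)),
                     start = 1L, end = 1L)
  out <- oppFilter(peps, c(4, 18))
  expect_setequal(out$sequence, c("AGCW", strrep("A", 18)))
  # brute-force length filter on random peptides
  set.seed(161)
  rp <- data.frame(sequence = randomPeptides(50, 1, 25), start = 1L,
                   end = 1L)
  expect_equal(oppFilter(rp, c(4, 18))$sequence,
               rp$sequence[nchar(rp$sequence) >= 4 &
                           nchar(rp$sequence) <= 18])
})

test_that("peptidase rules cover the 15 deletable genes and pepM is
           protected", {
  rules <- peptidaseRules()
  expect_equal(nrow(rules), 15L)
  expect_false("pepM" %in% rules$gene)
  expect_error(Genotype("bad", "pepM"), "essential")
  expect_error(Genotype("bad", "pepZZ"), "unknown peptidase")
})

test_that("an empty rule set leaves the pool unchanged", {
  pool <- data.frame(sequence = c("KVLPVPQ", "AGCW"), start = c(1L, 10L),
                     end = c(7L, 13L))
  rules <- peptidaseRules()
  set.seed(1)
  out <- peptidaseRound(pool, rules, deleted = rules$gene)
  expect_equal(out$peptides, pool, ignore_attr = TRUE)
  expect_equal(nrow(out$events), 0L)
})

test_that("PepX removes the N-terminal dipeptide of X-Pro peptides", {
  rules <- peptidaseRules(p_act_endo = 1, p_act_exo = 1)
  pool <- data.frame(sequence = "APGKW", start = 1L, end = 5L)
  active_only_pepX <- setdiff(rules$gene, "pepX")
  set.seed(2)
  out <- peptidaseRound(pool, rules, deleted = active_only_pepX)
  expect_equal(out$events$gene, "pepX")
  expect_setequal(out$peptides$sequence, c("AP", "GKW"))
  expect_equal(out$peptides$start[out$peptides$sequence == "GKW"], 3L)
})

test_that("general aminopeptidases stall at position-2 proline", {
  rules <- peptidaseRules(p_act_endo = 1, p_act_exo = 1)
  only <- function(gene) setdiff(rules$gene, gene)
  set.seed(3)
  # PepN trims a normal N-terminus
  out <- peptidaseRound(data.frame(sequence = "AGKW", start = 1L, end = 4L),
                        rules, deleted = only("pepN"))
  expect_equal(out$peptides$sequence, "GKW")
  # but not an X-Pro one
  set.seed(3)
  out2 <- peptidaseRound(data.frame(sequence = "APKW", start = 1L, end = 4L),
                         rules, deleted = only("pepN"))
  expect_equal(out2$peptides$sequence, "APKW")
  expect_equal(nrow(out2$events), 0L)
  # PepA requires an acidic N-terminal residue
  set.seed(3)
  out3 <- peptidaseRound(data.frame(sequence = "AGKW", start = 1L, end = 4L),
                         rules, deleted = only("pepA"))
  expect_equal(nrow(out3$events), 0L)
  set.seed(3)
  out4 <- peptidaseRound(data.frame(sequence = "EGKW", start = 1L, end = 4L),
                         rules, deleted = only("pepA"))
  expect_equal(out4$peptides$sequence, "GKW")
})

test_that("terminal peptidases decompose 2-3-mers into invisible residues", {
  rules <- peptidaseRules(p_act_endo = 1, p_act_exo = 1)
  only <- function(gene) setdiff(rules$gene, gene)
  set.seed(4)
  tri <- peptidaseRound(data.frame(sequence = "AGW", start = 1L, end = 3L),
                        rules, deleted = only("pepT"))
  expect_equal(nrow(tri$peptides), 0L)
  expect_equal(tri$events$bonds, 2L)
  set.seed(4)
  di <- peptidaseRound(data.frame(sequence = "AW", start = 1L, end = 2L),
                       rules, deleted = only("pepV"))
  expect_equal(nrow(di$peptides), 0L)
  # plain dipeptidase cannot touch X-Pro; prolidase can
  set.seed(4)
  xp <- peptidaseRound(data.frame(sequence = "AP", start = 1L, end = 2L),
                       rules, deleted = only("pepV"))
  expect_equal(xp$peptides$sequence, "AP")
  set.seed(4)
  xp2 <- peptidaseRound(data.frame(sequence = "AP", start = 1L, end = 2L),
                        rules, deleted = only("pepQ"))
  expect_equal(nrow(xp2$peptides), 0L)
})

test_that("with all endopeptidases deleted a 16-mer is never cleaved
           internally", {
  rules <- peptidaseRules(p_act_endo = 1, p_act_exo = 1)
  endo <- rules$gene[rules$class == "endopeptidase"]
  pool <- data.frame(sequence = "TQTPVVVPPFLQPEVM", start = 93L, end = 108L)
  set.seed(6)
  out <- peptidaseRound(pool, rules, deleted = c(endo, "pepT"))
  expect_false(any(out$events$gene %in% endo))
  # only N-terminal trimming can have occurred: products are suffixes
  expect_true(all(vapply(out$peptides$sequence, function(p)
    endsWith("TQTPVVVPPFLQPEVM", p), logical(1))))
})

test_that("cleavage events conserve mass up to one water per broken bond", {
  water <- attr(residueMasses(), "water")
  s <- simulateStrain(Genotype("MG1363"), smallConfig())
  log <- attr(s, "digest_log")
  expect_gt(nrow(log), 50)
  kids <- strsplit(log$children, "+", fixed = TRUE)
  lhs <- vapply(kids, function(k) sum(monoisotopicMass(k)), numeric(1))
  rhs <- monoisotopicMass(log$parent) + log$bonds * water
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("every simulated peptide is an exact substring of the mature
           substrate at its recorded position", {
  cfg <- smallConfig()
  s <- simulateStrain(Genotype("MGdpepXPQ", c("pepX", "pepP", "pepQ")), cfg)
  truth <- attr(s, "peptides")
  for (i in seq_len(nrow(truth))) {
    expect_equal(substring(cfg@substrate, truth$start[i], truth$end[i]),
                 truth$sequence[i])
    expect_gte(truth$start[i], 16L)
  }
  expect_true(all(vapply(records(s)$sequence, function(p)
    nrow(locatePeptide(p, betaCasein())) > 0, logical(1))))
})

test_that("simulation replays byte-identically from the same seed", {
  cfg <- smallConfig()
  gt <- Genotype("MGdpepOF2O2", c("pepO", "pepF2", "pepO2"))
  a <- simulateStrain(gt, cfg)
  b <- simulateStrain(gt, cfg)
  expect_identical(records(a), records(b))
  expect_identical(attr(a, "digest_log"), attr(b, "digest_log"))
  # and differs for a different master seed
  c_ <- simulateStrain(gt, digestConfig(molecules = 10, seed = 8))
  expect_false(identical(records(a), records(c_)))
})

test_that("zero dropout keeps every peptide in all replicates so consensus
           removes nothing", {
  cfg <- smallConfig(dropoutProb = 0)
  s <- simulateStrain(Genotype("MG1363"), cfg)
  rec <- records(s)
  per_rep <- table(rec$replicate)
  expect_equal(length(unique(per_rep)), 1L)
  expect_setequal(consensusPeptides(s, 2)$MG1363,
                  unique(rec$sequence))
})

test_that("observed masses stay within the normal-tail ppm bound", {
  s <- simulateStrain(Genotype("MG1363"), digestConfig(seed = 3))
  rec <- records(s)
  theo <- monoisotopicMass(rec$sequence)
  ppm <- ppmError(rec$observed_mass, theo)
  # Normal(0, 3 ppm) noise: essentially all records inside 4 sigma, none
  # beyond 6 sigma at this sample size
  expect_gte(mean(abs(ppm) <= 4 * 3), 0.999)
  expect_lt(max(abs(ppm)), 6 * 3)
  expect_lt(abs(mean(ppm)), 1)
})

test_that("deleting the terminal mop-up peptidases never decreases the
           small-peptide pool", {
  cfg <- smallConfig()
  wt <- attr(simulateStrain(Genotype("MG1363"), cfg), "peptides")
  nd <- attr(simulateStrain(
    Genotype("MG1363", c("pepT", "pepV", "pepDA", "pepDB", "pepQ")),
    cfg), "peptides")
  expect_gte(sum(nchar(nd$sequence) <= 3), sum(nchar(wt$sequence) <= 3))
})

test_that("a panel simulates every genotype with unique deterministic
           streams", {
  cfg <- smallConfig()
  gts <- list(Genotype("MG1363"),
              Genotype("MGdpepXPQ", c("pepX", "pepP", "pepQ")))
  panel <- simulatePanel(gts, cfg)
  expect_setequal(strainNames(panel$combined), c("MG1363", "MGdpepXPQ"))
  expect_identical(records(panel$sets$MG1363),
                   records(simulateStrain(gts[[1]], cfg)))
  expect_error(simulatePanel(list(Genotype("x"), Genotype("x")), cfg),
               "duplicate")
  single <- simulatePanel(list(Genotype("MG1363")), cfg)
  expect_identical(records(single$combined),
                   records(simulateStrain(gts[[1]], cfg)))
})
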