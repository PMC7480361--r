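toySource <- function(sequence, activities = "ACE-I", references = "r1",
                      source = "SRC-A", has_reference = TRUE,
                      predicted_only = FALSE, sequence_discrepancy = FALSE,
                      bitter_only = FALSE, fragment_start = NA,
                      fragment_end = NA) {
  data.frame(sequence = sequence, parent = "P02666",
             fragment_start = fragment_start, fragment_end = fragment_end,
             activities = activities, references = references,
             source = source, has_reference = has_reference,
             predicted_only = predicted_only,
             sequence_discrepancy = sequence_discrepancy,
             bitter_only = bitter_only)
}

test_that("merging unions evidence across sources by sequence", {
  a <- toySource("YPFPGPI", activities = "Opioid", references = "",
                 source = "SRC-A", has_reference = FALSE)
  b <- toySource("YPFPGPI", activities = "Opioid;ACE-I", references = "r35",
                 source = "SRC-B")
  m <- mergeSources(a, b)
  expect_equal(nrow(m), 1L)
  expect_true(m$has_reference)  # any source providing one suffices
  expect_equal(m$activities, "ACE-I;Opioid")
  expect_equal(m$source_db, "SRC-A;SRC-B")
  # disjoint sequences concatenate
  m2 <- mergeSources(toySource("AAAA"), toySource("CCCC"))
  expect_equal(nrow(m2), 2L)
})

test_that("merge is idempotent and flag combination is conservative", {
  a <- toySource("KVLPVPQ", predicted_only = TRUE)
  b <- toySource("KVLPVPQ", predicted_only = FALSE, source = "SRC-B")
  m <- mergeSources(a, b)
  expect_false(m$predicted_only)   # one experimentally supported source wins
  d <- mergeSources(toySource("AAAA", sequence_discrepancy = TRUE),
                    toySource("AAAA", source = "SRC-B"))
  expect_true(d$sequence_discrepancy)  # a discrepancy taints the entry
  twice <- mergeSources(m)
  expect_equal(twice, m)
})

test_that("conflicting fragment coordinates warn and keep alternatives", {
  a <- toySource("AAAA", fragment_start = 10, fragment_end = 13)
  b <- toySource("AAAA", fragment_start = 20, fragment_end = 23,
                 source = "SRC-B")
  expect_warning(m <- mergeSources(a, b), "conflicting fragment")
  expect_equal(m$fragment_start, 10)
  expect_equal(m$alt_fragments, "20-23")
})

test_that("curation applies the four exclusion rules", {
  src <- rbind(toySource("AAAA"),
               toySource("CCCC", has_reference = FALSE, references = ""),
               toySource("DDDD", predicted_only = TRUE),
               toySource("EEEE", sequence_discrepancy = TRUE),
               toySource("FFFF", activities = "other:bitter",
                         bitter_only = TRUE))
  db <- curateEntries(mergeSources(src))
  expect_equal(entries(db)$sequence, "AAAA")
  prov <- provenance(db)
  expect_equal(prov$input_n, 5L)
  expect_equal(prov$retained_n, 1L)
  expect_equal(unname(prov$excluded_by_rule),
               c(1L, 1L, 1L, 1L))
  # a fully clean set is retained in full, and curation is idempotent
  clean <- mergeSources(rbind(toySource("AAAA"), toySource("CCCC"),
                              toySource("DDDD"), toySource("EEEE"),
                              toySource("FFFF")))
  db2 <- curateEntries(clean)
  expect_equal(nrow(entries(db2)), 5L)
  db3 <- curateEntries(entries(db2))
  expect_equal(entries(db3)$sequence, entries(db2)$sequence)
})

test_that("curation survivors equal the brute-force predicate filter", {
  set.seed(131)
  for (trial in 1:10) {
    n <- 30
    src <- toySource(unique(randomPeptides(n, 4, 8)))
    n <- nrow(src)
    src$has_reference <- sample(c(TRUE, FALSE), n, replace = TRUE, c(.8, .2))
    src$predicted_only <- sample(c(TRUE, FALSE), n, replace = TRUE, c(.2, .8))
    src$sequence_discrepancy <- sample(c(TRUE, FALSE), n, replace = TRUE,
                                       c(.1, .9))
    src$bitter_only <- sample(c(TRUE, FALSE), n, replace = TRUE, c(.1, .9))
    db <- curateEntries(mergeSources(src))
    keep <- character(0)
    for (i in seq_len(n))
      if (src$has_reference[i] && !src$predicted_only[i] &&
          !src$sequence_discrepancy[i] && !src$bitter_only[i])
        keep <- c(keep, src$sequence[i])
    expect_setequal(entries(db)$sequence, keep)
    expect_lte(nrow(entries(db)), n)
  }
})

test_that("activity intersections follow UpSet semantics", {
  src <- rbind(toySource("AAAA", activities = "PEP-I"),
               toySource("CCCC", activities = "PEP-I"),
               toySource("DDDD", activities = "PEP-I"),
               toySource("EEEE", activities = "PEP-I;ACE-I"),
               toySource("FFFF", activities = "ACE-I"))
  out <- activityIntersections(curateEntries(mergeSources(src)))
  expect_equal(out$set_sizes$size[out$set_sizes$activity == "PEP-I"], 4L)
  expect_equal(out$intersections$size[out$intersections$pattern == "PEP-I"],
               3L)
  expect_equal(out$intersections$size[
    out$intersections$pattern == "ACE-I&PEP-I"], 1L)
  expect_equal(out$multi_activity, 1L)
  single <- activityIntersections(curateEntries(mergeSources(
    rbind(toySource("AAAA"), toySource("CCCC", activities = "AntiO")))))
  expect_equal(single$multi_activity, 0L)
})

test_that("intersection counts satisfy the partition identities and match
           exhaustive enumeration", {
  set.seed(141)
  vocab <- c("ACE-I", "DPP-IV-I", "Immuno", "AntiM", "AntiO", "PEP-I",
             "Opioid")
  for (trial in 1:10) {
    peps <- unique(randomPeptides(25, 4, 8))
    acts <- lapply(seq_along(peps), function(i)
      sort(sample(vocab, sample(1:3, 1))))
    src <- toySource(peps)
    src$activities <- vapply(acts, paste, "", collapse = ";")
    db <- curateEntries(mergeSources(src))
    out <- activityIntersections(db)
    expect_equal(sum(out$intersections$size), nrow(entries(db)))
    # set size of each activity = sum of intersections containing it
    for (a in out$set_sizes$activity) {
      in_pattern <- vapply(strsplit(out$intersections$pattern, "&"),
                           function(p) a %in% p, logical(1))
      expect_equal(out$set_sizes$size[out$set_sizes$activity == a],
                   sum(out$intersections$size[in_pattern]))
    }
    # exhaustive per-pattern oracle over the merged entry list
    ent <- entries(db)
    for (k in seq_len(nrow(out$intersections))) {
      pat <- sort(strsplit(out$intersections$pattern[k], "&")[[1]])
      oracle <- sum(vapply(ent$activities, function(x)
        identical(sort(strsplit(x, ";")[[1]]), pat), logical(1)))
      expect_equal(out$intersections$size[k], oracle)
    }
    expect_equal(out$multi_activity, sum(lengths(acts[match(ent$sequence,
                                                            peps)]) >= 2))
  }
})

test_that("activity labels outside the vocabulary are rejected", {
  expect_error(
    curateEntries(mergeSources(toySource("AAAA", activities = "Magic"))) |>
      activityIntersections(),
    "controlled vocabulary")
})

test_that("exact matching returns database hits sorted by fragment start", {
  db <- bundledCuratedDB()
  m <- matchPeptides(list(wt = c("KVLPVPQ", "WWWWW")), db)
  expect_equal(nrow(m$wt), 1L)
  expect_equal(m$wt$sequence, "KVLPVPQ")
  expect_match(m$wt$activities, "ACE-I")
  none <- matchPeptides(list(wt = "WWWWW"), db)
  expect_equal(nrow(none$wt), 0L)
  multi <- matchPeptides(list(wt = c("QEPVLGPVRGPFPIIV", "LNVPGEIVE")), db)
  expect_equal(multi$wt$sequence, c("LNVPGEIVE", "QEPVLGPVRGPFPIIV"))
})

test_that("matching is order invariant and equals the double loop", {
  db <- bundledCuratedDB()
  ent <- entries(db)
  set.seed(151)
  peps <- c(sample(ent$sequence, 5), randomPeptides(5, 4, 8))
  m1 <- matchPeptides(list(a = peps), db)$a
  m2 <- matchPeptides(list(a = rev(peps)), db)$a
  expect_equal(m1, m2)
  brute <- character(0)
  for (p in unique(peps)) for (e in ent$sequence)
    if (p == e) brute <- c(brute, p)
  expect_setequal(m1$sequence, brute)
  expect_true(all(m1$sequence %in% peps))
})

test_that("substring mode finds contained bioactive cores", {
  db <- curateEntries(mergeSources(toySource("KVLP")))
  expect_equal(nrow(matchPeptides(list(a = "AKVLPA"), db)$a), 0L)
  hit <- matchPeptides(list(a = "AKVLPA"), db, mode = "substring")$a
  expect_equal(hit$matched_entry, "KVLP")
})

test_that("the report recomputes masses, locates fragments and marks
           missing replicates with a dash", {
  db <- bundledCuratedDB()
  theo <- monoisotopicMass("YPFPGPIPN")
  s <- makeSampleSet(
    list("wt", 1, "YPFPGPIPN", 10, theo * (1 + 0.9e-6)),
    list("wt", 2, "YPFPGPIPN", 12, theo * (1 + 3.4e-6)),
    list("wt", 3, "AVPYPQR", 5, 829.4446))
  matches <- matchPeptides(list(wt = "YPFPGPIPN", empty = character(0)), db)
  rep <- bioactiveReport(matches, s)
  row <- rep[rep$strain == "wt", ]
  expect_equal(row$fragment, "75-83")
  expect_equal(row$theoretical_mass, 1000.5018, tolerance = 1e-7)
  expect_equal(row$mass_error_ppm, "0.9/3.4/—")
  expect_equal(rep$sequence[rep$strain == "empty"], "None")
  # row count equals match count per strain
  m2 <- matchPeptides(list(wt = c("KVLPVPQ", "AVPYPQR")), db)
  expect_equal(nrow(bioactiveReport(m2)), sum(nrow(m2$wt)))
})

test_that("unlocatable matched peptides warn and emit empty fragments", {
  db <- curateEntries(mergeSources(toySource("WWWW")))
  expect_warning(rep <- bioactiveReport(matchPeptides(list(a = "WWWW"), db)),
                 "does not locate")
  expect_equal(rep$fragment, "")
})
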