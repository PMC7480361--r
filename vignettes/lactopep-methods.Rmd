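---
title: "Models and methods behind lactopep"
author: "lactopep maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lactopep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lactopep)
```

## The biological system

*Lactococcus lactis* is auxotrophic for several amino acids and, in milk,
covers its nitrogen needs by degrading casein in three steps: the cell
envelope proteinase PrtP hydrolyses β-casein into oligopeptides; the
oligopeptide permease Opp internalizes peptides of roughly 4–18 residues;
and 15 intracellular peptidases, grouped by cleavage specificity
(endopeptidases, general aminopeptidases, the acidic-specific PepA,
pyroglutamyl peptidase Pcp, X-prolyl dipeptidyl aminopeptidase PepX,
aminopeptidase P, tripeptidase PepT, dipeptidases PepV/PepDA/PepDB and
prolidase PepQ; PepM is essential and not deletable), decompose them into
free amino acids. Deleting groups of peptidase genes stalls degradation at
characteristic intermediates, so engineered strains accumulate different —
sometimes bioactive — casein fragments in their cytoplasm.

`lactopep` implements the data-analysis layer of such experiments:
everything downstream of the peptide-identification tables produced by an
MS/MS search engine, plus a stochastic in-silico proteolysis generator
that emulates those tables where raw MS data are unavailable.

## Mass model

The neutral monoisotopic mass of a peptide is the sum of its residue
masses plus one water, plus modification deltas. Residue masses are the
standard monoisotopic values (6 decimal places, shipped as
`inst/extdata/residue_masses.tsv` and overridable). The modification
registry mirrors typical search settings: carbamidomethylation of
cysteine (+57.021464 Da) is *fixed* and applied to every cysteine
automatically; oxidation of methionine (+15.994915 Da) and
phosphorylation of serine (+79.966331 Da) are *variable* and contribute
only where declared on a record (`"Oxidation@3"` syntax). Nonstandard
letters (B, J, O, U, X, Z) are rejected with the offending character and
position rather than guessed.

Mass error is the signed relative deviation
`ppm = 10^6 (M_obs - M_theo) / M_theo`; the tolerance check (default
15 ppm, the usual precursor tolerance) is **inclusive** at the bound and
carries a 1e-9-ppm guard so that a value sitting exactly on the bound is
not rejected through floating-point rounding.

Reference tables of theoretical peptide masses in the peptidomics
literature are display output of acquisition software: they carry
4-decimal rounding and, at larger masses, last-digit artifacts consistent
with single-precision arithmetic (one float32 ulp is ~1.2e-4 Da at
1900 Da). The package therefore treats agreement *within two units of the
last printed decimal* as reproduction of a printed mass, while its own
values are full double-precision sums.

## Consensus and summaries

The replicate-consensus rule retains, per strain, every unique peptide
observed (≥ 1 PSM) in at least `minReplicates` (default 2) *distinct*
biological replicates. Two decisions were genuinely open:

* **Peptide identity.** A peptide is identified by the pair (sequence,
  modification multiset) by default — two differently modified forms are
  different peptides for the consensus count — with
  `distinguishMods = FALSE` collapsing to the bare sequence. Either way
  the returned sets contain bare sequences.
* **Mean relative intensity.** The reported value averages per-replicate
  mean intensities over the replicates *where the peptide was observed*;
  absent replicates do not contribute zeros. `zeroFill = TRUE` divides by
  the declared replicate count instead. The observed-only default matches
  the intended meaning of an average over detections; zero-filling
  systematically penalizes peptides near the detection limit.

Presence–absence matrices optionally attach hierarchical-clustering
orders; the method is fixed to Jaccard distance with average linkage, and
labels are sorted before clustering so ties break deterministically.
Set-overlap counts enumerate the full Venn partition for up to five named
sets (beyond five the display metaphor breaks down and the function
refuses).

## Localization and coverage profiles

Coordinates are 1-based inclusive on the **precursor** (the 224-residue
β-casein precursor P02666, whose first 15 residues are the signal
peptide); the mature chain spans 16–224. Localization reports *every*
exact substring occurrence, including overlapping ones, in ascending
start order; absence is an empty result, not an error. Peptides matching
at several positions contribute to the profile at each match — β-casein
has little internal repetition, so this choice is inert there.
Isoleucine and leucine are distinct letters by default (MS cannot
distinguish them, but reference tables report specific sequences); a
`collapseIL` flag maps both to L before matching.

A profile stores, per residue, the number of covering peptide occurrences
and the sum of their mean intensities; gaps are maximal zero-count runs,
and gaps plus covered segments always partition the protein. Peptides
that do not locate (e.g. host-proteome peptides when profiling β-casein)
are skipped and tallied in the `skipped` attribute rather than failing
the profile.

## Physicochemical descriptors

Per peptide: length; proline fraction (count of P over length); GRAVY as
the mean Kyte–Doolittle hydropathy; net charge at a configurable pH
(default 7.0) via Henderson–Hasselbalch over both termini and the
K/R/H/D/E/C/Y side chains with the EMBOSS pKa set (shipped as a data
file); aliphatic index `100 (f_A + 2.9 f_V + 3.9 (f_I + f_L))`; and
aromatic fraction (F, W, Y over length). The descriptor set follows the
standard output of sequence-property tools used in peptidomics; length
and proline fraction are the two that drive the genotype comparisons.

## Bioactive-peptide database

Source entries (emulating BIOPEP-, MBPDB- and EROP-Moscow-style records)
carry four boolean evidence flags, which make the manual curation rules
executable: an entry is excluded iff (i) it has no literature reference,
(ii) its activity is hypothetical/predicted only, (iii) a sequence
discrepancy exists between database and literature, or (iv) only a bitter
taste is recorded. Populating the flags (i.e. reading the literature) is
outside the package's scope. Merging by sequence unions activities,
references and sources; flags combine so that a flag holds only if it
holds after considering all evidence — one source with a reference makes
`has_reference` true, one experimentally supported source clears
`predicted_only`, while one documented discrepancy taints the merged
entry. Conflicting fragment coordinates keep the first-seen pair in the
numeric columns and preserve alternatives in `alt_fragments` with a
warning, since entries stay unique by sequence.

Activity labels form a closed vocabulary (ACE-I, DPP-IV-I, Immuno, AntiM,
AntiO, PEP-I, Opioid) with an `other:<text>` escape hatch. Intersection
counts use UpSet semantics: an activity's set size counts entries
carrying it; an intersection size counts entries whose activity set
equals *exactly* that pattern, so intersection sizes sum to the number of
entries. Matching is exact sequence equality by default (reference
reports list database hits verbatim); a substring mode (identified
peptide contains a known bioactive core) exists but is off by default.
The bundled `bioactive_sources_synthetic.tsv` is a synthetic emulation of
the three-source landscape; its peptide/activity rows for the documented
β-casein peptides transcribe published values, the remainder exist to
exercise merging and curation.

## The in-silico proteolysis generator

The generator emulates identification tables with the statistical
structure the analysis assumes; it is **not** a kinetic model of the
pathway. Stages and defaults:

1. **PrtP digestion.** The signal peptide (15 residues) is removed; each
   backbone bond of the mature chain is cleaved independently with
   probability `prtpCleaveProb` (0.08) times a per-residue weight for the
   residue N-terminal to the bond (2.5 after Q, E, L; PrtP's true
   specificity is not modeled — the weights are a synthetic stand-in).
   `molecules` (100) substrate copies are digested independently, giving
   the peptidome its depth.
2. **Opp transport.** Inclusive length window 4–18 residues.
3. **Peptidase rounds.** Per round and peptide, each of the 15 rules
   draws a Bernoulli variate (`p_act`: 0.2 for endopeptidases, 0.3
   otherwise) and the first firing, non-deleted, applicable rule acts.
   Endopeptidases cleave an internal bond sampled by C-terminal-residue
   weights (E, F, P at 4:1), leaving both children ≥ 2 residues; general
   aminopeptidases (and PepA on D/E N-termini, Pcp on N-terminal Q)
   release residue 1 but **stall when residue 2 is proline** — the
   domain reason the proline-specific enzymes exist; PepX removes the
   N-terminal X-Pro dipeptide, PepP the residue before a position-2
   proline; PepT decomposes tripeptides, PepV/PepDA/PepDB
   non-proline dipeptides and PepQ X-Pro dipeptides into free amino
   acids. Fragments shorter than two residues leave the pool (free amino
   acids are invisible to the detector). Rounds stop at a fixed point or
   after `rounds` (4) — a deliberate *finite snapshot*: cells are
   harvested during active casein utilization, and running to the true
   fixed point would leave the wild type with an empty pool.
4. **Detection and noise.** Survivors with monoisotopic mass in
   170–2000 Da become records; each peptide instance draws a log-normal
   latent intensity (meanlog 14, sdlog 1.5) shared across the 3
   replicates, each replicate multiplies log-normal noise (sdlog 0.25),
   drops the peptide with probability 0.1, and jitters the observed mass
   by Normal(0, 3 ppm) relative error.

Kinetics are per-round Bernoulli events rather than Michaelis–Menten: no
rates are available, and the analysis only needs the qualitative
genotype-to-peptidome structure. The per-round probabilities and round
count were set so that the simulated wild type is *partially* degraded at
harvest (~600 consensus peptides against the published order of ~10³)
and the two qualitative knockout signatures emerge: deleting the
endopeptidases raises the mean consensus peptide length by ~1.5 residues,
and deleting PepX/PepP/PepQ raises the mean proline fraction. During
model design we also tried making endopeptidase cleavage proline-resistant
(no cuts N-terminal to P); combined with the finite-round snapshot this
enriched the survivors of *every* genotype in proline and masked the
knockout contrast, so it was dropped.

Reproducibility: each strain's RNG stream is seeded from the master seed
plus a position-weighted character sum of the strain name (kept below
2³¹); Bernoulli draws are consumed for deleted genes too, so streams stay
aligned between genotypes for as long as their pools coincide.

### What the generator does and does not emulate

It reproduces: peptidase-class cleavage logic under knockouts, the Opp
and detection windows, replicate structure with dropout, log-normal
intensities with a shared peptide-level latent value, and ppm-scale mass
noise. It does **not** reproduce: MS/MS identification errors (every
record is a correct identification), ionization-efficiency biases,
host-proteome background peptides (all records derive from the
substrate), chromatographic effects, or the magnitude of the published
property shifts — the simulated proline-fraction contrast in particular
is directionally correct but much smaller than the published violin
plots. Passing tests on simulated data therefore validate the analysis
code and the qualitative genotype logic, not quantitative agreement with
real peptidomes.

## Numerical choices and degenerate inputs

* Printed-mass agreement: two units in the last printed decimal (see
  *Mass model*); the package's own masses are exact double sums.
* Tolerance bounds (ppm, Opp window, detection window) are inclusive.
* Clustering tie-break: labels sorted before `hclust`, Jaccard/average.
* Empty inputs are valid where they are meaningful: empty peptide lists
  give all-zero profiles, strains without matches yield a `"None"`
  report row, empty strain sets report `n = 0` with `NA` statistics.
* Rows violating record invariants are rejected with row-numbered
  warnings; only a missing mandatory column aborts parsing.
* Per-replicate ppm errors in reports are formatted to two significant
  digits with an em dash for replicates where the peptide was not
  detected.

## Problem sizes in the test suite

The suite exercises: 1,000 random peptides (length 1–30) against an
independently coded character-sum mass oracle at 1e-12 relative
tolerance; 100 random profile fixtures against a per-position
brute-force tally; randomized consensus, curation and UpSet fixtures
against nested-loop/predicate/enumeration oracles; and simulator runs at
10 substrate molecules for unit checks plus the full 100-molecule
configuration (seed 1) for the genotype-physiology checks. These sizes
keep the default run a few minutes long while leaving every property
well-sampled.

## Known limitations

* The generator's PrtP weights, per-round probabilities and intensity
  parameters are synthetic conventions, not measured quantities.
* Only exact (or optional substring) sequence matching against the
  bioactive database; no homology or I/L-ambiguous matching.
* Net charge uses a single fixed pKa set; no temperature or ionic
  strength corrections.
* One PSM per surviving peptide instance and replicate; charge states
  and spectral counts are not modeled.
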