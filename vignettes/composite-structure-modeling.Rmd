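---
title: "Methods: composite secondary-structure modelling from probing data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composite secondary-structure modelling from probing data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rnacomposer)
```

## The model

`rnacomposer` infers a single per-nucleotide paired/unpaired assignment
for a long transcript — a *composite model* — from three probing
channels plus thermodynamic prediction, then organizes the paired
positions into named helices, pseudoknot layers, and multiway
junctions.

The channels make different, partially contradictory measurements:

* **PARS** probes refolded RNA in vitro with two nucleases; the
  classification statistic is the S1:V1 mean-count ratio. The strict
  rule is: ratio above the cutoff (default 1) is single-stranded, below
  is double-stranded, *exactly at* the cutoff is undetermined. When
  V1 = 0 but S1 > 0 the ratio is computed against a pseudocount
  (default 0.5) so strong single-stranded signal is not lost to a
  division by zero.
* **DMS** probes cells in vivo, but only A and C react; counts above
  the cutoff (default 20) mean unprotected (unpaired), below mean
  protected. G/U are structurally `no_data` in this channel, and a
  "protected" call can also mean protein-bound rather than base-paired.
* **PARIS** yields duplex groups: two coordinate spans plus read counts
  per replicate dataset. Acceptance is deliberately strict and literal:
  reads `> 3` (i.e. at least 4) in at least 2 of 3 datasets, or reads
  `> 5` in any one dataset. Boundary cases `{3,3,3}` and `{5,0,0}` are
  rejected; `{4,4,0}` and `{8,0,0}` are accepted.

### Evidence precedence

Per nucleotide, `resolve_nucleotide()` applies:

1. membership in a registered pair of an accepted PARIS duplex forces
   `paired` (provenance `paris`);
2. concordant PARS+DMS calls give their shared state (`pars+dms`);
3. discordant determined channels adopt the MFE reference fold's state
   (`mfe_resolved`);
4. a lone unpaired-type call is honoured as is; a lone paired-type call
   (e.g. PARS `double` on a G, where DMS is silent) is honoured only
   when the MFE reference fold supplies a partner — otherwise the
   position is *designated unstructured* (`default_unstructured`);
5. no evidence at all: designated unstructured inside the probed
   region, `no_data` outside it.

Rule 4 is the one genuinely open design point. The alternative reading
(always adopt the MFE state for one-channel positions) lets the
thermodynamic model silently overrule unambiguous probing signal, and
makes perfect noise-free data unrecoverable. The implemented reading
follows the operational account of the source procedure: structured
signal without a discernible base-pairing partner ends up unstructured
in the final model. Its unit-level contract is pinned in the tests.

### The MFE reference fold is evidence-constrained

Inside the probed region the MFE structure consulted by rules 3–4 is
not an unconstrained fold: positions whose probing evidence says
*unpaired*, positions with no evidence, and PARIS-registered positions
(whose partners are already fixed) are all forbidden from pairing, and
the remainder is folded at MFE. This is the package's reading of
"nearest-neighbor rules applied together with the probing data": the
fold arbitrates among positions that could plausibly pair, rather than
competing with the evidence. Declared *uncovered* regions (e.g. a 5'
region without any probing coverage) are folded unconstrained by a
5'→3' scan — 100-nt windows, 20-nt overlap — and merged conservatively:
a pair survives only if predicted by every window that fully contains
both partners; residual conflicts go to the more 5' window.

### Partner harvesting and demotion

After resolution, pairs are harvested from the PARIS registry plus the
constrained fold; any position still `paired` without a partner is
demoted to unpaired with provenance `default_unstructured`. As a
consequence *every registered PARIS pair survives into the final
model*, which is why the PARIS-vs-composite agreement statistic is
exactly 100% on every pipeline output — an invariant, not an empirical
observation, and asserted as such in the acceptance tests.

### Pseudoknots

Helices are maximal stacked runs. Any helix crossing another is pushed
to a pseudoknot layer; among a crossing set, the helix whose removal
leaves more pairs nested (the larger one) stays nested, ties keeping
the more 5' helix. Naming follows appearance 5'→3': `H1..Hn` for nested
helices, `PK1..PKm` for crossing ones, junctions labelled by degree
(`3WJ` etc.).

## Folding backend

The environment-independent backend is a Nussinov-style dynamic program
(Rcpp): maximize pair score (G-C 3.0, A-U 2.0, G-U 1.0) plus a 1.0
stacking bonus per stacked pair, minimum hairpin loop 3 nt, N never
pairs; the reported "free energy" is the negated score in kcal/mol to
0.1. This is documented as an *approximation* of a Turner-parameter
folder, adequate for registry assignment, tiebreaks, gap re-checks and
sign-based ΔΔG comparisons, but not for quantitative thermodynamics. A
real Turner folder can be plugged in via
`options(rnacomposer.fold_backend = function(window) ...)`. The DP is
verified against an exhaustive enumeration oracle on all windows up to
14 nt — both sides share only the scoring function, not the search.
Windows are capped at 3000 nt (the DP is O(n^3) time / O(n^2) memory);
longer regions must go through the windowed scanner.

Duplex registry: PARIS spans bound a duplex but do not name pairs, so
the two spans are concatenated with a 3-nt unpairable `NNN` linker,
folded, and only cross-span pairs are kept. Spans with no canonical
complementarity yield an empty registry with a warning.

## Calibration

`calibrate()` grid-searches the two cutoffs against reference
structures with known truth, maximizing the unweighted mean of the two
channel accuracies (undetermined counts as covered-but-wrong). Ties
break toward the defaults (1, 20) and then toward smaller values — with
well-separated count distributions many DMS cutoffs tie at perfect
accuracy, and the tie-break is what makes the procedure reproducible.

## Conservation and covariation

Thresholds are absolute presence counts (43/53, 12/17, 42/51), not
percentages: the printed percentages in the source material are
descriptive and in one case (12/17 = 70.6% vs a printed ">71%")
inconsistent, so counts are authoritative. A helix is *present* in a
homolog row when ≥ 90% of its pairs are canonical after gap removal
*and* co-folding the homolog's strand segments recovers ≥ 90% of the
pairs (this MFE re-check is what lets a gapped-but-refolding helix
count). *Conserved* additionally requires pooled nucleotide identity
≥ 75% over the helix's paired columns against the reference row, gaps
counting as mismatches; identity is pooled per helix, not per column —
the per-column reading of an ambiguous phrasing would make single
variable columns veto otherwise invariant helices. A pair *covaries*
when two canonical realizations differing on both sides occur across
rows; realizations differing on one side (G-C vs G-U) are counted
separately as co-mutations. The covariation counter is checked against
a brute-force recount; statistical covariation testing (R-scape-style)
is out of scope.

## The synthetic world

`generate()` plants nested hairpins (default 15, 5–12 bp), long-range
duplexes (default 2, ≥ 100 intervening nt, nested end-joining
geometry), and H-type pseudoknots (default 1, arm in a host hairpin
loop pairing downstream of the stem) along a 1000-nt transcript, makes
planted pairs exactly Watson-Crick, and draws:

* counts from Poisson models straddling the cutoffs with ~5-fold
  separation — S1 10/2, V1 2/10 (unpaired/paired), DMS 60/5 on A/C —
  so default cutoffs (1, 20) are the generative optimum and
  calibration is recoverable;
* PARIS reads per true duplex per dataset from Poisson(8) across 3
  datasets (background: ~1 weak false duplex per dataset), so the
  acceptance criteria almost surely fire on true duplexes;
* homolog rows (53 including the reference) with per-position
  substitution rate 0.15, compensatory with probability 1.0 inside
  helices (a canonical pair type replaces the reference type), and
  non-conserved helices deleted in all but 5 homologs.

Unstated-by-anyone defaults chosen here, once: full track coverage
(`coverage_fraction = 1`; the probed region of a real transcript is
treated as covered in the source bookkeeping, and partial coverage is a
test-exercised parameter, not the default world); `p_cov = 1`;
`conserved_fraction = 0.75`.

What a green test establishes: that the pipeline's rules are
implemented as stated and recover a world that *obeys its assumptions*
(independent Poisson counts, exactly complementary planted duplexes,
alignment columns in 1:1 correspondence with reference positions). What
it does not establish: performance on real data with correlated
coverage, protein-occluded DMS protection, indel-rich alignments, or
PARIS spans that misalign with the true duplex registry. The headline
statistics of a real transcript (e.g. agreement percentages in the
50–60% range) are properties of real noise regimes and are not
reproduced by this generator, by design.

## Numerical choices

* Coordinates are 1-based inclusive everywhere; 0-based half-open
  appears only inside BED/bedGraph writers.
* Classification equality at a cutoff → undetermined (strict
  inequalities only).
* ΔG reported to 0.1 kcal/mol; ΔΔG > 0 means destabilizing.
* Duplex clustering slack 5 nt; merged cluster span = union of member
  spans, per-dataset reads summed before threshold evaluation.
* Dot-bracket tiers: `()` then `[]`, `{}`, `<>`, `Aa`..`Zz`; writer
  assigns each crossing helix the lowest tier free of conflicts,
  scanning 5'→3', so serialization is deterministic and round-trips.
* Degenerate inputs: empty duplex list is rejected-not-error in
  acceptance; empty track assembles a PARIS-only model; infeasible
  synthetic packing errors out.

## Known limitations

* Backend B energies are not thermodynamic free energies; mutation
  impact is meaningful in sign and relative magnitude only.
* `assemble()` resolves per nucleotide; the alternative region-level
  reading of "nucleotide or region" is not implemented (run-harvesting
  plus demotion approximates it).
* Non-canonical pairs are representable (a flag on `helix`) but never
  produced by the built-in backend and excluded from energy accounting.
* The triple helix of a real 3' stability element is representable only
  as an annotated hairpin region; base triples are out of scope.
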