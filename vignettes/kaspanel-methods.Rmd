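---
title: "Methods: building and validating a deep-sowing KASP panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and validating a deep-sowing KASP panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kaspanel)
```

## The problem

Deep sowing (10 cm) protects direct-seeded rice from predation and
surface drying, but emergence then depends on germination vigour and
mesocotyl elongation. Marker-assisted introgression of the QTL windows
governing these traits needs allele-specific (KASP) assays whose
behaviour is quantified: in which recipient backgrounds each assay can
distinguish the donor allele (*utility*), how often it mis-scores a
recipient line as carrying the donor allele (*false positive rate*, FPR),
how often it misses a true carrier (*false negative rate*, FNR), and
whether its allele classes actually differ in phenotype. `kaspanel`
implements that screen–design–call–QC–select pipeline, together with a
synthetic-population generator that provides the pedigree truth against
which the error rates are defined.

## Candidate screening

Parental variant tables are merged by site (union of positions; samples
absent at a site are missing), filtered, and windowed:

* **MAF filter** — minor allele frequency across all parents, counting
  diploid alleles over called samples, must *strictly exceed* 0.02. The
  strict inequality follows the wording of the filter the panel was built
  with; a site at exactly 2% is removed.
* **Call-rate filter** — at least 80% of samples must be called at the
  site. We read "retaining at least 80% of the data" as a per-site rate
  across samples (the filtering acts on variants, not on samples, at this
  stage of the pipeline); the per-sample reading is not implemented.
* **Windows** — 1-based inclusive bounds; Mb bounds convert as Mb × 10⁶.
  Registry windows must not overlap within a chromosome.

Donor specificity is decided on homozygous differences only: the donor
must be homozygous, and a recipient joins the utility set only when it is
homozygous for the other allele. A heterozygous or missing parental call
excludes that recipient, and a heterozygous donor skips the site. These
are inbred parents, so a het call is treated as evidence of an unreliable
site rather than genuine heterozygosity. Whether the original screen
required homozygous recipient calls or merely non-donor calls is not
documented; the conservative homozygous-difference rule is the default
and the behaviour is localized in `find_donor_specific()` if a user needs
the looser rule.

## Assay design

KASP assays consist of two allele-specific forward primers — identical
except for the 3′-terminal base (the SNP) and the 5′ fluorophore tail —
plus one common reverse primer. `design_primers()` constructs them from a
bracketed flank string (`LEFT[REF/ALT]RIGHT`, 100 bp flanks by default):

* allele primer core: suffix of the left flank ending on the allele base;
  length 18–36 nt, chosen to put both alleles' Tm inside 57–63 °C and as
  close to 60 °C as possible (ties: shorter primer). The upper length
  bound of 36 nt is deliberately generous because AT-rich rice flanks at
  ~44% GC often cannot reach 57 °C by 28 nt.
* common primer: reverse-complement of a right-flank window, subject to
  the same Tm window and an amplicon of 50–120 bp; ties broken by
  |Tm − 60|, then shorter length, then leftmost position, which makes the
  design fully deterministic.
* Tm: nearest-neighbour thermodynamics with the unified stacked-pair
  parameter set, duplex initiation terms, the entropic monovalent-salt
  correction 0.368 (N−1) ln[Na⁺], 200 nM oligo and 50 mM Na⁺ by default;
  the Wallace 2(A+T)+4(G+C) rule is available for quick checks. Tails are
  excluded from all Tm computations.
* specificity: instead of a heuristic aligner, the 3′-anchored 16-nt core
  of each allele primer is searched exactly against both strands of the
  reference. More than one hit rejects the assay (`rejected_multilocus`);
  this preserves the multi-locus rejection semantics while remaining
  exactly reproducible. Cores shorter than 12 nt are refused because
  random 11-mers are expected about 100 times per 100 Mb.

Failure to satisfy the constraints yields `rejected_design` rather than a
forced design; on this package's synthetic genomes roughly a quarter of
planted candidates reject this way, mostly for AT-rich left flanks.

## Genotype calling

Endpoint fluorescence is mapped to the angle θ = atan2(y, x), making
calls invariant to common gain. Three clusters seeded at 0°, 45°, 90°
(recipient hom / het / donor hom; channel x is the recipient fluorophore
by convention) are refined by a deterministic 1-D Lloyd iteration (25
iterations or convergence; empty clusters keep their seed). Calls within
`guard_deg` (default 10°) of a cluster boundary, or below `min_intensity`
(default 0.2 on the unit-intensity scale), become no-calls. If a cluster
ends empty, het calls are demoted to missing with a warning — a plate
with two clusters cannot distinguish het from drift. The renderer
(`render_fluorescence()`) inverts this model with angular noise of
`noise`·45° and relative radial noise `noise`, so zero noise round-trips
exactly and the calling accuracy can be measured against truth at any
noise level.

## Marker QC

All Table-style statistics treat the *negative* class as
recipient-homozygous calls and the *positive* class as donor-homozygous
calls; heterozygotes and missing calls are counted in `n_tested` but
belong to neither class, which is why the two printed frequencies never
sum to 100%. Frequencies are percentages of `n_tested` to one decimal;
an empty class yields `NA` means with a flag, never zero.

FPR and FNR need a truth channel. In simulation the pedigree truth is
used; with real data a reference-assay genotype matrix can stand in as
truth (`true_class` column). Missing calls count as discordant in both
numerators by default (strict), with a toggle.

The allelic-effect test is Kruskal–Wallis on the two homozygote classes
(equivalent to a rank-sum test; heterozygotes can be included as a third
group), with tie-corrected H and the χ² approximation on k−1 degrees of
freedom, and the printed significance tiers (\* < 5%, \*\* < 1%,
\*\*\* < 0.1%). The test suite checks H against the hand formula and the
χ² p against the exact permutation distribution; at group sizes ≤ 10 the
two p values can differ by up to about 0.1, so that is the agreement
asserted — the χ² approximation is simply not 2-decimal accurate at such
sizes. Single-marker analysis is least-squares regression on the 0/1/2
dosage coding (R², F-test p), and `anova_crd()` fits the one-way
completely-randomized-design model Y = μ + α + e on replicate-level
observations with CV% = 100·√MSE/mean; a zero-MSE fit is flagged rather
than reported as an infinite F.

## Panel selection

Selection criteria (max FPR, max FNR, min utility, minimum significance
tier, optional per-region quotas) are configuration, and the audit trail
records each marker's pass/fail per criterion. The thresholds behind the
published 12-assay panel were never printed, so that panel ships as a
pinned id list (`core_panel_ids()`) used for downstream summaries — we do
not pretend a threshold rule reproduces it. Marker spacing is the mean of
*adjacent* sorted positions within a window ("distance between two
markers" read as consecutive markers; the all-pairs alternative is a
one-line change), and kb→cM uses the fixed 244 kb/cM conversion. One
printed conversion (228.86 kb → 0.978 cM) is inconsistent with that
constant (it recomputes to ≈ 0.938) and is flagged by
`check_cm_conversions()` rather than reproduced.

## The packaged 54-marker fixture

`load_table3()` returns a checksum-verified transcription of the
published QC table. Three rows are internally inconsistent as printed
(two `n_tested` values that contradict their own percentages, one
count/percentage mismatch) and carry notes in the `provenance` column;
recomputation tests exclude exactly those flagged fields. The two
population classes are labelled `a` and `b` because the printed class
labels conflict with the prose ranges of the error rates; the `a` columns
carry the backcross-sized totals. Three chromosome-7 markers sit 0.05–0.16
Mb below the printed lower bound of *qSD7.1*; the registry keeps the
printed bounds, per-chromosome counts come from the chromosome column
(matching how the published per-chromosome totals are quoted), and
`assign_regions()` reports those three as unassigned.

## What the synthetic generator emulates — and what it does not

The generator reproduces the *structure* of the study material:

* 5 donors and 6 recipients; seven F₃:F₄ families totalling 256 progeny
  and eight BC₃F₂:₃ families totalling 713, each cross with its donor,
  recipient and foreground-selection target window;
* genotypes recorded at the study's generations: F₃:F₄ progeny carry the
  genotype after three selfing meioses from the F₁ (heterozygosity
  (1/2)³ = 1/8), BC₃F₂:₃ progeny the genotype of the BC₃F₂ plant — three
  backcrosses with certain foreground selection keeping the target window
  heterozygous, then one self, so donor-allele carriers sit at 3/4 at
  target windows. Single-seed descent is assumed (the founding scheme of
  the real families is not documented); both closed forms are verified by
  simulation at n = 10,000;
* germination as 3 replicate trays × 6 Bernoulli seeds per depth (the
  printed extremes 8.33% and 91.67% imply a 12-trial grid in places, so
  the replicate count is configurable to 2), with per-seed emergence
  probability logistic(baseline + Σ effects·dosage/2); mesocotyl, root
  and total lengths Gaussian around additive class means, truncated at 0;
* assay error injected per call: recipient-hom truths flip to het with
  the false-positive rate, carriers flip to recipient-hom with the
  false-negative rate, and calls drop with the missing rate;
* a miniature genome — the real windows scaled 1:100 onto ~0.2–0.4 Mb
  chromosomes at 44% GC — carrying planted donor-specific candidates in
  every window (six per window; utility sets cycle through sizes 5, 4, 3,
  2, 1 so utility varies by design) plus background variation with a
  donor-versus-elite group structure.

Two structural choices deserve emphasis. First, markers within one QTL
window cosegregate as a unit while distinct windows segregate
independently. Fully unlinked loci would break the central premise of the
QC design — that a marker's allele classes reflect its window's QTL — so
complete within-window linkage is the default; across-window closed forms
are unaffected. Second, each donor contributes one major-effect window
(germination +2.1 logits and mesocotyl +3.7 cm at 10 cm for the donor
homozygote; the other windows carry markers but no phenotypic effect),
and each marker's QC is computed on the populations whose donor owns its
window. With the recipient-class baselines (22% germination, 1.1 cm
mesocotyl at 10 cm; 44% and 1.8 cm at 4 cm) this places simulated
allele-class means inside the validation ranges reported for the real
populations — which is a *calibration*, chosen once, not an empirical
finding about rice.

The generator does **not** emulate: recombination-map realism or partial
linkage (beyond the fixed 244 kb/cM conversion used for reporting),
epistasis, genotype×environment interaction beyond the sowing-depth term,
seasonal/replication structure across years, or sequencing artefacts
(only biallelic SNPs exist). Passing tests therefore demonstrate that the
estimators recover what was planted under this model — not that real
trays, gels and plates behave this cleanly.

## Numerical and reproducibility choices

* All randomness flows from one master seed through named substreams
  (`reference`, `parents`, `cross/<population>`, `phenotype`,
  `assay_error`, ...), hashed to 32-bit seeds with a multiplicative
  string hash; adding a consumer never shifts another's draws, and
  identical configurations are byte-identical.
* UPGMA merges the closest pair (strictly smaller by 10⁻¹⁵), seeds
  leaf order lexicographically, and updates distances by size-weighted
  means; heights are distance/2, so trees are ultrametric to < 10⁻⁹,
  verified against an independent all-pairs re-averaging oracle and
  average-linkage `hclust`.
* PCA imputes missing dosages to the site mean, drops zero-variance
  sites, and centres columns before `prcomp`.
* Degenerate inputs are explicit: empty variant tables warn; an empty
  allele class gives `NA` means with a flag; constant phenotypes give
  H = 0, p = 1; one-replicate genotypes are dropped from the CRD ANOVA
  with a warning; a plate without three clusters demotes het calls.
* Simulation sizes in the tests: closed-form recovery runs at n = 10,000
  progeny; the phenotype-calibration and pipeline checks run at the
  study's own population sizes (256 + 713) or a quarter of them, which
  keeps the whole suite in a few minutes on one core.

## Limitations

* The fluorescence caller is a stand-in validated only against the
  package's own synthetic plates; the instrument software behind the real
  cluster plots is not documented.
* No multiple-testing correction is applied across markers (none was in
  the source analysis); a user screening thousands of candidates should
  add one.
* Primer design omits dimer/hairpin thermodynamics and genome-wide e-PCR
  of the primer *pair*; only the allele-primer core is checked for
  multi-locus identity.
* The SIFT-style deleteriousness layer is out of scope: coding variants
  are classified synonymous/missense/other, and external scores can be
  carried in a pass-through column.
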