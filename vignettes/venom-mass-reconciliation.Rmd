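---
title: "Reconciling venom peptide masses, identifications and bioassays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconciling venom peptide masses, identifications and bioassays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(venomics)
```

## The problem

A venom proteome is typically characterised by combining three streams of
evidence: a venom-gland transcriptome that supplies full-length precursor
sequences, shotgun (trypsinised) LC-MS/MS that identifies which precursors
are actually secreted, and intact-mass measurements of untreated venom that
reveal the *mature* processed forms — which rarely coincide with the naive
signal-cleaved translation. venomics implements the computational layer of
that workflow for disulfide-rich peptide venoms such as those of assassin
flies: modification-aware mass prediction, mature-form reconciliation,
cysteine counting by differential alkylation, identification filtering,
rational nomenclature, and the accompanying bioassay statistics.

## Mass arithmetic

A peptide's neutral monoisotopic mass is the sum of its residue masses plus
one water. The package applies four mass deltas on top of that:

| state | delta (Da) | chemistry |
|---|---|---|
| disulfide bond | $-2 \times 1.00783$ per bond | loss of 2 H on oxidation |
| pyroglutamate | $-17.02655$ | N-terminal Gln cyclises, losing NH$_3$ |
| hydroxyethyl-Cys | $+44.02621$ per Cys | iodoethanol caps a free thiol (+C$_2$H$_4$O) |
| reduction | $+1.00783$ per Cys | a half-cystine regains its H |

Residue masses are the standard monoisotopic values to five decimals, kept
in one place (`residue_mass_table()`, with a JSON override hook in
`mass_constants()`) so alternate conventions can be injected. Native venom
peptides are assumed fully oxidised — `floor(n_cys/2)` disulfide bonds —
which matches the uniform reduction/alkylation shifts observed for
disulfide-rich folds (ICK, CS-α/β defensin, Kazal). `ra_mass()` computes
the reduced/alkylated species directly as the free-thiol mass plus one
hydroxyethyl adduct per cysteine, rather than as "native plus
$n \times 45.034$"; the two agree for even cysteine counts, and the direct
form also remains exact for an odd count, where the unpaired cysteine is
alkylated without gaining a reduction hydrogen. Only pyroGlu from Gln is
implemented; the Glu variant ($-18.011$) does not occur in the data this
package targets.

The per-cysteine reduction/alkylation shift is therefore
$1.00783 + 44.02621 = 45.034$ Da. `shift_to_ncys()` inverts an observed
native-to-RA mass difference to a cysteine count over an allowed set
(default $\{0, 4, 6, 8\}$ — the counts seen in asilid venom peptides,
including the 8-cysteine family), choosing the count with the smallest
residual and breaking ties toward fewer cysteines.

## Mature-form enumeration and peak matching

Precursors are annotated with a 0-based `signal_end` (the first mature
residue; signal-peptide prediction is upstream of this package) and
optional domain intervals for multidomain Kazal-type precursors.
`enumerate_candidates()` generates the signal-cleaved form, N-terminal
truncations up to `max_n_trim = 4` and C-terminal truncations up to
`max_c_trim = 2` (the defaults cover, with margin, the two-residue
N-terminal heterogeneity that co-occurring subtypes show), each annotated
domain as an excised single-domain peptide, and a pyroGlu variant for any
candidate starting with Q.

`match_candidates()` assigns observed deconvoluted peaks to candidates
greedily by descending peak intensity — mirroring how abundance ranks are
read in practice — preferring the smallest mass error, then fewer
modifications, then the longer candidate. The result is a partial
injection (no peak or candidate used twice) and is invariant to input
order; tests compare it against a brute-force optimal assignment on small
instances. The default intact-mass tolerance is 0.15 Da: published
predicted/measured gaps for intact masses reach ~0.13 Da, whereas the much
tighter 50 mDa tolerance belongs to fragment-level database search, which
is out of scope here. Peaks carry a `condition` and are compared against
the candidate's native or reduced/alkylated prediction accordingly.

## Cysteine counting from two-condition mass lists

`count_cysteines()` reproduces the differential-alkylation procedure: take
the 50 most abundant masses between 1 and 10 kDa in each condition
(`select_top_peaks()`, ties broken toward lower mass), then walk the native
peaks by intensity rank and find, for each, the RA peak whose shift maps to
an allowed cysteine count within tolerance (`pair_conditions()`). Each RA
peak can satisfy only one native peak, since one molecular species yields
one shifted product. A zero count is reported only when essentially the
same mass appears in both top lists. By default the shifted partner must
itself lie in the RA top-50 (`ra_from_top = TRUE`); searching the full RA
list is available, since either reading of the procedure is defensible.

## Identification filtering

`accept_identification()` applies a signal-peptide-conditional threshold:
a protein needs three distinct tryptic fragments with confidence strictly
above 95%, or two if a secretion signal peptide was predicted for it.
"Distinct fragments" means distinct peptide sequences, not spectra —
standard venomics practice — so repeated PSMs of one peptide count once,
and the decision is monotone in evidence and invariant to PSM order and
duplication. Fragments shared between homologous precursors count for
every protein whose PSM table lists them; parsimony-based protein grouping
is deliberately out of scope. The bundled `tryptic_digest()` (cleave after
K/R except before P, with missed-cleavage windows) exists to support
synthetic PSM generation and fragment accounting.

## Nomenclature

Names follow the rational convention
*prefix*-*Family*~*n*~-*AcronymOrdinalLetter*, e.g. `U-Asilidin_12_-Dg3a`.
Subtypes are precursors whose **full precursor sequences** exceed 90%
identity; identity is computed by global alignment maximising identical
positions (match 1, mismatch 0, with a vanishing gap-extension penalty so
that among maximum-match alignments the one with fewest gap columns wins),
divided by alignment length including gap columns. The denominator choice
is documented here because conventions differ; it is the most conservative
of the common options. Clustering is single linkage at the strict >90%
threshold — the simplest rule consistent with observed a/b subtype pairs —
so chained similarity (A~B, B~C, but not A~C) still yields one cluster.
Clusters are numbered in discovery order of their first member, across all
families of one species (ordinals like Dg1…Dg51 span families); members of
multi-sequence clusters get letters a, b, c… in discovery order, and
singletons are letterless by default.

## Dose-response and abundance statistics

`fit_pd50()` fits a binomial GLM with a logit link on log10(dose) — the
standard quantal-assay model for insect toxicity; probit is available —
and reports PD50 $= 10^{-\beta_0/\beta_1}$ with a delta-method confidence
interval on the log scale. Under complete separation (every dose group
all-or-none) the likelihood has no interior maximum, so the fit is flagged
unstable and only the bracketing dose interval is reported. Dose
bookkeeping helpers convert an injected concentration to a per-fly dose
(2.1 uL injection volume), a per-fly dose to ug/g, and a harvest yield to
PD50-equivalent doses.

`composition_fractions()` turns per-entity proteomic intensity and
transcriptomic expression into per-group percentages of their grand totals
(each summing to 100). `expression_intensity_correlation()` reports
Pearson's r with the t-based p-value; it operates on raw values by default
with a `log` flag, because the transform used in published analyses of
FPKM-versus-intensity correlations is typically unstated — callers should
choose and report the scale.

## The synthetic-data generator

The generators exist so that every pipeline stage can be tested against a
planted truth without external data, and their defaults *are* the study
conditions the package targets: five families totalling 17 six-cysteine,
2 four-cysteine and 2 cysteine-free peptides (shares 30/25/20/15/10%),
0.02 Da mass noise, 29 decoy peaks per condition, 6 doses × 20 flies with
PD50 truths 1.16/3.07/15.58 ug per fly and slope 2.5, and 56-record
abundance tables at a correlation target of 0.51. Mature-length ranges
keep every planted peptide inside the 1–10 kDa comparison window; the
cysteine-free family uses the shorter linear-peptide size class for that
reason. Sequences are drawn from a uniform alphabet *excluding* cysteine,
with cysteines then placed at non-adjacent positions, giving exact
scaffold control; mature regions never start with Q so planted forms carry
no incidental pyroGlu ambiguity.

Decoy masses are drawn uniformly but re-sampled if they fall within 1 Da
of any allowed-shift relation (including zero shift) with any other peak
in either condition. This keeps planted-recovery tests well-posed — a
decoy can never form a valid native/RA pair — while still exercising the
tie-breaking and injection logic.

For the abundance table, `generate_expression()` constructs the bivariate
log-normal sample so that its *empirical* log-scale correlation equals the
target exactly (via `MASS::mvrnorm(empirical = TRUE)`). This is a
deliberate design choice: at n = 56 the sampling standard error of a
correlation around 0.5 is ≈ 0.1, so population-correlation sampling
produces tables whose sample correlation routinely misses the target by
more than that — useless as a controlled input. Population sampling
remains available (`empirical_correlation = FALSE`) and is what the
statistical recovery tests use where fluctuation is the point.

Every generator seeds its own stream at a fixed offset from the spec seed
(precursors +0, mass lists +1, PSMs +2, dose-response +3, expression +4),
so outputs are individually reproducible and independent of call order.

## What the tests do and do not show

The simulated venom has additive Gaussian mass noise, log-normal
intensities, independent decoys, and cleanly cleaved mature forms. Real
deconvoluted peak lists contain correlated artefacts (adducts, in-source
fragments, deamidation, incomplete alkylation) and real processing is
messier than trim-and-excise. Passing the planted-recovery tests therefore
demonstrates correctness of the inference logic under the stated noise
model, not robustness to every instrument artefact. Problem sizes in the
test-suite were chosen to characterise the estimators well while keeping
the default run fast: 200 simulation replicates for PD50 recovery and CI
coverage (6 doses × 20 animals each), 200 replicates for the correlation
stage, and ~100-peptide repertoires for matching and identification
recovery.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open throughout; printed mature sequences
  are reproduced by slicing.
* Masses are reported in daltons, neutral and monoisotopic; tables print
  4 decimals.
* `shift_to_ncys()` is total: it returns `NA` rather than failing when no
  allowed count fits, and ties go to the smaller count.
* Empty candidate or peak sets match to an empty table, not an error.
* An observed predicted/measured pair that is internally inconsistent
  (≈0.9 Da apart, beyond any plausible rounding) is carried in the
  reference table but flagged `exclude_from_reproduction`, and the
  reproduction machinery respects that flag.
* Complete separation in `fit_pd50()` is reported as a bracket, never as a
  point estimate with a fake standard error.
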