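---
title: "Methods: CSF circRNA profiling, screening and survival analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CSF circRNA profiling, screening and survival analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csfcirc)
```

# The analysis problem

Cerebrospinal fluid (CSF) is a privileged liquid-biopsy compartment for
brain metastases: the blood–brain barrier filters what reaches it, so its
circular RNA (circRNA) content is expected to be species-poor but
abundance-rich relative to plasma and tumor tissue, and highly variable
between patients. The workflow in this package takes per-sample chimeric
read records and gene models and produces: a cohort back-splice junction
count matrix, normalized circRNA expression, compartment comparisons, a
screened candidate list, a circRNA–miRNA–mRNA sponge network, and survival
models in which the exposure is a patient's candidate-circRNA detection
burden in CSF.

Because patient-level data of this kind is typically not shareable, the
package treats the *synthetic cohort generator* as a first-class module:
it plants a known ground truth (candidate junctions, binding sites,
co-expressed partners, hazard structure) so that every downstream stage has
an exact expected answer.

# Back-splice calling

A chimeric record stores two aligned segments. With `pos_a` the 1-based
first base after the donor segment and `pos_b` the 1-based last base before
the acceptor segment, a record is back-splice evidence iff both segments
share chromosome and strand and the acceptor lies upstream of the donor in
transcription order — the coordinate order is reversed relative to linear
splicing. On the "+" strand that is `pos_b < pos_a − 1`, yielding the
junction `[pos_b, pos_a − 1)` in 0-based half-open coordinates; on the "−"
strand the segment roles mirror (`pos_a < pos_b − 1`, junction
`[pos_a, pos_b − 1)`). Internally all coordinates are 0-based half-open
(`chrom:start|end:strand` IDs); the file dialect is 1-based, documented per
field. The generator and the caller share this convention and a brute-force
grouping oracle in the test suite guards it.

Supporting-read threshold: the default `min_reads = 1` matches the species
definition (a junction with read count > 0 is a detected species); stricter
thresholds are a flag. Annotation assigns a parental gene only when both
junction ends sit on exon boundaries of the same gene, exact by default
(`tolerance_nt = 0`) since boundary jitter is a property of foreign
pipelines, not of this one; junctions failing annotation are kept as
`"unannotated"` so that screening, not the caller, decides what to drop.
Distinct junctions of one gene are never merged.

# Quantification

Between-sample normalization is TMM (trimmed mean of M-values) computed
from the **linear** gene counts with edgeR, using the method's standard
trims (30% on M, 5% on A) and upper-quartile reference selection; factors
are rescaled to geometric mean 1. An independent re-implementation of the
doubly trimmed, inverse-variance-weighted mean serves as the test oracle.

FPKM is `count · 10^9 / (L · N · f)` with `L` the feature's effective
length, `N` the linear library size and `f` the TMM factor. For linear
genes `L` is the exon-union length. For circRNAs only read placements that
cross the back-splice joint with at least `anchor_size` nt on each side are
unambiguous evidence, so every circ shares the effective length

\[ L_\mathrm{eff} = 2\,(\text{read\_length} - \text{anchor\_size}), \]

260 nt at the default 150/20. The anchor size is not a quantity that can be
recovered from published FPKM tables, so it is a prominent, configurable
parameter; absolute circ FPKM values depend on it while all rank-based
comparisons do not. circ FPKM always borrows `N` and `f` from the same
sample's linear transcripts — circ totals never normalize themselves,
which would erase the compartment abundance signal.

# Compartment profiling

Species counts use the count > 0 rule. Shared-species counts between
samples are log2-transformed with pseudocount 1 (zero-shared pairs are
representable). Two-group comparisons use the Wilcoxon rank family: pairing
is applied only where samples actually pair (same patient), and since
compartment availability differs between patients, the cross-compartment
comparisons default to the unpaired rank-sum form; both variants are
exposed. Exact p-values are used for small tie-free samples (enumeration
oracles in the tests), normal approximation with tie correction otherwise.
Pearson correlation reports `t = r\sqrt{n-2}/\sqrt{1-r^2}` on `n − 2` df.
The therapy-line trend test is a Kendall-tau correlation against the
ordinal line index — a Jonckheere-style choice made because no specific
trend test is canonical in this setting; with tied line labels tau-b is
attenuated below 1 even for a perfect trend, which is documented behavior.

# Candidate screening

The cascade is: CSF-detected junctions → minus the normal-brain exclusion
list (exact junction-ID matching) → intersected with junctions detected in
tumor tissue of at least 2 *distinct* patients (multiple tissue samples of
one patient count once). The two filters commute (the result is an
intersection); stage counts are reported in cascade order. Per-patient
burden is the number of candidates with CSF count > 0, and the cohort is
dichotomized at the top 25% using the nearest-rank quantile — the
`ceiling((1−q)·n)`-th order statistic — because among the common empirical
quantile definitions it is the only one that always returns an attainable
integer burden; an explicit cutoff override exists for reproducing a
published split (≤ cutoff deficient, > cutoff abundant). An ambiguity worth
recording: "top 25% of expressed circRNAs" could also be read per-circRNA;
the per-patient-burden reading is implemented because the downstream
survival contrast is defined on patients.

# Sponge network

Only binding sites that span the back-splice joint are unique to the
circular isoform, so prediction runs on the junction probe: the last 30 nt
of the spliced circ joined to its first 30 nt (shorter circs contribute
their full sequence without duplication). The duplex scorer is a local
alignment of the reversed miRNA against the probe with miRanda-style
parameters — Watson–Crick +5, G:U wobble +1, mismatch −3, gap open −9, gap
extend −4, substitution scores at miRNA seed positions 2–8 multiplied by 4 —
and acceptance thresholds score > 170 and energy < −30 with a strict seed
(positions 2–8 contiguously Watson–Crick paired). The energy term is a
per-pair sum (G:C −3, A:U −2, G:U −1 kcal/mol), a deliberately simple
stand-in for a nearest-neighbor thermodynamic model; it ranks planted sites
far from random decoys, which is what the thresholding needs, and the
thermodynamic model is the natural extension point. The score threshold is
honored numerically but is not calibrated against any external tool's
scale. A single seed convention (positions 2–8) is used everywhere:
alignment weighting, the strict filter, and miRNA→mRNA matching (7mer-m8,
upgraded to 8mer with an A opposite position 1).

Co-expression edges require |PCC| ≥ 0.70 **and** p < 0.01, computed on
samples where both features are measured; the thresholds are applied to raw
p-values, matching common practice in this analysis style, with BH q-values
reported alongside to surface the multiplicity issue rather than silently
fixing it. In the workflow scripts the correlation is computed over tumor
tissue samples, where both feature classes are consistently quantified;
mixing compartments would attenuate r through the CSF species masking.
Over-representation of network target genes is a hypergeometric upper tail
against a user-supplied universe — a generic replacement for annotation-
database services, which keeps the statistics reproducible offline.

# Survival analysis

Overall survival runs from brain-metastasis diagnosis to death from any
cause or last follow-up. Kaplan–Meier uses the product-limit estimator with
censored-at-event-time individuals remaining at risk through that time;
the median is the smallest time with Ŝ ≤ 0.5 and "not reached" is an
explicit state. Median follow-up is the reverse-KM median (event indicator
flipped). Group comparison is the standard log-rank test; Cox models use
Efron tie handling (the survival framework's default) with sex, smoking and
extracranial metastasis coded as binary indicators and age continuous. The
per-candidate scan dichotomizes patients by detection (or median FPKM),
reporting log-rank and univariate Cox per candidate with BH q-values;
degenerate splits (a candidate detected in every patient) are flagged rows,
not errors. With ~20 patients some adjusted coefficients can separate
(e.g. a near-constant metastasis indicator); the fit surfaces the
underlying warning rather than masking it.

# The synthetic cohort generator

Defaults encode the targeted study conditions: 21 patients, compartments
CSF/plasma/tissue with CSF absent for patients 1 and 20 and tissue absent
for patients 4, 7, 9, 11, 18, 19 (19 CSF, 21 plasma, 15 tissue samples);
read length 150 nt, anchor 20 nt; 150 back-splice junctions over 80
multi-exon genes on a ~1 Mb three-chromosome toy genome; 12 true
candidates and a 40-entry exclusion list.

* **Counts** are negative binomial (dispersion 0.3) with lognormal per-circ
  means — the standard overdispersion model for RNA-seq, chosen because no
  distributional detail is recoverable from published summaries; only
  rank/summary contrasts are meaningful, not magnitudes.
* **CSF structure**: each patient draws an independent Bernoulli species
  mask (`csf_species_fraction = 0.4`), reproducing the species deficit and
  the inter-patient heterogeneity with one parameter; expressed CSF species
  have means boosted by `csf_abundance_factor = 5`.
* **Cascade exactness by construction**: junctions are stratified
  (brain-listed / candidate / CSF-absent / low-recurrence), with candidate
  detection forced in ≥ 3 CSF and ≥ 2 tissue patients and low-recurrence
  junctions confined to one tissue patient, so screening has a unique exact
  answer under every seed.
* **Binding sites**: each candidate's miRNA is the perfect antiparallel
  complement of a 22-nt window crossing the probe joint, so the site cannot
  exist on the linear transcript; decoys are random 22-mers.
* **Co-expression**: candidate circs and their partner mRNAs share a
  Gaussian copula with latent correlation 0.9, making the
  |PCC| ≥ 0.70 edge rule recoverable at n = 15 tissue samples.
* **Survival**: exponential OS with baseline median 17 months; the
  abundant group's hazard is multiplied by `hazard_ratio_abundant = 3`;
  censoring is independent uniform on [0, 68.2] months so the censoring
  median (what reverse KM estimates) is 34.1 months. ctDNA concentrations
  are drawn by Gaussian copula against log CSF circ abundance with target
  correlation −0.76.

What the generator does **not** emulate: read-level sequences and error
models, batch effects, isoform structure within genes, compartment-specific
library chemistry, and the composition of real normal-brain circRNA
catalogues. Tests passing on this cohort therefore demonstrate algorithmic
correctness and statistical calibration, not robustness to alignment
artifacts or annotation noise in real data.

# Numerical choices and problem sizes

Determinism: every generator stage derives its RNG stream from the config
seed plus a fixed per-stage offset, so cohorts are byte-identical under a
fixed seed while stages remain independently callable. Degenerate inputs
are explicit states, not silent numbers: zero-variance correlation inputs
error, all-zero paired differences error, single-group dichotomizations and
all-detected survival splits are flagged, parent-FPKM-zero ratios are
missing values rather than infinities, and "median not reached" is `NA`
with the printed label NR.

The test suite and the acceptance script use scaled-down cohorts chosen as
the package's own verification sizes: 8-patient cohorts (36 junctions) for
round-trips and cascade recovery (20 seeds), 200 null seeds at n = 40 for
log-rank type-I error, 100 seeds at n = 200 for Cox log-HR recovery, 50
seeds at n = 15 for the co-expression edge rule, and a 60-patient cohort
for the per-candidate prognostic scan, where per-circ power at a hazard
ratio of 3 is adequate. The full default cohort is exercised in the
`analysis/` scripts.

# Known limitations

The duplex energy model is additive per pair, not thermodynamic; the score
scale is internally consistent but not comparable to external tools. The
screening burden treats detection as binary and ignores abundance within
the candidate set. Cox models on ~20-patient cohorts are fragile to
separation, and the per-candidate scan's q-values inherit the small-n
discreteness of the log-rank test. The exclusion-list matching is exact by
junction ID; a coordinate-tolerance mode exists for lists produced by other
pipelines but inexact matching necessarily risks collapsing distinct
junctions.
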