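# csfcirc

Circular RNAs (circRNAs) arise from back-splicing — a downstream splice
donor joined to an upstream acceptor — which makes them covalently closed,
exonuclease-resistant, and therefore attractive liquid-biopsy analytes.
In lung adenocarcinoma with brain metastases, cerebrospinal fluid (CSF) sits
behind the blood–brain barrier and is expected to carry a *smaller set* of
circRNA species than plasma or tumor tissue, but at *higher abundance* and
with strong inter-patient heterogeneity. `csfcirc` is an R toolkit for that
analysis setting: it goes from chimeric read records to called back-splice
junctions, compartment profiles, a screened candidate list, a
circRNA–miRNA–mRNA sponge network, and survival models keyed to how many
candidate circRNAs a patient's CSF carries. A synthetic cohort generator
with planted ground truth makes every stage testable without patient data.

## What it computes

* **Back-splice calling.** A chimeric record (STAR-style
  `Chimeric.out.junction` layout) is back-splice evidence iff both segments
  share chromosome and strand and the acceptor lies upstream of the donor in
  transcription order. Junctions are grouped by
  (chrom, start, end, strand), thresholded on supporting reads, and
  annotated by exact exon-boundary matching against BED12 gene models.
* **Quantification.** TMM normalization factors and library sizes come from
  the *linear* gene counts (edgeR). Linear FPKM uses exon-union lengths;
  circRNA FPKM uses the junction-specific effective length

  `L_eff = 2 (read_length − anchor_size)`

  (260 nt at 150/20), with `FPKM = c · 10^9 / (L_eff · N · f_TMM)` where `N`
  and `f_TMM` are always the same sample's linear library size and factor.
* **Profiling.** Species counts (reads > 0), shared-species tables
  (log2 with pseudocount 1), Wilcoxon rank tests, Pearson correlation with
  its t-test p, and a Kendall-tau trend test across therapy lines.
* **Screening.** CSF-detected junctions minus a normal-brain exclusion
  list, intersected with junctions recurring in tumor tissue of ≥ 2 distinct
  patients; per-patient detection burden over the candidates is dichotomized
  at the nearest-rank top-25% cutoff (deficient ≤ cutoff < abundant).
* **Sponge network.** Binding prediction runs on the reverse-joined
  junction probe (30 nt from each side of the joint), so sites must span the
  back-splice joint. The duplex scorer is a miRanda-style local alignment
  (WC +5, G:U +1, mismatch −3, gaps −9/−4, seed positions 2–8 weighted ×4)
  with a per-pair energy sum; hits need score > 170, energy < −30 and a
  strict Watson–Crick seed. miRNA→mRNA edges use 7mer-m8/8mer seed matches;
  co-expression edges need |PCC| ≥ 0.70 and p < 0.01. Over-representation
  of target genes is hypergeometric with BH q-values.
* **Survival.** Kaplan–Meier curves (median = smallest t with Ŝ ≤ 0.5, "NR"
  when never reached), reverse-KM median follow-up, log-rank tests, Cox
  models with Efron ties (univariate, and adjusted for age, sex, smoking,
  extracranial metastasis), and a per-candidate log-rank/Cox scan.

## Worked example

The `analysis/` scripts run the whole workflow on the default synthetic
cohort (21 patients; 19 CSF, 21 plasma, 15 tissue samples; 150 junctions
with 12 planted candidates). `Rscript analysis/01_simulate.R` through
`06_survival.R` print, among others:

```
Species per sample (mean):
   csf plasma tissue
  42.2  149.6  104.1
Median nonzero circ FPKM by compartment:
   csf plasma tissue
 22800   4310   4210
```

— the CSF species deficit and abundance excess the generator encodes —

```
Screening cascade report
  CSF-detected circRNAs:       101
  after brain-list exclusion:  61
  after tumor recurrence:      12
  burden cutoff:              7
  groups:  abundant=3, deficient=16
Planted candidates recovered exactly: TRUE
```

— the cascade narrowing 101 CSF junctions to exactly the 12 planted
candidates, with the top-25% burden cutoff at 7 detected candidates — and

```
Cohort median OS: 17.0 months ...; median follow-up: 39.1 months
Abundant vs deficient log-rank: chisq = 10.50, p = 0.0012
```

— the abundant group's shorter survival, reflecting the generator's true
hazard ratio of 3. Step 5 builds the sponge network (12/12 planted
circRNA–miRNA duplexes recovered, all junction-spanning; 17 co-expression
edges over tumor-tissue samples).

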