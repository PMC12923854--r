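---
title: "Methods: imputation-aware HIrisPlex-S phenotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: imputation-aware HIrisPlex-S phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

The HIrisPlex-S system predicts eye, hair and skin colour from the diploid
genotypes of 41 autosomal pigmentation markers. It was designed for a
multiplex PCR assay on modern DNA, and its input is *probe-based*: per
marker, the count (0/1/2) of the allele the assay probe reports, expressed
on the strand the probe was designed on. Sequencing-based studies — ancient
DNA above all — instead produce *reference-based* genotypes in VCF, on the
reference forward strand, and at the 0.1–2× coverages typical of ancient
samples most of the 41 markers carry at best a single read (a pseudo-haploid
observation), so diploid genotypes must first be recovered by
haplotype-reference-panel imputation.

`hisplexr` implements the downstream workflow around such an imputation
engine: building the genomic target windows for imputation, translating
reference-based diploid genotypes into probe-based allele counts, evaluating
the 14 trait probabilities, classifying the three phenotypes with an
auditable rule set, and quantifying how imputation errors propagate into
phenotype calls. The imputation engine itself is external; the package only
provides a per-window command hook for it, plus a deliberately naive
panel-based imputer used as a test oracle.

## Marker catalog

The catalog (`inst/extdata/markers_hisplex_s.tsv`) is data, not code: rsid,
per-build coordinates (GRCh37/hg19 and GRCh38/hg38, differing only in the
chromosome-name dialect), forward-strand ref/alt alleles, probe strand,
probe-counted allele, variant class, global minor allele frequency and trait
tags. Eleven markers are tagged `mc1r`: the MC1R coding variants that drive
red-hair prediction. Seven of them have global MAF below 1.5%, which is why
red hair is the trait most sensitive to imputation error. One marker,
rs312262906, is a single-base duplication (dupA) rather than a SNP; it is
treated as an ordinary biallelic variant whose alt allele is the duplicated
form. rs201326893 is flagged as possibly absent from GRCh38-based joint call
sets; loading the GRCh38 catalog warns about it rather than failing, since
the marker simply imputes as missing there.

Coordinates and probe metadata were curated from the published HIrisPlex-S
assay literature. Corrections belong in the TSV; every function takes the
catalog as an argument.

## Genotype translation

For a SNP, the probe-counted allele is mapped onto the reference forward
strand — reverse-complemented when the probe sits on the reverse strand —
and the translated count is the number of the two called alleles equal to
that target. The translation is therefore independent of phase and allele
order, and for probes that count the alt allele (directly or as its
complement) it coincides with the alt dosage. Genotypes with one or both
alleles missing translate to `NA`: a half-called diploid genotype carries no
usable dosage for a model defined on 0/1/2 counts.

VCF matching is by chromosome, position and alleles; the ID column is used
only as a cross-check because IDs are unreliable in the wild. Multiallelic
records are decomposed and only the catalog alt participates in the count.
For the dupA marker both the left-aligned (`A`→`AA` at the site) and the
anchor-base (`C`→`CA` one base upstream) representations are accepted, via
allele trimming and a one-base position tolerance.

The upload CSV dialect (header spelling, `NA` token, column order) lives in
`inst/extdata/upload_dialect.yaml`. The hosted batch service's exact header
spelling is not under our control, so it is isolated as configuration.

## The 14 trait probabilities

Each trait group (eye: 3 categories; hair colour: 4; hair shade: 2; skin: 5)
is a multinomial logistic model over probe counts: for non-reference
category $k$, $\eta_k = \beta_{0k} + \sum_i \beta_{ik} d_i$ with dosages
$d_i \in \{0,1,2\}$, $\eta_{\text{ref}} = 0$, and
$p_k = e^{\eta_k} / \sum_j e^{\eta_j}$ (computed after subtracting
$\max_k \eta_k$ as the usual overflow guard). Missing markers are dropped
from the linear predictor and counted in `n_missing`; this is the simplest
defensible partial-information rule, isolated in one function because the
hosted tool's exact missing-data algebra is not published. Two hard rules
sit above the model: when all 11 MC1R counts are missing, hair is not
predicted at all (`hair_available = FALSE`); and a group whose model markers
are all missing is reported as undefined (`NA`), never silently uniform.

The published HIrisPlex-S coefficients are not redistributed. The package
ships a clearly labelled synthetic demo model (`model_demo.yaml`) whose
coefficients merely point in biologically sensible directions — derived
pigmentation alleles darken, MC1R dosage pushes towards red — so the test
suite and examples run self-contained. Users holding the published
coefficients supply them in the same YAML layout.

One vocabulary wrinkle is inherited from the system's own documentation,
which in places names the eye categories blue/brown/black and elsewhere
blue/intermediate/brown. The category labels here are configuration
(`blue`, `intermediate`, `brown` by default); the discrepancy is documented
rather than resolved.

## Phenotype classification

Eye colour is the argmax of the three eye probabilities. Hair and skin use
heuristic rules approximating the published user manual's decision tree; the
manual's exact constants are not reproduced, so all thresholds live in a
versioned rules file (`rules_default.yaml`) that a user holding the manual
can transcribe over without code changes. The shipped defaults are:

* **Hair**: red takes precedence whenever the red probability ties or wins
  the colour argmax. Otherwise the base colour (blond/brown/black, ties to
  darker) is refined by the dark-shade probability against two cut points
  (0.3 and 0.7) into the 8-way vocabulary (blonde … black).
* **Skin**: the base tone is the argmax of the five skin probabilities
  (ties to darker). An adjacent tone whose probability is at least half
  (`modifier_ratio = 0.5`) of the base tone's attaches a lighter/darker
  modifier, darker winning when both fire, giving the 12-way vocabulary.

Two properties are engineered in deliberately. Exact ties always resolve to
the darker category, matching the scheme's darker-tone precedence. And skin
modifiers are *ratio*-based rather than absolute-threshold-based: ratios of
the five probabilities are invariant under renormalisation, which makes the
classification monotone — increasing the darkest skin probability (and
renormalising) can never move the call to a strictly lighter category. The
test suite checks totality, determinism and this monotonicity over dense
probability-simplex grids.

Every call carries a `rule_trace` of the rules that fired, because error
analyses (e.g. tracing a false-red call back to two mis-imputed MC1R
markers) need to know *why* a category was assigned.

## Imputation target windows

Each marker contributes `[pos − 1 − slop, pos + slop)` (0-based half-open;
a 1-bp marker slopped by 2.5 Mb spans 5,000,001 bp, the standard
`bedtools slop` arithmetic). Overlapping or book-ended windows merge; any
merged window below 5 Mb — markers near telomeres or centromeres — is
extended away from the clipped end (or symmetrically if unclipped) until it
reaches 5 Mb, and a chromosome shorter than 5 Mb yields the whole
chromosome. Extension can create new overlaps, so merge and extend iterate
to a fixed point. On the shipped GRCh38 catalog this yields 10 disjoint
regions (~55 Mb): the slopped windows of the two chromosome-9 markers
(TYRP1 and BNC2, 4.15 Mb apart) overlap and must merge under these
semantics. Region counts from external chunking tools can differ, since
those may split long regions; the builder here is defined purely by the
slop/merge/minimum-length rules above.

## Validation metrics

*Total error* counts every imputed diploid genotype differing from truth
(including an imputed missing); *opposite error* counts only homozygous
flips (HOMREF↔HOMALT), the failure mode that most distorts the phenotype
probabilities under any inheritance model; opposite ⊆ total by
construction. Truth-missing sites are excluded from denominators.
Replicate phenotype concordance is the fraction of replicate classifications
exactly matching the truth classification, per sample, trait and coverage.
Red-hair confusion pools individual×replicate comparisons: the false
negative rate over truth-red comparisons and the false positive rate over
truth-non-red comparisons. Systematic error is flagged per (sample, marker)
combination when the mean error across the *high* coverage levels reaches
15%: error that persists when genotype information is plentiful points at
reference panel bias rather than at missing data, and the attribution
statistic reports what fraction of all errors the flagged set carries.
Imputation variability is one minus the modal genotype frequency across
replicates.

## The synthetic generator, and what it does not emulate

The test harness needs inputs with known answers and no downloads. Panels
are built by Li-Stephens-style mosaic copying from 8 founder haplotypes
with a per-site switch probability (default 0.02), which produces the one
property the workflow actually exploits — linkage between neighbouring
sites — without pretending to model recombination maps or demography.
Marker sites take their alt frequency from the catalog's global MAF, so
rare MC1R variants are rare in the panel too. Individuals are haplotype
pairs from the panel; read observations are Poisson(coverage) per site with
uniform allele sampling, the marker-level equivalent of BAM subsampling (at
coverage c the covered-site fraction is 1 − e^(−c): ~9.5% at 0.1×, ~39% at
0.5× — "half the markers" only under a generous reading). Post-mortem
damage is modelled as a per-read C→T/G→A flip applied only when the damaged
base coincides with the site's other allele — a simplification of
fragment-end damage curves that suffices to exercise the error-metric and
robustness paths. Fragment length, contamination and UDG treatment are not
modelled.

The naive imputer scores every panel haplotype pair by a read-level
genotype likelihood (per-read error rate 0.01), lets the k best pairs vote
per site (ties → heterozygous), and falls back to Hardy–Weinberg argmax
genotypes for an individual with no reads. Its keystone correctness
property is exact recovery: with full observations and the truth pair in
the panel, k = 1 reproduces the truth at every site. Its replicate seed
only breaks exact score ties (a 1e-9 jitter), so it is deterministic given
a seed. It exists to give the validation machinery a workload whose error
falls with coverage; nothing about its accuracy transfers to real imputation
engines, and passing tests say nothing about real aDNA beyond the metric
algebra being right.

## Numerical and design choices

* Softmax is computed after subtracting the maximum linear predictor.
* The p-value oracle tolerance is 1e-12; group probabilities must sum to 1
  within 1e-9.
* Interval work is 1-based internally (marker positions, VCF) and 0-based
  half-open at the BED boundary, with the conversion in exactly one place.
* Degenerate inputs fail loudly and early: wrong marker counts, duplicated
  rsids, non-finite coefficients, rule sets with inconsistent category
  orders, and configs referencing missing files are all load-time errors.
* Problem sizes in the test suite were chosen to keep the full run at a
  few minutes on one CPU while leaving the statistical checks
  well-powered: panels of 60–100 haplotypes over 400–10,000 sites, 20
  individuals for exact recovery, 20 seeds for the coverage-monotonicity
  sign test, 0.01–0.1-step simplex grids for the classifier sweeps.

## Known limitations

* The default hair/skin thresholds are an explicit approximation pending
  transcription of the manual's decision tree; they are configuration, not
  claims.
* The demo model is synthetic; no phenotype prediction from it has forensic
  meaning.
* The catalog's coordinates are curated data and should be re-verified
  against a current dbSNP build before production use.
* The external-command hook runs one command per window and expects VCF
  output; engines with binary reference formats need their own preparation
  step, which is out of scope here.
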