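# hisplexr

Imputation-aware eye, hair and skin colour prediction from diploid
genotypes with the 41-marker HIrisPlex-S system — built for the
low-coverage regime of ancient DNA and degraded forensic samples, where
most markers carry at best a single sequencing read and diploid genotypes
must first be recovered by haplotype-panel imputation.

The HIrisPlex-S system takes *probe-based* allele counts: per marker, the
0/1/2 dosage of the allele its assay probe reports, written on the strand
the probe was designed on. Sequencing pipelines instead produce
*reference-based* VCF genotypes on the reference forward strand. `hisplexr`
covers everything downstream of an (external) imputation engine:

* **Translation** — strand-aware conversion of VCF genotypes into probe
  allele counts (`vcf_to_rows()`, `write_upload_csv()`), including the
  dupA red-hair insertion and multiallelic decomposition.
* **Trait probabilities** — the 14 p-values (3 eye, 4 hair colour, 2 hair
  shade, 5 skin) from a multinomial logistic model
  `p_k = exp(η_k)/Σ_j exp(η_j)` with `η_k = β_0k + Σ_i β_ik d_i` over the
  probe dosages `d_i`, coefficients supplied as configuration
  (`compute_pvalues()`). When all 11 MC1R markers are missing, hair is not
  predicted at all.
* **Classification** — eye (3), hair (8) and skin (12) categories from the
  p-values via a data-driven rule set with darker-tone precedence and a
  full audit trail of fired rules (`classify_all()`).
* **Imputation windows** — per-marker 2.5 Mb slop, merge, extension to a
  5 Mb minimum, emitted as BED (`build_windows()`).
* **Validation metrics** — total vs opposite genotype error, replicate
  phenotype concordance, red-hair false positive/negative rates,
  reference-bias flagging (≥15% mean error at high coverage), imputation
  variability (`compare_genotypes()` and friends).
* **Synthetic harness** — an LD-bearing haplotype panel, diploid
  individuals, Poisson pseudo-haploid reads with optional post-mortem
  damage, and a naive panel-based imputer used as a test oracle
  (`simulate_panel()`, `naive_impute()`).

The published HIrisPlex-S model coefficients and manual thresholds are not
redistributed; the package ships a clearly labelled synthetic demo model
and an approximate default rule set, both replaceable files. See the
methods vignette (`vignettes/hisplexr-methods.Rmd`) for the science and
every design decision.

## Worked example

Simulate three individuals from a synthetic haplotype panel carrying the
41 markers, write their genotypes as a VCF, and run the whole pipeline
(translate → p-values → classify) with the demo model:

```r
library(hisplexr)

catalog <- load_catalog(build = "GRCh38")
sites   <- hisplexr:::harness_sites(catalog, filler_per_marker = 4L)
panel   <- simulate_panel(n_hap = 40, sites = sites, seed = 7)
ind     <- sample_individuals(panel, 3, seed = 8)
write_truth_vcf(ind, "truth.vcf")

cfg   <- load_workflow_config(overrides = list(out_dir = "demo_out", seed = 7L))
paths <- run_pipeline(cfg, "truth.vcf")

read.csv(paths$pvalues)[, c("p_eye_blue", "p_eye_brown", "p_hair_red",
                            "p_shade_dark", "p_skin_pale", "p_skin_dark")]
#>   p_eye_blue p_eye_brown p_hair_red p_shade_dark p_skin_pale p_skin_dark
#> 1      0.158       0.581      0.783        0.622       0.062       0.306
#> 2      0.006       0.962      0.697        0.870       0.010       0.204
#> 3      0.001       0.984      0.011        0.948       0.008       0.147
```

Each row is one sample's trait probabilities under the demo model (each
trait group sums to 1 across its categories). The classifier turns them
into categories, recording why:

```
sampleid  eye    hair   skin        rule_trace
ind001    brown  red    dark-black  eye:argmax=brown;hair:red;skin:base=dark_black
ind002    brown  red    dark-black  eye:argmax=brown;hair:red;skin:base=dark_black
ind003    brown  black  dark-black  eye:argmax=brown;hair:base=black;hair:shade=dark;skin:base=dark_black
```

`hair:red` means the red-precedence rule fired (these two synthetic
individuals carry high MC1R dosages under the demo model); `ind003` instead
went through the base-colour + shade refinement. Remember: the demo model
is synthetic — these calls demonstrate the machinery, not real phenotypes.

A thin CLI wrapping the same functions ships in `inst/cli/hisplexr`
(subcommands `translate`, `pvalues`, `classify`, `windows`, `simulate`,
`evaluate`, `run`).

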