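# End-to-end synthetic validation harness: panel -> individuals ->
# downsample -> naive imputation -> translation -> p-values -> phenotype
# classification -> concordance metrics. Mirrors the replicate design of a
# downsampling validation study (several coverages, several downsampling
# replicates, several imputation replicates) at desk scale.

#' Construct a replicate validation design
#'
#' @param coverages numeric mean coverages to simulate (default the
#'   five-level ladder `10, 2, 1, 0.5, 0.1`).
#' @param n_downsample_reps independent downsampling replicates per
#'   coverage (default 10).
#' @param n_imputation_reps imputation replicates per downsampled data set
#'   (default 10).
#' @param base_seed integer from which all replicate seeds derive.
#' @return A `replicate_design` list with a unique seed per
#'   (coverage, downsample, imputation) cell.
#' @export
replicate_design <- function(coverages = c(10, 2, 1, 0.5, 0.1),
                             n_downsample_reps = 10L,
                             n_imputation_reps = 10L,
                             base_seed = 1L) {
  if (n_downsample_reps < 1L || n_imputation_reps < 1L) {
    stop("replicate counts must be >= 1", call. = FALSE)
  }
  if (anyDuplicated(coverages)) stop("coverages must be unique", call. = FALSE)
  cells <- expand.grid(imp = seq_len(n_imputation_reps),
                       ds = seq_len(n_downsample_reps),
                       cov = seq_along(coverages))
  seeds <- (as.integer(base_seed) +
              13L * cells$cov + 131L * cells$ds + 1009L * cells$imp) %% .Machine$integer.max
  if (anyDuplicated(seeds)) seeds <- seq_along(seeds) + as.integer(base_seed)
  structure(list(coverages = coverages,
                 n_downsample_reps = as.integer(n_downsample_reps),
                 n_imputation_reps = as.integer(n_imputation_reps),
                 cells = cbind(cells, seed = seeds)),
            class = "replicate_design")
}

# panel sites: the 41 catalog markers (alt frequency = global MAF) plus
# `filler_per_marker` linked filler sites within +/- 50 kb of each marker
harness_sites <- function(catalog, filler_per_marker = 10L) {
  marker_sites <- data.frame(chrom = catalog$chrom, pos = catalog$pos,
                             ref = substr(catalog$ref, 1L, 1L),
                             alt = ifelse(catalog$variant_class == "SNP",
                                          catalog$alt, "T"),
                             id = catalog$rsid,
                             freq = catalog$global_maf,
                             stringsAsFactors = FALSE)
  # the dupA insertion is carried as a biallelic site; for simulation
  # purposes only its 0/1 dosage matters, not the allele spelling
  marker_sites$alt[marker_sites$id == "rs312262906"] <- "AA"
  marker_sites$ref[marker_sites$id == "rs312262906"] <- "A"
  fillers <- do.call(rbind, lapply(seq_len(nrow(catalog)), function(m) {
    offs <- setdiff(seq(-filler_per_marker / 2, filler_per_marker / 2), 0)
    offs <- offs[seq_len(min(filler_per_marker, length(offs)))]
    data.frame(chrom = catalog$chrom[m],
               pos = catalog$pos[m] + as.integer(offs * 7919L),
               ref = "A", alt = "G",
               id = paste0(catalog$rsid[m], "_flank", seq_along(offs)),
               freq = NA_real_, stringsAsFactors = FALSE)
  }))
  sites <- rbind(marker_sites, fillers)
  sites[!duplicated(paste(sites$chrom, sites$pos)), , drop = FALSE]
}

#' Run the synthetic end-to-end validation study
#'
#' Simulates a haplotype panel carrying the 41 markers (alt frequencies set
#' to the catalog's global MAFs) plus linked filler sites, draws diploid
#' truth individuals, then for every design cell downsamples to
#' pseudo-haploid reads, imputes with [naive_impute()], translates both
#' truth and imputed genotypes to probe counts, computes p-values with the
#' demo model, classifies phenotypes, and accumulates the genotype and
#' phenotype concordance metrics.
#'
#' @param design a [replicate_design()].
#' @param n_ind number of truth individuals.
#' @param n_hap panel haplotypes.
#' @param filler_per_marker linked filler sites per marker.
#' @param pmd_rate per-read damage probability applied at downsampling.
#' @param k neighbour pairs voting in the naive imputer.
#' @param seed master seed for panel and individuals.
#' @param catalog,model,rules workflow configuration objects.
#' @return List: `genotype_errors` (per-coverage error summary),
#'   `per_marker_errors` (per sample/marker/coverage error fractions and
#'   counts), `truth_phenotypes`, `replicate_phenotypes` (with `coverage`
#'   and replicate columns), `truth`, `panel`.
#' @export
simulate_validation_study <- function(design = replicate_design(),
                                      n_ind = 10L, n_hap = 100L,
                                      filler_per_marker = 10L,
                                      pmd_rate = 0, k = 5L, seed = 1L,
                                      catalog = load_catalog(),
                                      model = load_model(catalog = catalog),
                                      rules = load_rules()) {
  sites <- harness_sites(catalog, filler_per_marker)
  panel <- simulate_panel(n_hap = n_hap, seed = seed, sites = sites)
  truth <- sample_individuals(panel, n_ind, seed = seed + 1L)

  truth_rows <- genotypes_to_rows(truth, catalog)
  truth_pv <- compute_pvalues(truth_rows, model, catalog)
  truth_ph <- classify_all(truth_pv, rules)
  truth_calls <- genotype_calls(truth, catalog$rsid, source = "truth")

  all_test_calls <- list()
  rep_phenos <- list()
  cells <- design$cells
  for (r in seq_len(nrow(cells))) {
    cov <- design$coverages[cells$cov[r]]
    obs <- downsample_observations(truth, coverage = cov, pmd_rate = pmd_rate,
                                   seed = cells$seed[r])
    imp <- naive_impute(obs, panel, k = k, seed = cells$seed[r] + 7L)
    calls <- genotype_calls(imp, catalog$rsid, source = "imputed")
    calls$coverage <- format(cov)
    calls$ds_rep <- cells$ds[r]
    calls$imp_rep <- cells$imp[r]
    all_test_calls[[r]] <- calls

    rows <- genotypes_to_rows(imp, catalog)
    pv <- compute_pvalues(rows, model, catalog)
    ph <- classify_all(pv, rules)
    ph$coverage <- format(cov)
    ph$ds_rep <- cells$ds[r]
    ph$imp_rep <- cells$imp[r]
    rep_phenos[[r]] <- ph
  }
  test_calls <- do.call(rbind, all_test_calls)
  geno_err <- compare_genotypes(truth_calls, test_calls, group_by = "coverage")

  per_marker <- compare_genotypes(truth_calls, test_calls,
                                  group_by = c("sample_id", "rsid", "coverage"))
  per_marker <- data.frame(sample_id = per_marker$sample_id,
                           rsid = per_marker$rsid,
                           coverage = per_marker$coverage,
                           error_frac = per_marker$frac_total,
                           n_errors = per_marker$n_total_error,
                           stringsAsFactors = FALSE)

  list(genotype_errors = geno_err,
       per_marker_errors = per_marker,
       truth_phenotypes = truth_ph,
       replicate_phenotypes = do.call(rbind, rep_phenos),
       truth = truth, panel = panel)
}
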