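# Synthetic fixtures: LD-bearing haplotype panel, diploid individuals,
# pseudo-haploid low-coverage observations with optional post-mortem-damage
# style noise, and a deliberately naive panel-based imputer used as a test
# oracle for the validation machinery. None of this emulates a production
# imputation engine; it exists so the whole workflow can be exercised
# offline and its metrics checked against constructions with known answers.

#' Simulate a phased haplotype reference panel with LD
#'
#' Haplotypes are built by Li-Stephens-style mosaic copying from a small set
#' of founder haplotypes: each haplotype follows one founder and switches to
#' a random founder with probability `mosaic_switch_rate` per site. Low
#' switch rates give long shared stretches, hence linkage disequilibrium
#' between neighbouring sites; a switch rate near 0.5 approaches site
#' independence. Monomorphic sites are re-polymorphised by flipping one
#' random haplotype so every site has a frequency in (0, 1).
#'
#' @param n_hap number of haplotypes (>= 4).
#' @param n_sites number of sites (>= 2); ignored when `sites` is given.
#' @param mosaic_switch_rate per-site founder switch probability in (0, 0.5].
#' @param seed integer seed; identical seeds give identical panels.
#' @param sites optional site table (`chrom`, `pos`, `ref`, `alt`, optional
#'   `id` and `freq` columns); defaults to evenly spaced synthetic SNPs on
#'   chromosome "1".
#' @param n_founders number of founder haplotypes (default 8).
#' @return A `hap_panel` object: `sites` (with realised `freq`),
#'   `haplotypes` (`n_hap x n_sites` 0/1 matrix) and the mosaic parameters.
#' @export
simulate_panel <- function(n_hap, n_sites = NULL, mosaic_switch_rate = 0.02,
                           seed = 1L, sites = NULL, n_founders = 8L) {
  if (n_hap < 4L) stop("need at least 4 haplotypes", call. = FALSE)
  if (is.null(sites)) {
    if (is.null(n_sites) || n_sites < 2L) stop("need at least 2 sites", call. = FALSE)
    bases <- c("A", "C", "G", "T")
    set.seed(seed)
    ref <- sample(bases, n_sites, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
    sites <- data.frame(chrom = "1", pos = seq_len(n_sites) * 1000L,
                        ref = ref, alt = unname(alt), stringsAsFactors = FALSE)
  }
  n_sites <- nrow(sites)
  if (is.null(sites$id)) sites$id <- paste0("s", seq_len(n_sites))
  ord <- order(chrom_rank(sites$chrom), sites$pos)
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  if (mosaic_switch_rate <= 0 || mosaic_switch_rate > 0.5) {
    stop("mosaic_switch_rate must lie in (0, 0.5]", call. = FALSE)
  }
  set.seed(seed)
  target <- runif(n_sites, 0.1, 0.5)
  if (!is.null(sites$freq)) {
    have <- !is.na(sites$freq)
    target[have] <- pmin(pmax(sites$freq[have], 0.02), 0.98)
  }
  founders <- matrix(rbinom(n_founders * n_sites, 1L, rep(target, each = n_founders)),
                     nrow = n_founders, ncol = n_sites)
  H <- matrix(0L, nrow = n_hap, ncol = n_sites)
  for (h in seq_len(n_hap)) {
    src <- sample.int(n_founders, 1L)
    for (s in seq_len(n_sites)) {
      if (runif(1) < mosaic_switch_rate) src <- sample.int(n_founders, 1L)
      H[h, s] <- founders[src, s]
    }
  }
  mono <- which(colSums(H) %in% c(0L, n_hap))
  for (s in mono) H[sample.int(n_hap, 1L), s] <- 1L - H[1L, s]
  sites$freq <- colMeans(H)
  structure(list(sites = sites, haplotypes = H,
                 params = list(mosaic_switch_rate = mosaic_switch_rate,
                               n_founders = n_founders, seed = seed)),
            class = "hap_panel")
}

#' Draw diploid individuals from a haplotype panel
#'
#' Each individual is a pair of panel haplotypes (drawn without replacement
#' within an individual); truth genotypes are the site-wise allele sums. The
#' drawn haplotype indices are kept so tests can verify exact recovery.
#'
#' @param panel a `hap_panel`.
#' @param n number of individuals (>= 1).
#' @param seed integer seed.
#' @return A `diploid_truth` object: `genotypes` (`n x n_sites` matrix of
#'   0/1/2 with sample ids as rownames), `hap_pairs`, and the panel's
#'   `sites`.
#' @export
sample_individuals <- function(panel, n, seed = 1L) {
  stopifnot(inherits(panel, "hap_panel"))
  if (n < 1L) stop("need n >= 1 individuals", call. = FALSE)
  set.seed(seed)
  n_hap <- nrow(panel$haplotypes)
  pairs <- t(vapply(seq_len(n), function(i) sample.int(n_hap, 2L), integer(2)))
  G <- panel$haplotypes[pairs[, 1L], , drop = FALSE] +
    panel$haplotypes[pairs[, 2L], , drop = FALSE]
  rownames(G) <- sprintf("ind%03d", seq_len(n))
  structure(list(genotypes = G, hap_pairs = pairs, sites = panel$sites),
            class = "diploid_truth")
}

# site-level PMD eligibility: a damaged read only changes the recorded
# allele when the C>T (G>A) transition maps onto the site's ref/alt pair
pmd_flippable <- function(sites) {
  list(ref_to_alt = (sites$ref == "C" & sites$alt == "T") |
         (sites$ref == "G" & sites$alt == "A"),
       alt_to_ref = (sites$alt == "C" & sites$ref == "T") |
         (sites$alt == "G" & sites$ref == "A"))
}

#' Simulate pseudo-haploid low-coverage read observations
#'
#' Read depth per (sample, site) is Poisson(`coverage`); each read samples
#' one of the individual's two alleles uniformly (the pseudo-haploid
#' regime: at low coverage most covered sites carry a single read). With
#' probability `pmd_rate` a read carrying a C (G) is deaminated to T (A);
#' the flip is only recorded when the damaged base coincides with the
#' site's other allele, otherwise the read is unchanged. This per-read flip
#' is a deliberate simplification of fragment-end damage curves.
#'
#' @param truth a `diploid_truth`.
#' @param coverage mean reads per site (> 0).
#' @param pmd_rate per-read damage probability in `[0, 1)`.
#' @param seed integer seed.
#' @return A `read_obs` object: matrices `nref`/`nalt` of post-noise read
#'   counts (`n x n_sites`), `n_damaged` flips applied, plus parameters.
#' @export
downsample_observations <- function(truth, coverage, pmd_rate = 0, seed = 1L) {
  stopifnot(inherits(truth, "diploid_truth"))
  if (coverage <= 0) stop("coverage must be positive", call. = FALSE)
  if (pmd_rate < 0 || pmd_rate >= 1) stop("pmd_rate must lie in [0, 1)", call. = FALSE)
  set.seed(seed)
  G <- truth$genotypes
  n <- nrow(G); s <- ncol(G)
  depth <- matrix(rpois(n * s, coverage), n, s)
  nalt <- matrix(rbinom(n * s, depth, G / 2), n, s)
  nref <- depth - nalt
  n_damaged <- matrix(0L, n, s)
  if (pmd_rate > 0) {
    fl <- pmd_flippable(truth$sites)
    r2a <- matrix(rbinom(n * s, nref, pmd_rate * rep(fl$ref_to_alt, each = n)), n, s)
    a2r <- matrix(rbinom(n * s, nalt, pmd_rate * rep(fl$alt_to_ref, each = n)), n, s)
    nref <- nref - r2a + a2r
    nalt <- nalt - a2r + r2a
    n_damaged <- r2a + a2r
  }
  dimnames(nref) <- dimnames(nalt) <- dimnames(G)
  structure(list(nref = nref, nalt = nalt, n_damaged = n_damaged,
                 sites = truth$sites, coverage = coverage,
                 pmd_rate = pmd_rate, seed = seed),
            class = "read_obs")
}

#' Full (noise-free) observations of every site
#'
#' Reads each of the two chromosomes exactly once at every site; used for
#' the exact-recovery oracle of [naive_impute()].
#'
#' @param truth a `diploid_truth`.
#' @return A `read_obs` object.
#' @export
full_observations <- function(truth) {
  stopifnot(inherits(truth, "diploid_truth"))
  G <- truth$genotypes
  structure(list(nref = 2L - G, nalt = G,
                 n_damaged = matrix(0L, nrow(G), ncol(G)),
                 sites = truth$sites, coverage = Inf, pmd_rate = 0, seed = NA),
            class = "read_obs")
}

#' Naive panel-based genotype imputation (test oracle)
#'
#' For each individual, every ordered pair of panel haplotypes is scored by
#' the read-level genotype log-likelihood of its implied diploid genotypes
#' (uncovered sites are uninformative); the `k` best-scoring pairs vote per
#' site and the majority genotype wins, with ties resolved to heterozygous.
#' An individual with no reads at all falls back to the per-site most
#' probable Hardy-Weinberg genotype under the panel allele frequencies.
#' This is a desk-scale test oracle with the qualitative behaviour of
#' reference-panel imputation (LD-informed recovery that degrades as
#' coverage falls); it is in no way a substitute for a production engine.
#'
#' @param obs a `read_obs`.
#' @param panel the `hap_panel` the observations' sites belong to.
#' @param k number of best haplotype pairs that vote (default 5).
#' @param seed replicate seed; only breaks exact score ties, so replicate
#'   runs differ only where the data leave the choice genuinely ambiguous.
#' @param error_rate per-read error rate of the likelihood model.
#' @return A `diploid_truth`-shaped object of imputed genotypes (class
#'   `imputed_calls`).
#' @export
naive_impute <- function(obs, panel, k = 5L, seed = 1L, error_rate = 0.01) {
  stopifnot(inherits(obs, "read_obs"), inherits(panel, "hap_panel"))
  if (nrow(panel$haplotypes) == 0L) stop("empty panel", call. = FALSE)
  if (!all(obs$sites$id %in% panel$sites$id)) {
    stop("observation sites must be a subset of panel sites", call. = FALSE)
  }
  site_idx <- match(obs$sites$id, panel$sites$id)
  H <- panel$haplotypes[, site_idx, drop = FALSE]
  n_hap <- nrow(H); S <- ncol(H)
  n <- nrow(obs$nref)
  e <- error_rate
  G_out <- matrix(NA_integer_, n, S, dimnames = dimnames(obs$nref))

  pair_idx <- which(upper.tri(matrix(0, n_hap, n_hap), diag = TRUE), arr.ind = TRUE)
  set.seed(seed)
  jitter <- runif(nrow(pair_idx)) * 1e-9  # breaks exact ties only

  freq <- panel$sites$freq[site_idx]
  hwe_best <- max.col(cbind((1 - freq)^2, 2 * freq * (1 - freq), freq^2),
                      ties.method = "last") - 1L

  for (i in seq_len(n)) {
    nr <- obs$nref[i, ]; na <- obs$nalt[i, ]
    if (sum(nr) + sum(na) == 0L) {
      G_out[i, ] <- hwe_best
      next
    }
    L0 <- nr * log(1 - e) + na * log(e)
    L1 <- (nr + na) * log(0.5)
    L2 <- nr * log(e) + na * log(1 - e)
    A0 <- as.numeric(H %*% L0)
    A1 <- as.numeric(H %*% L1)
    Q0 <- (H * rep(L0, each = n_hap)) %*% t(H)
    Q1 <- (H * rep(L1, each = n_hap)) %*% t(H)
    Q2 <- (H * rep(L2, each = n_hap)) %*% t(H)
    S0 <- sum(L0)
    # score(a,b) = sum_s L_{ha+hb}(s), expanded over the 0/1 indicator algebra
    sc <- S0 - (A0[pair_idx[, 1]] + A0[pair_idx[, 2]]) +
      (A1[pair_idx[, 1]] + A1[pair_idx[, 2]]) +
      Q0[pair_idx] - 2 * Q1[pair_idx] + Q2[pair_idx]
    best <- order(sc + jitter, decreasing = TRUE)[seq_len(min(k, length(sc)))]
    votes <- H[pair_idx[best, 1], , drop = FALSE] + H[pair_idx[best, 2], , drop = FALSE]
    n0 <- colSums(votes == 0L); n1 <- colSums(votes == 1L); n2 <- colSums(votes == 2L)
    g <- ifelse(n0 > n1 & n0 > n2, 0L, ifelse(n2 > n1 & n2 > n0, 2L, 1L))
    G_out[i, ] <- g
  }
  structure(list(genotypes = G_out, sites = obs$sites, k = k, seed = seed),
            class = "imputed_calls")
}

#' Long-format genotype calls from a genotype matrix object
#'
#' @param x a `diploid_truth` or `imputed_calls` object.
#' @param site_ids optional subset of site ids (default: all sites).
#' @param source provenance label stored on each record.
#' @return Data frame `sample_id`, `rsid` (site id), `a1`, `a2`,
#'   `gt_class`, `source` suitable for [compare_genotypes()].
#' @export
genotype_calls <- function(x, site_ids = NULL, source = "truth") {
  sites <- x$sites
  if (is.null(site_ids)) site_ids <- sites$id
  idx <- match(site_ids, sites$id)
  if (anyNA(idx)) stop("unknown site id(s)", call. = FALSE)
  G <- x$genotypes[, idx, drop = FALSE]
  n <- nrow(G); s <- length(idx)
  g <- as.integer(t(G))
  ref <- rep(sites$ref[idx], times = n)
  alt <- rep(sites$alt[idx], times = n)
  data.frame(
    sample_id = rep(rownames(G), each = s),
    rsid = rep(site_ids, times = n),
    a1 = ifelse(is.na(g), NA_character_, ifelse(g >= 1L, alt, ref)),
    a2 = ifelse(is.na(g), NA_character_, ifelse(g == 2L, alt, ref)),
    gt_class = ifelse(is.na(g), "MISSING",
                      c("HOMREF", "HET", "HOMALT")[g + 1L]),
    source = source,
    stringsAsFactors = FALSE
  )
}

#' Probe allele-count rows from simulated genotypes at the catalog markers
#'
#' @param x a `diploid_truth` or `imputed_calls` whose sites include the
#'   catalog rsids as site ids.
#' @param catalog marker catalog.
#' @return Data frame in [vcf_to_rows()] shape.
#' @export
genotypes_to_rows <- function(x, catalog) {
  idx <- match(catalog$rsid, x$sites$id)
  out <- data.frame(sampleid = rownames(x$genotypes), stringsAsFactors = FALSE)
  for (m in seq_len(nrow(catalog))) {
    marker <- catalog[m, ]
    if (is.na(idx[m])) {
      out[[marker$probe]] <- NA_integer_
      next
    }
    g <- x$genotypes[, idx[m]]
    target_is_alt <- counted_allele_forward(marker) == marker$alt
    out[[marker$probe]] <- as.integer(if (target_is_alt) g else 2L - g)
  }
  out
}

#' Write a haplotype panel as a phased VCF
#'
#' Minimal VCF 4.2 with `|`-phased genotypes; haplotypes `2i-1` and `2i`
#' form panel sample `i` (`n_hap` must be even).
#'
#' @param panel a `hap_panel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  H <- panel$haplotypes
  if (nrow(H) %% 2L != 0L) stop("need an even number of haplotypes", call. = FALSE)
  n_s <- nrow(H) / 2L
  gt <- matrix("", nrow(panel$sites), n_s)
  for (j in seq_len(n_s)) {
    gt[, j] <- paste0(H[2L * j - 1L, ], "|", H[2L * j, ])
  }
  write_simple_vcf(panel$sites, gt, sprintf("PANEL%03d", seq_len(n_s)), path)
}

#' Write diploid genotypes as an unphased VCF
#'
#' @param x a `diploid_truth` or `imputed_calls`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_vcf <- function(x, path) {
  G <- x$genotypes
  gt_map <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", ncol(G), nrow(G))
  for (j in seq_len(nrow(G))) {
    g <- G[j, ]
    gt[, j] <- ifelse(is.na(g), "./.", gt_map[g + 1L])
  }
  write_simple_vcf(x$sites, gt, rownames(G), path)
}

write_simple_vcf <- function(sites, gt, sample_ids, path) {
  stopifnot(nrow(gt) == nrow(sites), ncol(gt) == length(sample_ids))
  contigs <- unique(sites$chrom)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=hisplexr-synthetic",
    paste0("##contig=<ID=", contigs, ">"),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(sites)), function(i) {
    paste(c(sites$chrom[i], sites$pos[i], sites$id[i], sites$ref[i],
            sites$alt[i], ".", "PASS", ".", "GT", gt[i, ]), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}
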