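# the brute-force strand/allele oracle: an independent complement table and
# a literal count over the two alleles
oracle_translate <- function(a1, a2, ref, alt, strand, counted) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  target <- if (strand == "reverse") unname(comp[counted]) else counted
  sum(c(a1, a2) == target)
}

fake_marker <- function(rsid = "rsX", ref, alt, strand, counted,
                        variant_class = "SNP") {
  data.frame(rsid = rsid, chrom = "1", pos = 1000L, ref = ref, alt = alt,
             probe_strand = strand, counted_allele = counted,
             variant_class = variant_class, global_maf = 0.1,
             trait_tags = "skin", may_be_absent = FALSE,
             probe = paste0(rsid, "_", counted), stringsAsFactors = FALSE)
}

test_that("translation equals the exhaustive strand/allele enumeration oracle", {
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  n_checked <- 0L
  for (ref in bases) for (alt in setdiff(bases, ref)) {
    for (strand in c("forward", "reverse")) {
      for (counted_fwd in c(ref, alt)) {
        counted <- if (strand == "reverse") unname(comp[counted_fwd]) else counted_fwd
        marker <- fake_marker(ref = ref, alt = alt, strand = strand,
                              counted = counted)
        for (a1 in c(ref, alt)) for (a2 in c(ref, alt)) {
          call <- genotype_call("S1", "rsX", a1, a2)
          expect_identical(
            translate_genotype(call, marker),
            as.integer(oracle_translate(a1, a2, ref, alt, strand, counted)),
            label = paste(ref, alt, strand, counted, a1, a2))
          n_checked <- n_checked + 1L
        }
      }
    }
  }
  expect_equal(n_checked, 12L * 2L * 2L * 4L)
})

test_that("dosage conservation: counted-allele dosage equals alt dosage when probes count alt", {
  # for forward probes counting alt, and reverse probes whose counted allele
  # is the complement of alt, count == number of alt alleles for every
  # genotype; allele order/phase never matters
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (ref in c("A", "C")) for (alt in setdiff(c("G", "T"), ref)) {
    fwd <- fake_marker(ref = ref, alt = alt, strand = "forward", counted = alt)
    rev <- fake_marker(ref = ref, alt = alt, strand = "reverse",
                       counted = unname(comp[alt]))
    for (pair in list(c(ref, ref), c(ref, alt), c(alt, ref), c(alt, alt))) {
      n_alt <- sum(pair == alt)
      for (m in list(fwd, rev)) {
        c1 <- translate_genotype(genotype_call("S", "rsX", pair[1], pair[2]), m)
        c2 <- translate_genotype(genotype_call("S", "rsX", pair[2], pair[1]), m)
        expect_identical(c1, n_alt)
        expect_identical(c2, c1)  # phase/order invariance
      }
    }
  }
})

test_that("missing and foreign alleles are handled per contract", {
  marker <- fake_marker(ref = "A", alt = "G", strand = "forward", counted = "G")
  expect_true(is.na(translate_genotype(genotype_call("S", "rsX"), marker)))
  expect_true(is.na(translate_genotype(genotype_call("S", "rsX", "A", NA), marker)))
  expect_error(
    translate_genotype(genotype_call("S", "rsX", "A", "C"), marker),
    "matches neither ref")
  expect_error(
    translate_genotype(genotype_call("S", "rsY", "A", "G"), marker),
    "does not match marker")
})

test_that("the dupA red-hair marker translates as a biallelic duplication", {
  cat_df <- the_catalog()
  dup <- cat_df[cat_df$rsid == "rs312262906", ]
  het <- genotype_call("S", "rs312262906", dup$ref, dup$alt)
  hom <- genotype_call("S", "rs312262906", dup$alt, dup$alt)
  expect_identical(translate_genotype(het, dup), 1L)
  expect_identical(translate_genotype(hom, dup), 2L)
})

test_that("vcf_to_rows translates a complete single-sample VCF without NAs", {
  cat_df <- the_catalog()
  f <- withr::local_tempfile(fileext = ".vcf")
  catalog_vcf(f, cat_df, function(m, s) "0/1")
  rows <- vcf_to_rows(f, cat_df)
  expect_equal(nrow(rows), 1L)
  counts <- unlist(rows[1, cat_df$probe])
  expect_false(anyNA(counts))
  expect_true(all(counts == 1L))  # HET counts 1 whichever allele is probed
})

test_that("markers absent from the VCF and missing genotypes yield NA", {
  cat_df <- the_catalog()
  f <- withr::local_tempfile(fileext = ".vcf")
  keep <- 1:21  # drop 20 catalog sites
  sub <- cat_df[keep, ]
  attr(sub, "build") <- "GRCh38"
  catalog_vcf(f, sub, function(m, s) if (m == 1L) "./." else "0/0")
  rows <- vcf_to_rows(f, cat_df)
  counts <- unlist(rows[1, cat_df$probe])
  expect_equal(sum(is.na(counts)), 20L + 1L)

  # half-missing diploid genotypes are conservatively NA
  catalog_vcf(f, sub, function(m, s) if (m == 2L) "./1" else "0/0")
  rows <- vcf_to_rows(f, cat_df)
  expect_true(is.na(rows[1, cat_df$probe[2]]))
})

test_that("multiallelic records are decomposed against the catalog alt", {
  cat_df <- the_catalog()
  marker <- cat_df[cat_df$rsid == "rs16891982", ]  # ref C, alt G, counts C
  third <- setdiff(c("A", "C", "G", "T"), c(marker$ref, marker$alt))[1]
  f <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(f, marker$chrom, marker$pos, marker$ref,
                 paste(third, marker$alt, sep = ","),
                 matrix("0/2", 1, 1))
  sub <- marker
  attr(sub, "build") <- "GRCh38"
  rows <- vcf_to_rows(f, sub)
  # GT 0/2 = ref + catalog alt; the probe counts the ref allele here -> 1
  expect_identical(rows[[marker$probe]], 1L)

  # an allele that is neither ref nor the catalog alt contributes nothing
  write_test_vcf(f, marker$chrom, marker$pos, marker$ref,
                 paste(third, marker$alt, sep = ","),
                 matrix("1/2", 1, 1))
  rows <- vcf_to_rows(f, sub)
  expect_identical(rows[[marker$probe]], 0L)
})

test_that("dupA matches both left-aligned and anchor-base VCF representations", {
  cat_df <- the_catalog()
  dup <- cat_df[cat_df$rsid == "rs312262906", ]
  attr_dup <- dup; attr(attr_dup, "build") <- "GRCh38"
  f <- withr::local_tempfile(fileext = ".vcf")
  # left-aligned: pos, A -> AA
  write_test_vcf(f, dup$chrom, dup$pos, "A", "AA", matrix("0/1", 1, 1))
  expect_identical(vcf_to_rows(f, attr_dup)[[dup$probe]], 1L)
  # anchor-base-previous: pos-1, C -> CA
  write_test_vcf(f, dup$chrom, dup$pos - 1L, "C", "CA", matrix("1/1", 1, 1))
  expect_identical(vcf_to_rows(f, attr_dup)[[dup$probe]], 2L)
})

test_that("a VCF on the wrong build's contigs is a configuration error", {
  cat_df <- the_catalog()
  f <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(f, "GL000205.2", 1000L, "A", "G", matrix("0/0", 1, 1))
  expect_error(vcf_to_rows(f, cat_df), "no catalog contig")
})

test_that("upload CSV writing is byte-stable and round-trips", {
  cat_df <- the_catalog()
  f <- withr::local_tempfile(fileext = ".vcf")
  catalog_vcf(f, cat_df, function(m, s) c("0/0", "0/1", "1/1")[(m + s) %% 3 + 1],
              samples = c("S1", "S2"))
  rows <- vcf_to_rows(f, cat_df)
  rows[1, cat_df$probe[5]] <- NA_integer_

  out1 <- withr::local_tempfile(fileext = ".csv")
  out2 <- withr::local_tempfile(fileext = ".csv")
  write_upload_csv(rows, out1, cat_df)
  write_upload_csv(rows, out2, cat_df)
  expect_identical(readLines(out1), readLines(out2))

  header <- strsplit(readLines(out1)[1], ",")[[1]]
  expect_identical(header, upload_columns(cat_df))
  expect_equal(length(readLines(out1)), 1L + nrow(rows))
  # the missing count is encoded as the dialect NA token
  expect_match(readLines(out1)[2], "NA")

  back <- read_upload_csv(out1, cat_df)
  expect_equal(back$sampleid, rows$sampleid)
  for (p in cat_df$probe) expect_equal(back[[p]], rows[[p]], label = p)
})
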