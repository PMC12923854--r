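# Shared fixtures, built in code. Loading the shipped catalog warns about
# the marker known to be absent from GRCh38 joint call sets; tests that are
# not about that warning load quietly.

the_catalog <- function(build = "GRCh38") {
  suppressWarnings(load_catalog(build = build))
}

the_model <- function(catalog = the_catalog()) {
  load_model(catalog = catalog)
}

the_rules <- function() load_rules()

# a valid p-value row in compute_pvalues() output shape
pv_row <- function(eye = c(1, 0, 0) / 1, hair = c(1, 0, 0, 0),
                   shade = c(1, 0), skin = c(1, 0, 0, 0, 0),
                   hair_available = TRUE, sampleid = "S1") {
  out <- data.frame(sampleid = sampleid, stringsAsFactors = FALSE)
  vals <- c(eye, hair, shade, skin)
  cols <- c(paste0("p_eye_", c("blue", "intermediate", "brown")),
            paste0("p_hair_", c("blond", "brown", "red", "black")),
            paste0("p_shade_", c("light", "dark")),
            paste0("p_skin_", c("very_pale", "pale", "intermediate",
                                "dark", "dark_black")))
  for (i in seq_along(cols)) out[[cols[i]]] <- vals[i]
  out$n_missing <- 0L
  out$hair_available <- hair_available
  out
}

# write a minimal VCF for arbitrary records; gt is a records x samples
# character matrix of GT strings
write_test_vcf <- function(path, chrom, pos, ref, alt, gt,
                           samples = paste0("S", seq_len(ncol(gt))),
                           id = ".") {
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", unique(chrom), ">"),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  id <- rep_len(id, length(pos))
  body <- vapply(seq_along(pos), function(i) {
    paste(c(chrom[i], pos[i], id[i], ref[i], alt[i], ".", "PASS", ".", "GT",
            gt[i, ]), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  path
}

# VCF carrying all 41 catalog markers with a fixed genotype pattern:
# gt_maker(marker_index) -> GT string per sample
catalog_vcf <- function(path, catalog, gt_maker, samples = c("S1")) {
  gt <- t(vapply(seq_len(nrow(catalog)),
                 function(m) vapply(seq_along(samples),
                                    function(s) gt_maker(m, s), ""),
                 character(length(samples))))
  gt <- matrix(gt, nrow = nrow(catalog))
  write_test_vcf(path, catalog$chrom, catalog$pos, catalog$ref, catalog$alt,
                 gt, samples = samples, id = catalog$rsid)
}

# small genotype-call table builder for metric tests
calls_df <- function(sample_id, rsid, gt_class, ...) {
  data.frame(sample_id = sample_id, rsid = rsid, gt_class = gt_class, ...,
             stringsAsFactors = FALSE)
}
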