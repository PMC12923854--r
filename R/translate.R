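# Genotype translation: reference-based diploid genotypes -> probe-based
# allele counts (the "translate" stage of the workflow).

revcomp <- function(x) {
  chartr("ACGT", "TGCA", sapply(lapply(strsplit(toupper(x), ""), rev), paste, collapse = ""))
}

# Forward-strand allele the probe counts. For the dupA insertion the counted
# allele is the duplication haplotype itself (the alt allele); strand is
# irrelevant for counting an A duplicated inside an A run.
counted_allele_forward <- function(marker) {
  if (marker$variant_class == "single-base-duplication") {
    marker$alt
  } else if (marker$probe_strand == "reverse") {
    revcomp(marker$counted_allele)
  } else {
    marker$counted_allele
  }
}

#' Build a genotype call record
#'
#' A light-weight constructor for the diploid genotype records used by
#' [translate_genotype()] and the validation metrics. Alleles are expressed
#' on the reference forward strand; a missing genotype carries no alleles.
#'
#' @param sample_id sample identifier.
#' @param rsid marker identifier.
#' @param a1,a2 the two alleles (forward strand), or `NA` when missing.
#' @param source one of `"truth"`, `"imputed"`, `"external"`.
#' @return A one-row data frame with a derived `gt_class` column
#'   (`HOMREF`/`HET`/`HOMALT`/`MISSING` is derived later against a marker).
#' @export
genotype_call <- function(sample_id, rsid, a1 = NA_character_, a2 = NA_character_,
                          source = "truth") {
  data.frame(sample_id = sample_id, rsid = rsid,
             a1 = toupper(as.character(a1)), a2 = toupper(as.character(a2)),
             source = source, stringsAsFactors = FALSE)
}

#' Classify a diploid genotype against a marker
#'
#' @param a1,a2 alleles on the forward strand (`NA` = missing).
#' @param marker one catalog row.
#' @return `"HOMREF"`, `"HET"`, `"HOMALT"` or `"MISSING"`. Half-missing
#'   genotypes are treated as `MISSING` (conservative diploid requirement).
#' @export
gt_class <- function(a1, a2, marker) {
  if (is.na(a1) || is.na(a2)) return("MISSING")
  alleles <- c(a1, a2)
  bad <- setdiff(alleles, c(marker$ref, marker$alt))
  if (length(bad) > 0L) {
    stop("allele '", bad[1], "' at ", marker$rsid,
         " matches neither ref nor alt", call. = FALSE)
  }
  n_alt <- sum(alleles == marker$alt)
  c("HOMREF", "HET", "HOMALT")[n_alt + 1L]
}

#' Translate one diploid genotype into a probe allele count
#'
#' Counts how many of the two alleles equal the probe-counted allele after
#' mapping that allele onto the reference forward strand (reverse complement
#' when the probe was designed on the reverse strand). The result is the
#' 0/1/2 dosage the HIrisPlex-S upload format expects; a missing genotype
#' translates to `NA`.
#'
#' @param call a one-row genotype record (see [genotype_call()]); its `rsid`
#'   must match the marker's.
#' @param marker one catalog row.
#' @return Integer count in `{0, 1, 2}` or `NA`.
#' @export
translate_genotype <- function(call, marker) {
  if (!identical(call$rsid, marker$rsid)) {
    stop("call rsid '", call$rsid, "' does not match marker '", marker$rsid, "'",
         call. = FALSE)
  }
  if (is.na(call$a1) || is.na(call$a2)) return(NA_integer_)
  alleles <- toupper(c(call$a1, call$a2))
  bad <- setdiff(alleles, c(marker$ref, marker$alt))
  if (length(bad) > 0L) {
    stop("sample ", call$sample_id, ", marker ", marker$rsid,
         ": allele '", bad[1], "' matches neither ref '", marker$ref,
         "' nor alt '", marker$alt, "'", call. = FALSE)
  }
  target <- counted_allele_forward(marker)
  sum(alleles == target)
}

# Canonical (pos, ref, alt) for indel-representation comparison: shared
# trailing bases are trimmed first, then shared leading bases (advancing
# pos), keeping at least one base on each allele. Left-aligned duplications
# and anchor-base insertions of the same base then compare equal up to a
# one-base position shift, which match_marker_records() tolerates.
normalize_variant <- function(pos, ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L && substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

# Does a VCF record (possibly one decomposed alt) represent this marker?
marker_matches_record <- function(marker, rec_pos, rec_ref, rec_alt) {
  if (marker$variant_class == "SNP") {
    return(rec_pos == marker$pos && rec_ref == marker$ref && rec_alt == marker$alt)
  }
  # duplication: compare normalized representations, tolerating the
  # anchor-base-previous form (pos off by one, same inserted base)
  m <- normalize_variant(marker$pos, marker$ref, marker$alt)
  r <- normalize_variant(rec_pos, rec_ref, rec_alt)
  ins_m <- sub(paste0("^", m$ref), "", m$alt)
  ins_r <- sub(paste0("^", r$ref), "", r$alt)
  nchar(r$alt) - nchar(r$ref) == 1L && ins_r == ins_m && abs(r$pos - m$pos) <= 1L
}

#' Translate a VCF into probe allele-count rows
#'
#' Reads diploid genotypes from a VCF (plain or bgzipped), matches the 41
#' catalog markers by chromosome, position and alleles (the VCF ID column is
#' never trusted on its own), decomposes multiallelic records so only the
#' catalog alt is considered, and translates every genotype into probe
#' allele counts. Markers absent from the VCF, or with (half-)missing
#' genotypes, yield `NA`.
#'
#' @param vcf path to a VCF file.
#' @param catalog catalog from [load_catalog()]; its build must match the
#'   VCF coordinates.
#' @return Data frame: `sampleid` column plus one integer column per probe
#'   (41 columns, catalog order).
#' @export
vcf_to_rows <- function(vcf, catalog) {
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  chrom_plain <- normalize_chrom(fix[, "CHROM"], "plain")
  cat_chroms <- unique(normalize_chrom(catalog$chrom, "plain"))
  if (nrow(fix) > 0L && !any(chrom_plain %in% cat_chroms)) {
    stop("no catalog contig found in VCF; is the build (",
         attr(catalog, "build"), ") correct?", call. = FALSE)
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field", call. = FALSE)
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix),
                                     dimnames = list(NULL, colnames(v@gt)[-1]))
  samples <- colnames(gt)
  pos <- as.integer(fix[, "POS"])

  counts <- matrix(NA_integer_, nrow = length(samples), ncol = nrow(catalog),
                   dimnames = list(samples, catalog$probe))
  for (m in seq_len(nrow(catalog))) {
    marker <- catalog[m, ]
    marker_chrom <- normalize_chrom(marker$chrom, "plain")
    cand <- which(chrom_plain == marker_chrom & abs(pos - marker$pos) <= 1L)
    hit <- NULL
    for (i in cand) {
      alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
      for (ai in seq_along(alts)) {
        if (marker_matches_record(marker, pos[i], toupper(fix[i, "REF"]),
                                  toupper(alts[ai]))) {
          hit <- list(row = i, alt_index = ai, alts = toupper(alts),
                      ref = toupper(fix[i, "REF"]))
          break
        }
      }
      if (!is.null(hit)) break
    }
    if (is.null(hit)) next  # marker absent from VCF -> NA
    target_is_alt <- counted_allele_forward(marker) == marker$alt ||
      marker$variant_class == "single-base-duplication"
    for (s in seq_along(samples)) {
      gt_str <- gt[hit$row, s]
      if (is.na(gt_str)) next
      idx <- strsplit(gt_str, "[/|]")[[1]]
      if (length(idx) != 2L || any(idx == ".")) next  # half/fully missing
      idx <- as.integer(idx)
      # count against the catalog alleles only; other decomposed alts
      # contribute nothing to the counted dosage
      is_target <- if (target_is_alt) idx == hit$alt_index else idx == 0L
      counts[s, m] <- sum(is_target)
    }
  }
  out <- data.frame(sampleid = samples, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(counts, optional = TRUE))
  rownames(out) <- NULL
  out
}

#' Write probe allele-count rows as the batch-upload CSV
#'
#' Emits the fixed-header CSV consumed by the HIrisPlex-S batch phenotyping
#' service (header spelling from `inst/extdata/upload_dialect.yaml`, missing
#' counts encoded as the dialect's NA token). Output is byte-stable for
#' identical input.
#'
#' @param rows data frame from [vcf_to_rows()].
#' @param path output CSV path.
#' @param catalog catalog defining the probe column order.
#' @return `path`, invisibly.
#' @export
write_upload_csv <- function(rows, path, catalog = load_catalog()) {
  cols <- upload_columns(catalog)
  missing_cols <- setdiff(cols, names(rows))
  if (length(missing_cols) > 0L) {
    stop("rows are missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  dialect <- yaml::read_yaml(hisplex_extdata("upload_dialect.yaml"))
  out <- rows[, cols, drop = FALSE]
  lines <- c(paste(cols, collapse = ","),
             apply(out, 1L, function(r) {
               r[is.na(r)] <- dialect$na_token
               paste(trimws(r), collapse = ",")
             }))
  writeLines(lines, path)
  invisible(path)
}

#' Read a batch-upload CSV back into probe allele-count rows
#'
#' @param path CSV written by [write_upload_csv()] (or hand-prepared in the
#'   same dialect).
#' @param catalog catalog defining the expected columns.
#' @return Data frame in the same shape as [vcf_to_rows()] output.
#' @export
read_upload_csv <- function(path, catalog = load_catalog()) {
  dialect <- yaml::read_yaml(hisplex_extdata("upload_dialect.yaml"))
  tab <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = dialect$na_token)
  cols <- upload_columns(catalog)
  missing_cols <- setdiff(cols, names(tab))
  if (length(missing_cols) > 0L) {
    stop("upload file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- tab[, cols, drop = FALSE]
  for (p in catalog$probe) out[[p]] <- as.integer(out[[p]])
  bad <- vapply(catalog$probe,
                function(p) any(!is.na(out[[p]]) & !out[[p]] %in% 0:2),
                logical(1))
  if (any(bad)) {
    stop("counts outside {0,1,2,NA} in column(s): ",
         paste(catalog$probe[bad], collapse = ", "), call. = FALSE)
  }
  out
}
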