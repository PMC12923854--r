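# Marker catalog: loading, validation and per-build views.

BUILDS <- c("GRCh37", "hg19", "GRCh38", "hg38")

# GRCh37/hg19 share coordinates, as do GRCh38/hg38; hg* builds use the UCSC
# "chr"-prefixed chromosome dialect, GRCh* the plain Ensembl dialect.
build_family <- function(build) {
  if (!is.character(build) || length(build) != 1L || !build %in% BUILDS) {
    stop("unknown build '", paste(build, collapse = ","),
         "'; expected one of ", paste(BUILDS, collapse = ", "), call. = FALSE)
  }
  if (build %in% c("GRCh37", "hg19")) "GRCh37" else "GRCh38"
}

build_dialect <- function(build) {
  if (build_family(build) == build) "plain" else "ucsc"
}

#' Normalize chromosome names between naming dialects
#'
#' Converts chromosome names to either the plain Ensembl dialect (`"16"`) or
#' the UCSC dialect (`"chr16"`). Normalization is applied when catalogs and
#' chromosome-length tables are loaded, so mixed-dialect inputs compare
#' correctly.
#'
#' @param chrom character vector of chromosome names.
#' @param dialect `"plain"` or `"ucsc"`.
#' @return Character vector in the requested dialect.
#' @export
normalize_chrom <- function(chrom, dialect = c("plain", "ucsc")) {
  dialect <- match.arg(dialect)
  plain <- sub("^chr", "", as.character(chrom))
  if (dialect == "plain") plain else paste0("chr", plain)
}

#' Load the HIrisPlex-S marker catalog for a reference build
#'
#' Reads the 41-marker catalog table, validates it and returns the per-build
#' view used by every other function in the package. The catalog is data, not
#' constants: coordinates, probe strand and counted alleles live in the TSV
#' (see `inst/extdata/SCHEMA.md`) and corrections belong there.
#'
#' @param path path to a catalog TSV; defaults to the shipped fixture.
#' @param build one of `"GRCh37"`, `"hg19"`, `"GRCh38"`, `"hg38"`. Selects
#'   the coordinate column and the chromosome naming dialect.
#' @return A data frame of 41 rows with columns `rsid`, `chrom`, `pos`,
#'   `ref`, `alt`, `probe_strand`, `counted_allele`, `variant_class`,
#'   `global_maf`, `trait_tags`, `may_be_absent`, `probe`, carrying
#'   attributes `build` and `catalog = TRUE`. Markers flagged as possibly
#'   absent from joint call sets of the requested build family raise a
#'   warning, not an error.
#' @export
load_catalog <- function(path = NULL, build = "GRCh38") {
  if (is.null(path)) path <- hisplex_extdata("markers_hisplex_s.tsv")
  if (!file.exists(path)) stop("catalog file not found: ", path, call. = FALSE)
  fam <- build_family(build)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE)
  required <- c("rsid", "chrom", "pos_GRCh37", "pos_GRCh38", "ref", "alt",
                "probe_strand", "counted_allele", "variant_class",
                "global_maf", "trait_tags", "may_be_absent_GRCh38")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("catalog is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  dup <- raw$rsid[duplicated(raw$rsid)]
  if (length(dup) > 0L) {
    stop("duplicated rsid(s) in catalog: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (nrow(raw) != 41L) {
    stop("expected 41 markers, found ", nrow(raw), call. = FALSE)
  }

  pos_col <- paste0("pos_", fam)
  cat_df <- data.frame(
    rsid = raw$rsid,
    chrom = normalize_chrom(raw$chrom, build_dialect(build)),
    pos = as.integer(raw[[pos_col]]),
    ref = toupper(raw$ref),
    alt = toupper(raw$alt),
    probe_strand = raw$probe_strand,
    counted_allele = toupper(raw$counted_allele),
    variant_class = raw$variant_class,
    global_maf = as.numeric(raw$global_maf),
    trait_tags = raw$trait_tags,
    may_be_absent = fam == "GRCh38" & toupper(raw$may_be_absent_GRCh38) == "TRUE",
    stringsAsFactors = FALSE
  )
  validate_catalog(cat_df)
  cat_df$probe <- paste0(cat_df$rsid, "_", cat_df$counted_allele)
  attr(cat_df, "build") <- build
  attr(cat_df, "catalog") <- TRUE
  if (any(cat_df$may_be_absent)) {
    warning("marker(s) possibly absent from ", fam, "-based joint call sets: ",
            paste(cat_df$rsid[cat_df$may_be_absent], collapse = ", "),
            call. = FALSE)
  }
  cat_df
}

validate_catalog <- function(cat_df) {
  fail_row <- function(i, msg) {
    stop("catalog row ", i, " (", cat_df$rsid[i], "): ", msg, call. = FALSE)
  }
  for (i in seq_len(nrow(cat_df))) {
    row <- cat_df[i, ]
    if (is.na(row$pos) || row$pos < 1L) fail_row(i, "position must be >= 1")
    if (!row$probe_strand %in% c("forward", "reverse")) {
      fail_row(i, paste0("bad probe_strand '", row$probe_strand, "'"))
    }
    if (is.na(row$global_maf) || row$global_maf < 0 || row$global_maf > 0.5) {
      fail_row(i, "global_maf must lie in [0, 0.5]")
    }
    if (row$variant_class == "SNP") {
      if (nchar(row$ref) != 1L || nchar(row$alt) != 1L || row$ref == row$alt) {
        fail_row(i, "SNP must have distinct single-base ref and alt")
      }
      counted_fwd <- if (row$probe_strand == "reverse") {
        revcomp(row$counted_allele)
      } else {
        row$counted_allele
      }
      if (!counted_fwd %in% c(row$ref, row$alt)) {
        fail_row(i, paste0("counted allele '", row$counted_allele,
                           "' maps to neither ref nor alt on the forward strand"))
      }
    } else if (row$variant_class == "single-base-duplication") {
      if (nchar(row$alt) != nchar(row$ref) + 1L || !startsWith(row$alt, row$ref)) {
        fail_row(i, "duplication must have alt = ref plus one duplicated base")
      }
    } else {
      fail_row(i, paste0("unknown variant_class '", row$variant_class, "'"))
    }
  }
  key <- paste(cat_df$chrom, cat_df$pos)
  if (anyDuplicated(key)) {
    stop("catalog has markers sharing (chrom, pos): ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  }
  tags <- strsplit(cat_df$trait_tags, ",", fixed = TRUE)
  bad_tags <- setdiff(unique(unlist(tags)), c("eye", "hair", "skin", "mc1r"))
  if (length(bad_tags) > 0L) {
    stop("unknown trait tag(s): ", paste(bad_tags, collapse = ", "), call. = FALSE)
  }
  n_mc1r <- sum(vapply(tags, function(t) "mc1r" %in% t, logical(1)))
  if (n_mc1r != 11L) {
    stop("expected exactly 11 MC1R-tagged markers, found ", n_mc1r, call. = FALSE)
  }
  invisible(TRUE)
}

#' Write a per-build catalog view back to TSV
#'
#' Inverse of [load_catalog()] for a single build: a written catalog re-loads
#' to an identical table (round-trip property).
#'
#' @param catalog a catalog from [load_catalog()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(isTRUE(attr(catalog, "catalog")))
  fam <- build_family(attr(catalog, "build"))
  out <- data.frame(
    rsid = catalog$rsid,
    chrom = normalize_chrom(catalog$chrom, "plain"),
    pos_GRCh37 = if (fam == "GRCh37") catalog$pos else NA_integer_,
    pos_GRCh38 = if (fam == "GRCh38") catalog$pos else NA_integer_,
    ref = catalog$ref,
    alt = catalog$alt,
    probe_strand = catalog$probe_strand,
    counted_allele = catalog$counted_allele,
    variant_class = catalog$variant_class,
    global_maf = catalog$global_maf,
    trait_tags = catalog$trait_tags,
    may_be_absent_GRCh38 = ifelse(catalog$may_be_absent, "TRUE", "FALSE"),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Subset a catalog to its MC1R markers
#'
#' The 11 MC1R gene variants drive red-hair prediction; when all of them are
#' missing the HIrisPlex-S system does not predict hair phenotype at all.
#'
#' @param catalog a catalog data frame (any subset of one).
#' @return Rows of `catalog` tagged `mc1r`, in catalog order.
#' @export
mc1r_subset <- function(catalog) {
  tags <- strsplit(catalog$trait_tags, ",", fixed = TRUE)
  keep <- vapply(tags, function(t) "mc1r" %in% t, logical(1))
  catalog[keep, , drop = FALSE]
}

#' Load chromosome lengths for a reference build
#'
#' @param path length TSV (`build`, `chrom`, `length`); defaults to the
#'   shipped table covering the 22 autosomes of both build families.
#' @param build reference build; selects rows and the naming dialect.
#' @return Named integer-valued numeric vector: chromosome -> length in bp.
#' @export
load_chrom_lengths <- function(path = NULL, build = "GRCh38") {
  if (is.null(path)) path <- hisplex_extdata("chrom_lengths.tsv")
  fam <- build_family(build)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = c("character", "character", "numeric"))
  tab <- tab[tab$build == fam, , drop = FALSE]
  if (nrow(tab) == 0L) stop("no chromosome lengths for build ", fam, call. = FALSE)
  if (any(!is.finite(tab$length) | tab$length <= 0)) {
    stop("chromosome lengths must be positive", call. = FALSE)
  }
  chroms <- normalize_chrom(tab$chrom, build_dialect(build))
  if (anyDuplicated(chroms)) stop("duplicated chromosome in length table", call. = FALSE)
  stats::setNames(tab$length, chroms)
}

#' Ordered probe-count column names for the upload file
#'
#' @param catalog a catalog from [load_catalog()].
#' @return Character vector: the sample-id column followed by the 41 probe
#'   columns in catalog order.
#' @export
upload_columns <- function(catalog) {
  dialect <- yaml::read_yaml(hisplex_extdata("upload_dialect.yaml"))
  cols <- c(dialect$sample_column, catalog$probe)
  # the dialect file is the authority on spelling; the catalog on order
  if (!setequal(dialect$probe_columns, catalog$probe)) {
    stop("upload dialect and catalog disagree on probe names", call. = FALSE)
  }
  cols
}
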