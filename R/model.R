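# The 14-p-value engine: multinomial-logistic trait model over probe
# allele counts, with coefficients supplied as configuration.

MODEL_GROUPS <- list(
  eye         = c("blue", "intermediate", "brown"),
  hair_colour = c("blond", "brown", "red", "black"),
  hair_shade  = c("light", "dark"),
  skin        = c("very_pale", "pale", "intermediate", "dark", "dark_black")
)

# native p-value column names, fixed order (3 eye + 4 hair + 2 shade + 5 skin)
pvalue_columns <- function() {
  c(paste0("p_eye_", MODEL_GROUPS$eye),
    paste0("p_hair_", MODEL_GROUPS$hair_colour),
    paste0("p_shade_", MODEL_GROUPS$hair_shade),
    paste0("p_skin_", MODEL_GROUPS$skin))
}

#' Load and validate a trait-model coefficient file
#'
#' The model is a multinomial-logistic regression per trait group (eye 3,
#' hair colour 4, hair shade 2, skin 5 categories) over probe allele counts.
#' One category per group is the reference with linear predictor fixed at 0;
#' every other category carries an intercept and per-probe dosage
#' coefficients. The package ships a clearly labelled synthetic demo model;
#' the published HIrisPlex-S coefficients are configuration the user
#' supplies in the same layout (see `inst/extdata/SCHEMA.md`).
#'
#' @param path YAML coefficient file; defaults to the shipped demo model.
#' @param catalog catalog used to resolve probe names.
#' @return A validated model object (list), class `"hisplex_model"`.
#' @export
load_model <- function(path = NULL, catalog = load_catalog()) {
  if (is.null(path)) path <- hisplex_extdata("model_demo.yaml")
  spec <- yaml::read_yaml(path)
  if (is.null(spec$groups)) stop("model file has no 'groups' section", call. = FALSE)
  for (g in names(MODEL_GROUPS)) {
    if (is.null(spec$groups[[g]])) stop("group missing from model: ", g, call. = FALSE)
  }
  model <- list(name = spec$model %||% "unnamed", groups = list())
  for (g in names(MODEL_GROUPS)) {
    gspec <- spec$groups[[g]]
    cats <- MODEL_GROUPS[[g]]
    if (is.null(gspec$reference) || !gspec$reference %in% cats) {
      stop("group ", g, ": reference category must be one of ",
           paste(cats, collapse = ", "), call. = FALSE)
    }
    non_ref <- setdiff(cats, gspec$reference)
    missing_cat <- setdiff(non_ref, names(gspec$categories))
    if (length(missing_cat) > 0L) {
      stop("group ", g, ": category missing: ",
           paste(missing_cat, collapse = ", "), call. = FALSE)
    }
    cat_list <- list()
    for (cc in non_ref) {
      cspec <- gspec$categories[[cc]]
      beta <- unlist(cspec$coefficients)
      if (is.null(beta)) beta <- stats::setNames(numeric(0), character(0))
      intercept <- as.numeric(cspec$intercept %||% 0)
      if (!is.finite(intercept) || any(!is.finite(beta))) {
        stop("group ", g, ", category ", cc, ": non-finite coefficient",
             call. = FALSE)
      }
      unknown <- setdiff(names(beta), catalog$probe)
      if (length(unknown) > 0L) {
        stop("model references unknown marker probe(s): ",
             paste(unknown, collapse = ", "), call. = FALSE)
      }
      cat_list[[cc]] <- list(intercept = intercept, beta = beta)
    }
    model$groups[[g]] <- list(reference = gspec$reference,
                              categories = cats, coef = cat_list)
  }
  class(model) <- "hisplex_model"
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Probes used by the model in a given group (union over categories).
group_probes <- function(model, group) {
  unique(unlist(lapply(model$groups[[group]]$coef, function(x) names(x$beta))))
}

# Softmax over linear predictors for one group and one dosage vector.
# Missing markers are dropped from the linear predictor (partial-information
# rule); the reference category's predictor stays 0.
group_pvalues <- function(gmodel, dosages) {
  eta <- stats::setNames(numeric(length(gmodel$categories)), gmodel$categories)
  for (cc in names(gmodel$coef)) {
    co <- gmodel$coef[[cc]]
    d <- dosages[names(co$beta)]
    ok <- !is.na(d)
    eta[cc] <- co$intercept + sum(co$beta[ok] * d[ok])
  }
  eta <- eta - max(eta)  # overflow guard
  p <- exp(eta)
  p / sum(p)
}

#' Compute the 14 trait p-values for probe allele-count rows
#'
#' Per trait group the linear predictor of each non-reference category is
#' its intercept plus the dosage-weighted coefficient sum over non-missing
#' markers; probabilities follow by softmax with the reference category's
#' predictor fixed at 0. Missing markers are dropped from the predictor and
#' counted in `n_missing`. When all 11 MC1R counts are missing the system
#' does not predict hair at all: both hair groups are `NA` and
#' `hair_available` is `FALSE`. A group whose model markers are all missing
#' is likewise undefined (`NA`), never silently uniform.
#'
#' @param rows probe allele-count rows ([vcf_to_rows()] / [read_upload_csv()]).
#' @param model model from [load_model()].
#' @param catalog catalog matching `rows` and `model`.
#' @return Data frame: `sampleid`, the 14 p-value columns in fixed native
#'   order, `n_missing` (markers without a count) and `hair_available`.
#' @export
compute_pvalues <- function(rows, model, catalog = load_catalog()) {
  stopifnot(inherits(model, "hisplex_model"))
  missing_cols <- setdiff(catalog$probe, names(rows))
  if (length(missing_cols) > 0L) {
    stop("rows lack probe column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  mc1r_probes <- mc1r_subset(catalog)$probe
  pcols <- pvalue_columns()
  out <- data.frame(sampleid = rows$sampleid, stringsAsFactors = FALSE)
  for (col in pcols) out[[col]] <- NA_real_
  out$n_missing <- NA_integer_
  out$hair_available <- NA

  group_prefix <- c(eye = "p_eye_", hair_colour = "p_hair_",
                    hair_shade = "p_shade_", skin = "p_skin_")
  for (i in seq_len(nrow(rows))) {
    dosages <- stats::setNames(
      as.numeric(rows[i, catalog$probe]), catalog$probe)
    out$n_missing[i] <- sum(is.na(dosages))
    hair_ok <- !all(is.na(dosages[mc1r_probes]))
    out$hair_available[i] <- hair_ok
    for (g in names(MODEL_GROUPS)) {
      if (g %in% c("hair_colour", "hair_shade") && !hair_ok) next
      probes <- group_probes(model, g)
      if (length(probes) > 0L && all(is.na(dosages[probes]))) next  # undefined
      p <- group_pvalues(model$groups[[g]], dosages)
      out[i, paste0(group_prefix[[g]], names(p))] <- p
    }
  }
  out
}

#' Write a p-value table as CSV in the native dialect
#'
#' @param pvals output of [compute_pvalues()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_pvalues_csv <- function(pvals, path) {
  cols <- c("sampleid", pvalue_columns(), "n_missing", "hair_available")
  stopifnot(all(cols %in% names(pvals)))
  out <- pvals[, cols, drop = FALSE]
  num <- setdiff(cols, c("sampleid", "n_missing", "hair_available"))
  for (cc in num) {
    out[[cc]] <- ifelse(is.na(out[[cc]]), "NA", sprintf("%.15g", out[[cc]]))
  }
  lines <- c(paste(cols, collapse = ","),
             apply(out, 1L, function(r) paste(trimws(as.character(r)), collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}
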