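# Phenotype classification: 14 p-values -> categorical eye (3), hair (8)
# and skin (12) phenotypes, with an auditable rule trace.

#' Load and validate a classification rule set
#'
#' The hair and skin decision heuristics are data-driven: threshold
#' constants and the light-to-dark category orders live in a YAML rules file
#' (default `inst/extdata/rules_default.yaml`), so a user transcribing the
#' published manual's decision tree can replace the file without code
#' changes. Totality of the rule set (every valid p-value vector maps to
#' exactly one category per trait) is a load-time validation, never a
#' classify-time failure.
#'
#' @param path rules YAML; defaults to the shipped rule set.
#' @return A rules object (list), class `"hisplex_rules"`.
#' @export
load_rules <- function(path = NULL) {
  if (is.null(path)) path <- hisplex_extdata("rules_default.yaml")
  if (!file.exists(path)) stop("rules file not found: ", path, call. = FALSE)
  spec <- yaml::read_yaml(path)
  rules <- list(
    version = spec$ruleset %||% "unversioned",
    eye_categories = unlist(spec$eye$categories),
    hair_colour_categories = unlist(spec$hair$colour_categories),
    shade_categories = unlist(spec$hair$shade_categories),
    dark_shade_low = as.numeric(spec$hair$dark_shade_low),
    dark_shade_high = as.numeric(spec$hair$dark_shade_high),
    skin_base_categories = unlist(spec$skin$base_categories),
    modifier_ratio = as.numeric(spec$skin$modifier_ratio)
  )
  if (!identical(rules$eye_categories, MODEL_GROUPS$eye) ||
      !identical(rules$hair_colour_categories, MODEL_GROUPS$hair_colour) ||
      !identical(rules$shade_categories, MODEL_GROUPS$hair_shade) ||
      !identical(rules$skin_base_categories, MODEL_GROUPS$skin)) {
    stop("rule set category orders do not match the model groups", call. = FALSE)
  }
  with(rules, {
    if (!is.finite(dark_shade_low) || !is.finite(dark_shade_high) ||
        dark_shade_low < 0 || dark_shade_high > 1 ||
        dark_shade_low >= dark_shade_high) {
      stop("hair shade thresholds must satisfy 0 <= low < high <= 1",
           call. = FALSE)
    }
    if (!is.finite(modifier_ratio) || modifier_ratio <= 0 || modifier_ratio > 1) {
      stop("skin modifier_ratio must lie in (0, 1]", call. = FALSE)
    }
  })
  class(rules) <- "hisplex_rules"
  rules
}

# argmax with exact ties resolved to the DARKER category; `p` must be named
# in light-to-dark order. Encodes the darker-tone precedence of the
# classification scheme.
argmax_darker <- function(p) {
  idx <- which(p == max(p))
  names(p)[idx[length(idx)]]
}

#' Classify eye colour
#'
#' The eye call is the plain argmax of the three eye probabilities; exact
#' ties resolve to the darker category.
#'
#' @param p named numeric vector of the 3 eye probabilities in light-to-dark
#'   order (`blue`, `intermediate`, `brown`).
#' @return List with `category` and `rule_trace`.
#' @export
classify_eye <- function(p) {
  if (length(p) != 3L || any(is.na(p))) {
    stop("eye group undefined: need 3 non-missing probabilities", call. = FALSE)
  }
  names(p) <- MODEL_GROUPS$eye
  cat <- argmax_darker(p)
  list(category = cat, rule_trace = paste0("eye:argmax=", cat))
}

#' Classify hair colour and shade
#'
#' Red takes precedence whenever the red colour probability is the argmax of
#' the four hair-colour p-values. Otherwise the winning base colour (blond,
#' brown or black; ties to darker) is refined into the 8-way vocabulary by
#' the dark-shade probability against the rule set's two cut points. When
#' hair prediction is unavailable (all 11 MC1R markers missing) the call is
#' `"unavailable"`.
#'
#' @param p_colour named numeric vector of 4 hair-colour probabilities
#'   (`blond`, `brown`, `red`, `black`).
#' @param p_shade named numeric vector of 2 shade probabilities (`light`,
#'   `dark`).
#' @param available logical; `FALSE` when the system does not predict hair.
#' @param rules rule set from [load_rules()].
#' @return List with `category` and `rule_trace`.
#' @export
classify_hair <- function(p_colour, p_shade, available = TRUE,
                          rules = load_rules()) {
  if (!isTRUE(available)) {
    return(list(category = "unavailable", rule_trace = "hair:unavailable"))
  }
  if (length(p_colour) != 4L || any(is.na(p_colour)) ||
      length(p_shade) != 2L || any(is.na(p_shade))) {
    stop("hair groups undefined: need 4 colour and 2 shade probabilities",
         call. = FALSE)
  }
  names(p_colour) <- MODEL_GROUPS$hair_colour
  names(p_shade) <- MODEL_GROUPS$hair_shade
  trace <- character(0)
  # red precedence: red wins any tie for the colour argmax
  if (p_colour[["red"]] >= max(p_colour)) {
    return(list(category = "red", rule_trace = "hair:red"))
  }
  base <- argmax_darker(p_colour[c("blond", "brown", "black")])
  trace <- c(trace, paste0("hair:base=", base))
  pd <- p_shade[["dark"]]
  lo <- rules$dark_shade_low
  hi <- rules$dark_shade_high
  shade_bin <- if (pd < lo) "light" else if (pd < hi) "mid" else "dark"
  trace <- c(trace, paste0("hair:shade=", shade_bin))
  cat <- switch(base,
    blond = switch(shade_bin, light = "blonde",
                   mid = "dark-blonde/blonde", dark = "dark-blonde/brown"),
    brown = switch(shade_bin, light = "dark-blonde/brown",
                   mid = "brown", dark = "dark-brown/brown"),
    black = switch(shade_bin, light = "dark-brown/black",
                   mid = "dark-brown/black", dark = "black"))
  list(category = cat, rule_trace = paste(trace, collapse = ";"))
}

#' Classify skin tone
#'
#' The base tone is the argmax of the five skin probabilities (ties to
#' darker). A lighter/darker modifier attaches when an adjacent tone's
#' probability reaches `modifier_ratio` times the base tone's probability;
#' the darker modifier wins when both would fire, encoding the scheme's
#' darker-tone precedence. Modifiers are ratio-based, so they are invariant
#' under renormalisation of the five p-values.
#'
#' @param p named numeric vector of the 5 skin probabilities in
#'   light-to-dark order.
#' @param rules rule set from [load_rules()].
#' @return List with `category` (one of the 12-way vocabulary) and
#'   `rule_trace`.
#' @export
classify_skin <- function(p, rules = load_rules()) {
  if (length(p) != 5L || any(is.na(p))) {
    stop("skin group undefined: need 5 non-missing probabilities", call. = FALSE)
  }
  names(p) <- MODEL_GROUPS$skin
  base <- argmax_darker(p)
  bi <- match(base, MODEL_GROUPS$skin)
  trace <- paste0("skin:base=", base)
  darker_ok <- bi < 5L &&
    p[[bi + 1L]] >= rules$modifier_ratio * p[[bi]] && p[[bi + 1L]] > 0
  # the vocabulary has no "very pale/lighter" and no modifiers on dark-black
  lighter_ok <- bi > 1L && bi < 5L &&
    p[[bi - 1L]] >= rules$modifier_ratio * p[[bi]] && p[[bi - 1L]] > 0
  modifier <- if (darker_ok) "darker" else if (lighter_ok) "lighter" else "none"
  if (modifier != "none") trace <- c(trace, paste0("skin:mod=", modifier))
  label <- c("very_pale" = "very pale", "pale" = "pale",
             "intermediate" = "intermediate", "dark" = "dark",
             "dark_black" = "dark-black")[[base]]
  cat <- switch(modifier,
    none = label,
    darker = if (base == "dark") "dark/dark-black" else paste0(label, "/darker"),
    lighter = paste0(label, "/lighter"))
  list(category = cat, rule_trace = paste(trace, collapse = ";"))
}

read_pvalue_table <- function(path, dialect = c("native", "webtool")) {
  dialect <- match.arg(dialect)
  spec <- yaml::read_yaml(hisplex_extdata("pvalue_dialects.yaml"))[[dialect]]
  tab <- utils::read.csv(path, check.names = FALSE)
  expected <- c(spec$sample, unlist(spec$columns))
  missing_cols <- setdiff(expected, names(tab))
  if (length(missing_cols) > 0L) {
    stop("p-value table does not match the ", dialect, " dialect; missing: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  native <- yaml::read_yaml(hisplex_extdata("pvalue_dialects.yaml"))$native
  out <- data.frame(sampleid = as.character(tab[[spec$sample]]),
                    stringsAsFactors = FALSE)
  for (i in seq_along(native$columns)) {
    out[[native$columns[[i]]]] <- as.numeric(tab[[spec$columns[[i]]]])
  }
  out$n_missing <- if ("n_missing" %in% names(tab)) tab$n_missing else NA_integer_
  out$hair_available <- if ("hair_available" %in% names(tab)) {
    as.logical(tab$hair_available)
  } else {
    # a table without the flag (e.g. the web tool's download) signals
    # unavailability through missing hair p-values
    !is.na(out$p_hair_blond)
  }
  out
}

#' Classify all samples of a p-value table
#'
#' Accepts either the data frame produced by [compute_pvalues()] or a path
#' to a p-value CSV in the native dialect or the web tool's download dialect
#' (`dialect = "webtool"`). Undefined eye/skin groups yield the explicit
#' `"undefined"` marker; unavailable hair yields `"unavailable"`.
#'
#' @param pvals data frame or CSV path.
#' @param rules rule set from [load_rules()].
#' @param dialect p-value column dialect when `pvals` is a path.
#' @return Data frame: `sampleid`, `eye`, `hair`, `skin`, `rule_trace`.
#' @export
classify_all <- function(pvals, rules = load_rules(),
                         dialect = c("native", "webtool")) {
  if (is.character(pvals) && length(pvals) == 1L) {
    pvals <- read_pvalue_table(pvals, dialect)
  }
  n <- nrow(pvals)
  out <- data.frame(sampleid = pvals$sampleid,
                    eye = character(n), hair = character(n),
                    skin = character(n), rule_trace = character(n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    traces <- character(0)
    p_eye <- as.numeric(pvals[i, paste0("p_eye_", MODEL_GROUPS$eye)])
    if (any(is.na(p_eye))) {
      out$eye[i] <- "undefined"; traces <- c(traces, "eye:undefined")
    } else {
      r <- classify_eye(p_eye)
      out$eye[i] <- r$category; traces <- c(traces, r$rule_trace)
    }
    avail <- isTRUE(pvals$hair_available[i])
    p_col <- as.numeric(pvals[i, paste0("p_hair_", MODEL_GROUPS$hair_colour)])
    p_sh <- as.numeric(pvals[i, paste0("p_shade_", MODEL_GROUPS$hair_shade)])
    if (avail && (any(is.na(p_col)) || any(is.na(p_sh)))) {
      out$hair[i] <- "undefined"; traces <- c(traces, "hair:undefined")
    } else {
      r <- classify_hair(p_col, p_sh, available = avail, rules = rules)
      out$hair[i] <- r$category; traces <- c(traces, r$rule_trace)
    }
    p_skin <- as.numeric(pvals[i, paste0("p_skin_", MODEL_GROUPS$skin)])
    if (any(is.na(p_skin))) {
      out$skin[i] <- "undefined"; traces <- c(traces, "skin:undefined")
    } else {
      r <- classify_skin(p_skin, rules = rules)
      out$skin[i] <- r$category; traces <- c(traces, r$rule_trace)
    }
    out$rule_trace[i] <- paste(traces, collapse = ";")
  }
  out
}

#' Write phenotype calls as TSV
#'
#' @param calls data frame from [classify_all()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_phenotypes_tsv <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
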