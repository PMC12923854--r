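# Imputation target regions: per-marker slop, merge, minimum-length
# extension, BED output. Marker positions are 1-based internally; windows
# are 0-based half-open (BED convention) externally.

#' Build imputation target windows around the catalog markers
#'
#' Each marker contributes the interval `[pos - 1 - slop, pos + slop)`
#' clipped to its chromosome. Overlapping or book-ended intervals are
#' merged. Any merged window shorter than `min_len` (markers near telomeres
#' or centromeres) is extended away from the clipped end (or symmetrically
#' when no end was clipped) until it reaches `min_len` or exhausts the
#' chromosome; a chromosome shorter than `min_len` yields the whole
#' chromosome. Extension can create new overlaps, so merge and extend
#' iterate to a fixed point.
#'
#' @param markers catalog rows (needs `chrom`, `pos`).
#' @param lengths named vector of chromosome lengths ([load_chrom_lengths()]),
#'   in the same naming dialect as `markers`.
#' @param slop bp added on each side of a marker (default 2.5 Mb).
#' @param min_len minimum final window length (default 5 Mb).
#' @return Data frame `chrom`, `start`, `end` (0-based half-open), sorted,
#'   pairwise disjoint per chromosome, with attributes `slop` and `min_len`.
#' @export
build_windows <- function(markers, lengths, slop = 2.5e6, min_len = 5e6) {
  missing_chrom <- setdiff(unique(markers$chrom), names(lengths))
  if (length(missing_chrom) > 0L) {
    stop("marker chromosome(s) missing from length table: ",
         paste(missing_chrom, collapse = ", "), call. = FALSE)
  }
  out <- list()
  for (chrom in unique(markers$chrom)) {
    chr_len <- unname(lengths[[chrom]])
    pos <- markers$pos[markers$chrom == chrom]
    start <- pmax(0, pos - 1 - slop)
    end <- pmin(chr_len, pos + slop)
    iv <- merge_intervals(start, end)
    repeat {
      iv <- extend_short(iv, chr_len, min_len)
      merged <- merge_intervals(iv$start, iv$end)
      if (nrow(merged) == nrow(iv)) { iv <- merged; break }
      iv <- merged
    }
    iv$chrom <- chrom
    out[[chrom]] <- iv[, c("chrom", "start", "end")]
  }
  res <- do.call(rbind, out)
  res <- res[order(chrom_rank(res$chrom), res$start), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "slop") <- slop
  attr(res, "min_len") <- min_len
  res
}

# merge overlapping/book-ended half-open intervals on one chromosome
merge_intervals <- function(start, end) {
  ir <- IRanges::reduce(IRanges::IRanges(start = start + 1, end = end))
  data.frame(start = IRanges::start(ir) - 1, end = IRanges::end(ir))
}

extend_short <- function(iv, chr_len, min_len) {
  for (i in seq_len(nrow(iv))) {
    len <- iv$end[i] - iv$start[i]
    if (len >= min_len) next
    if (chr_len <= min_len) {          # chromosome itself too short
      iv$start[i] <- 0; iv$end[i] <- chr_len
      next
    }
    need <- min_len - len
    at_start <- iv$start[i] == 0
    at_end <- iv$end[i] == chr_len
    if (at_start && !at_end) {
      iv$end[i] <- min(chr_len, iv$end[i] + need)
    } else if (at_end && !at_start) {
      iv$start[i] <- max(0, iv$start[i] - need)
    } else {
      # unclipped (or doubly clipped, impossible when chr_len > min_len):
      # grow symmetrically, spilling the remainder to the other side
      half <- ceiling(need / 2)
      iv$start[i] <- iv$start[i] - half
      iv$end[i] <- iv$end[i] + (need - half)
      if (iv$start[i] < 0) { iv$end[i] <- iv$end[i] - iv$start[i]; iv$start[i] <- 0 }
      if (iv$end[i] > chr_len) {
        iv$start[i] <- max(0, iv$start[i] - (iv$end[i] - chr_len))
        iv$end[i] <- chr_len
      }
    }
  }
  iv
}

chrom_rank <- function(chrom) {
  plain <- normalize_chrom(chrom, "plain")
  num <- suppressWarnings(as.integer(plain))
  ifelse(is.na(num), 100L + as.integer(factor(plain)), num)
}

#' Write a window set as a 3-column BED file
#'
#' @param windows data frame from [build_windows()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(windows, path) {
  if (nrow(windows) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  lines <- sprintf("%s\t%d\t%d", windows$chrom,
                   as.integer(windows$start), as.integer(windows$end))
  writeLines(lines, path)
  invisible(path)
}

#' Read a 3-column BED file into a window set
#'
#' @param path BED path (0-based half-open, no header).
#' @return Data frame `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(0), start = numeric(0), end = numeric(0)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(chrom = vapply(parts, `[`, "", 1L),
             start = as.numeric(vapply(parts, `[`, "", 2L)),
             end = as.numeric(vapply(parts, `[`, "", 3L)),
             stringsAsFactors = FALSE)
}
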