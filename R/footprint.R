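## Footprint densitometry: per-base protection / hyperexposure percentages
## from paired free-DNA and complexed-DNA lane profiles, and replicate
## averaging. Strands are independent profiles and are never merged.

#' Construct a lane densitometry profile
#'
#' One gel lane's integrated per-base intensities, indexed by position within
#' the probed fragment (1-based, per strand).
#'
#' @param base_index Integer base positions, unique and increasing.
#' @param intensity Non-negative densitometry values, not all zero.
#' @param base Optional nucleotide letters.
#' @param strand `"top"` or `"bottom"`.
#' @return A data frame of class `"lane_profile"`.
#' @export
lane_profile <- function(base_index, intensity, base = NA_character_,
                         strand = c("top", "bottom")) {
  strand <- match.arg(strand)
  base_index <- as.integer(base_index)
  intensity <- as.numeric(intensity)
  if (length(base_index) != length(intensity) || !length(base_index))
    stop_bindpoly("base_index and intensity must be non-empty, equal length",
                  "bindpoly_invalid_input")
  if (anyDuplicated(base_index) || is.unsorted(base_index))
    stop_bindpoly("base_index must be unique and increasing",
                  "bindpoly_invalid_input")
  if (anyNA(intensity) || any(intensity < 0) || all(intensity == 0))
    stop_bindpoly("intensities must be >= 0 and not all zero",
                  "bindpoly_invalid_input")
  structure(data.frame(base_index = base_index, base = base,
                       strand = strand, intensity = intensity),
            class = c("lane_profile", "data.frame"))
}

check_profile_pair <- function(free, complexed) {
  for (p in list(free, complexed))
    if (!inherits(p, "lane_profile"))
      stop_bindpoly("inputs must be lane_profile objects",
                    "bindpoly_invalid_input")
  if (free$strand[1] != complexed$strand[1])
    stop_bindpoly("free and complexed profiles are from different strands",
                  "bindpoly_alignment_error")
  if (!identical(free$base_index, complexed$base_index))
    stop_bindpoly("free and complexed profiles cover different base indices",
                  "bindpoly_alignment_error")
}

#' Normalise a complexed lane against its free-DNA lane
#'
#' Gel lanes differ in loading and exposure, so the complexed lane is
#' rescaled before per-base comparison: the scale factor makes its total
#' intensity over the reference bases (default: all bases) match the free
#' lane. Bands known to be unaffected by binding can be supplied as
#' `reference` instead.
#'
#' @param free,complexed [lane_profile()] objects over the same strand and
#'   base indices.
#' @param reference Optional integer vector of `base_index` values to use as
#'   the normalisation reference.
#' @return A list with `free`, `complexed` (rescaled) and `scale`.
#' @export
normalize_profiles <- function(free, complexed, reference = NULL) {
  check_profile_pair(free, complexed)
  idx <- if (is.null(reference)) seq_len(nrow(free))
         else match(reference, free$base_index)
  if (anyNA(idx))
    stop_bindpoly("reference bases not present in the profiles",
                  "bindpoly_alignment_error")
  tot_free <- sum(free$intensity[idx])
  tot_cplx <- sum(complexed$intensity[idx])
  if (tot_free <= 0 || tot_cplx <= 0)
    stop_bindpoly("zero total reference intensity: cannot normalise",
                  "bindpoly_invalid_input")
  scale <- tot_free / tot_cplx
  complexed$intensity <- complexed$intensity * scale
  list(free = free, complexed = complexed, scale = scale)
}

#' Per-base protection / hyperexposure percentages
#'
#' For each base, the signed percentage change of the (normalised) complexed
#' lane against the free lane: `100 * (I_complex - I_free) / I_free`.
#' Negative values are protection (reduced reactivity under the bound
#' protein), positive values hyperexposure. Bases at or beyond the threshold
#' magnitude are classified `"protected"` / `"hyperexposed"`, the rest
#' `"unchanged"`. A base with zero free-lane intensity cannot be quantified
#' and is flagged, not dropped.
#'
#' @param free,complexed_scaled A normalised profile pair (see
#'   [normalize_profiles()]).
#' @param threshold Classification threshold in percent (default 20).
#' @return A data frame of class `"footprint_report"` with columns
#'   `base_index`, `base`, `strand`, `percent_change`, `classification`,
#'   `quantifiable`; the threshold is stored as an attribute.
#' @export
percent_change <- function(free, complexed_scaled, threshold = 20) {
  check_profile_pair(free, complexed_scaled)
  if (threshold <= 0)
    stop_bindpoly("threshold must be a positive percentage",
                  "bindpoly_invalid_input")
  quant <- free$intensity > 0
  pct <- rep(NA_real_, nrow(free))
  pct[quant] <- 100 * (complexed_scaled$intensity[quant] -
                       free$intensity[quant]) / free$intensity[quant]
  cls <- rep("unquantifiable", nrow(free))
  cls[quant] <- ifelse(pct[quant] <= -threshold, "protected",
                ifelse(pct[quant] >= threshold, "hyperexposed", "unchanged"))
  structure(data.frame(
    base_index = free$base_index, base = free$base, strand = free$strand,
    percent_change = pct, classification = cls, quantifiable = quant
  ), class = c("footprint_report", "data.frame"), threshold = threshold)
}

#' Average footprint reports across replicate gels
#'
#' Per-base arithmetic mean of the signed percent changes from at least two
#' independent sequencing gels, with the classification recomputed on the
#' mean at the common threshold.
#'
#' @param reports A list of `>= 2` [percent_change()] reports over the same
#'   bases and strand.
#' @return A `"footprint_report"` data frame of the per-base means.
#' @export
average_replicates <- function(reports) {
  if (!is.list(reports) || length(reports) < 2)
    stop_bindpoly("at least two replicate reports are required",
                  "bindpoly_invalid_input")
  if (!all(vapply(reports, inherits, logical(1), "footprint_report")))
    stop_bindpoly("all elements must be footprint_report objects",
                  "bindpoly_invalid_input")
  ref <- reports[[1]]
  for (r in reports[-1]) {
    if (!identical(r$base_index, ref$base_index) ||
        r$strand[1] != ref$strand[1])
      stop_bindpoly("replicate reports cover different bases or strands",
                    "bindpoly_alignment_error")
  }
  threshold <- attr(ref, "threshold")
  pct <- rowMeans(vapply(reports, function(r) r$percent_change,
                         numeric(nrow(ref))))
  quant <- !is.na(pct)
  cls <- rep("unquantifiable", nrow(ref))
  cls[quant] <- ifelse(pct[quant] <= -threshold, "protected",
                ifelse(pct[quant] >= threshold, "hyperexposed", "unchanged"))
  structure(data.frame(
    base_index = ref$base_index, base = ref$base, strand = ref$strand,
    percent_change = pct, classification = cls, quantifiable = quant
  ), class = c("footprint_report", "data.frame"), threshold = threshold)
}

#' @export
print.footprint_report <- function(x, ...) {
  cat(sprintf("Footprint report: %s strand, %d bases, threshold %g%%\n",
              x$strand[1], nrow(x), attr(x, "threshold")))
  hit <- x$classification %in% c("protected", "hyperexposed")
  if (any(hit)) {
    for (i in which(hit))
      cat(sprintf("  base %d%s: %+.1f%% (%s)\n", x$base_index[i],
                  if (!is.na(x$base[i])) paste0(" [", x$base[i], "]") else "",
                  x$percent_change[i], x$classification[i]))
  } else {
    cat("  no base beyond threshold\n")
  }
  if (any(!x$quantifiable))
    cat(sprintf("  unquantifiable bases (zero free-lane signal): %s\n",
                paste(x$base_index[!x$quantifiable], collapse = ", ")))
  invisible(x)
}

#' @export
plot.footprint_report <- function(x, ...) {
  thr <- attr(x, "threshold")
  col <- ifelse(x$classification == "protected", "#7570b3",
         ifelse(x$classification == "hyperexposed", "#d95f02", "grey60"))
  graphics::plot(x$base_index, x$percent_change, type = "h", col = col,
                 lwd = 3, xlab = "base index",
                 ylab = "% change vs free DNA", ...)
  graphics::abline(h = c(-thr, 0, thr), lty = c(3, 1, 3))
  invisible(x)
}
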