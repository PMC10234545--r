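# Column-sum profile of the scalogram (SCWS), its above-mean segmentation
# (SCWSS), and the seven wavelet features computed from the segments.

#' Column-sum wavelet profile (SCWS)
#'
#' Collapses a scalogram to one nonnegative value per base position by
#' summing coefficient magnitudes over the first `n_layers_sum` layers
#' (default 20): the per-position "power" profile from which segments and
#' features are derived.
#'
#' @param scalogram An `lnc_scalogram` from [morse_cwt()], or a numeric
#'   magnitude matrix (layers x positions).
#' @param n_layers_sum Number of leading layers to sum; defaults to the
#'   scalogram's own parameter (20) or all rows of a bare matrix.
#' @return Object of class `scws_profile`: list with `power` (numeric
#'   vector), `n_layers_sum`, `mean_power`.
#' @export
scws_profile <- function(scalogram, n_layers_sum = NULL) {
  if (inherits(scalogram, "lnc_scalogram")) {
    mag <- Mod(scalogram$coeffs)
    if (is.null(n_layers_sum)) n_layers_sum <- scalogram$params$n_layers_sum
  } else {
    mag <- abs(as.matrix(scalogram))
    if (is.null(n_layers_sum)) n_layers_sum <- nrow(mag)
  }
  n_layers_sum <- as.integer(n_layers_sum)
  if (n_layers_sum < 1L || n_layers_sum > nrow(mag)) {
    stop("n_layers_sum must be between 1 and the number of layers (",
         nrow(mag), ")")
  }
  power <- colSums(mag[seq_len(n_layers_sum), , drop = FALSE])
  structure(list(power = power, n_layers_sum = n_layers_sum,
                 mean_power = mean(power)),
            class = "scws_profile")
}

#' Corrected midpoint statistic of a segment
#'
#' For a segment spanning 0-based positions `[p_start, p_end)` the statistic
#' is \deqn{FMid = \frac{1}{2}\,\frac{P_{end}-P_{start}}{P_{end}}}
#' which is bounded in (0, 0.5] without needing any per-dataset
#' normalization: a segment spanning the whole prefix of the transcript
#' scores 0.5 and late, short segments score near 0.
#'
#' @param p_start 0-based inclusive start.
#' @param p_end 0-based exclusive end (segment end coordinate in the
#'   transcript, not the transcript length).
#' @return Value in (0, 0.5]. Vectorized.
#' @export
fmid <- function(p_start, p_end) {
  if (any(p_end <= p_start) || any(p_start < 0) || any(p_end <= 0)) {
    stop("require 0 <= p_start < p_end")
  }
  0.5 * (p_end - p_start) / p_end
}

#' Above-mean segmentation of an SCWS profile (SCWSS)
#'
#' Returns the maximal contiguous runs of positions whose power is strictly
#' greater than the profile mean, left to right.
#'
#' @param profile An `scws_profile` (or bare numeric vector).
#' @return A data.frame with one row per segment: `p_start` (0-based
#'   inclusive), `p_end` (0-based exclusive), `length`, `mean_power`
#'   (mean profile power over the run), `fmid`.
#' @export
segments_above_mean <- function(profile) {
  if (inherits(profile, "scws_profile")) {
    power <- profile$power
    mu <- profile$mean_power
  } else {
    power <- as.numeric(profile)
    mu <- mean(power)
  }
  if (length(power) == 0L) stop("empty profile")
  above <- power > mu
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  if (!any(keep)) {
    return(data.frame(p_start = integer(0), p_end = integer(0),
                      length = integer(0), mean_power = numeric(0),
                      fmid = numeric(0)))
  }
  s <- starts[keep]
  e <- ends[keep]
  data.frame(
    p_start = s - 1L,
    p_end = e,
    length = e - s + 1L,
    mean_power = vapply(seq_along(s),
                        function(i) mean(power[s[i]:e[i]]), numeric(1)),
    fmid = fmid(s - 1L, e)
  )
}

# mean with the empty-set-is-zero convention used throughout the features
.mean0 <- function(x) if (length(x) == 0L) 0 else mean(x)

#' Seven wavelet features from the segment set
#'
#' Computes, from the above-mean segments of an SCWS profile:
#' \describe{
#'   \item{Count}{number of segments ("fragments above average power").}
#'   \item{LenMean}{mean segment length.}
#'   \item{LenVar}{variance of segment lengths (population variance by
#'     default; see `variance_mode`).}
#'   \item{MidMean}{mean of the corrected midpoint statistic [fmid()].}
#'   \item{30Count}{number of segments that rank in the top third by length
#'     AND are longer than 30 bases.}
#'   \item{30PwMean}{mean power of those same segments.}
#'   \item{30LenCount}{mean length of all segments longer than 30 bases.}
#' }
#' The 30-base floor is the nucleotide length of the shortest known protein,
#' so sub-30 runs are treated as non-coding noise. The "top third" is the
#' first `ceiling(Count/3)` segments after ranking by length descending
#' (ties broken by earlier start); an alternative literal reading, keeping
#' segments whose length exceeds `Count/3`, is available via
#' `third_rule = "length_vs_count"`.
#'
#' @param segments Segment data.frame from [segments_above_mean()].
#' @param variance_mode `"population"` (default) or `"sample"`.
#' @param third_rule `"top_rank"` (default) or `"length_vs_count"`.
#' @return Named numeric vector of the seven features, all finite; all zero
#'   when there are no segments.
#' @export
wavelet_features <- function(segments,
                             variance_mode = c("population", "sample"),
                             third_rule = c("top_rank", "length_vs_count")) {
  variance_mode <- match.arg(variance_mode)
  third_rule <- match.arg(third_rule)
  n <- nrow(segments)
  if (n == 0L) {
    return(c(Count = 0, LenMean = 0, LenVar = 0, MidMean = 0,
             `30Count` = 0, `30PwMean` = 0, `30LenCount` = 0))
  }
  len <- segments$length
  lv <- if (n == 1L) 0 else if (variance_mode == "population") {
    mean((len - mean(len))^2)
  } else {
    stats::var(len)
  }
  ord <- order(-len, segments$p_start)
  top <- segments[ord[seq_len(ceiling(n / 3))], , drop = FALSE]
  sel <- if (third_rule == "top_rank") {
    top[top$length > 30, , drop = FALSE]
  } else {
    segments[segments$length > n / 3 & segments$length > 30, , drop = FALSE]
  }
  c(Count = n,
    LenMean = mean(len),
    LenVar = lv,
    MidMean = mean(segments$fmid),
    `30Count` = nrow(sel),
    `30PwMean` = .mean0(sel$mean_power),
    `30LenCount` = .mean0(len[len > 30]))
}
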