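#' Arcsinh transformation for mass cytometry intensities
#'
#' Elementwise `asinh(x / cofactor)`; strictly monotone. Cofactor 5 is the
#' CyTOF convention.
#'
#' @param x Numeric vector, matrix or data frame of raw intensities.
#' @param cofactor Positive scaling constant.
#' @return Transformed object of the same shape.
#' @examples
#' arcsinh_transform(5)        # asinh(1) = log(1 + sqrt(2))
#' @export
arcsinh_transform <- function(x, cofactor = 5) {
  if (!is.numeric(cofactor) || length(cofactor) != 1L || !is.finite(cofactor) ||
      cofactor <= 0) {
    stop_cb("cofactor must be a positive number",
            class = "cytobarcode_parameter_error")
  }
  if (is.data.frame(x)) {
    return(dplyr::mutate(x, dplyr::across(dplyr::everything(), ~ asinh(.x / cofactor))))
  }
  asinh(x / cofactor)
}

#' Event-cleanup gate settings
#'
#' Cell identification uses the DNA intercalator (Rh) intensity and the event
#' length parameter; dead-cell removal uses the palladium viability channel.
#' Rh and Pd thresholds are in arcsinh-transformed units (scale-stable);
#' event length is compared raw. The defaults are conventions tuned to the
#' simulator's stated world, not measured instrument values, and should be
#' set per experiment.
#'
#' @param rh_channel,pd_channel,length_channel Channel references (short name
#'   or label).
#' @param rh_min Minimum transformed Rh intensity for a cell event.
#' @param length_range `c(lo, hi)` raw event-length window.
#' @param pd_max Maximum transformed Pd intensity for a live event.
#' @param cofactor Arcsinh cofactor applied before thresholding Rh/Pd.
#' @return A `gate_config` list.
#' @export
gate_config <- function(rh_channel = "Rh103Di", rh_min = 2,
                        length_channel = "Event_length",
                        length_range = c(5, 75),
                        pd_channel = "Pd106Di", pd_max = 2.75,
                        cofactor = 5) {
  if (length(length_range) != 2L || anyNA(length_range) ||
      length_range[1] > length_range[2]) {
    stop_cb("length_range must be c(lo, hi) with lo <= hi",
            class = "cytobarcode_parameter_error")
  }
  structure(list(rh_channel = rh_channel, rh_min = rh_min,
                 length_channel = length_channel,
                 length_range = as.numeric(length_range),
                 pd_channel = pd_channel, pd_max = pd_max,
                 cofactor = cofactor),
            class = "gate_config")
}

#' Identify cell events by DNA signal and event length
#'
#' Keeps events with transformed Rh >= `rh_min` and event length inside
#' `length_range`. Returns the subset together with the kept row indices for
#' traceability.
#'
#' @param events An [fcs_events] table.
#' @param gate A [gate_config].
#' @return List with `events` (subset, attributes preserved) and `kept`
#'   (integer indices into the input).
#' @export
gate_cells <- function(events, gate = gate_config()) {
  rh <- events[[match_channel(events, gate$rh_channel)]]
  len <- events[[match_channel(events, gate$length_channel)]]
  keep <- arcsinh_transform(rh, gate$cofactor) >= gate$rh_min &
    len >= gate$length_range[1] & len <= gate$length_range[2]
  kept <- which(keep)
  list(events = events_subset(events, kept), kept = kept)
}

#' Remove dead events by palladium viability signal
#'
#' Keeps events with transformed Pd <= `pd_max`.
#'
#' @inheritParams gate_cells
#' @return List with `events` and `kept` as in [gate_cells()].
#' @export
gate_live <- function(events, gate = gate_config()) {
  pd <- events[[match_channel(events, gate$pd_channel)]]
  kept <- which(arcsinh_transform(pd, gate$cofactor) <= gate$pd_max)
  list(events = events_subset(events, kept), kept = kept)
}

#' Percentile rescaling of barcode channels to [0, 1]
#'
#' Per column, subtracts the `lo_pct` percentile, divides by the
#' `hi_pct - lo_pct` percentile span, and clamps to `[0, 1]`. Percentile
#' endpoints (1st/99th by default) are used instead of min/max for outlier
#' robustness. A constant column cannot be rescaled and is set to all zeros
#' with a warning. This normalization is what puts the separation score on a
#' common `[0, 1]` scale across channels.
#'
#' @param transformed Events x channels numeric matrix or data frame of
#'   (typically arcsinh-transformed) barcode intensities.
#' @param lo_pct,hi_pct Percentiles in `[0, 100]`, `lo_pct < hi_pct`.
#' @return Numeric matrix with values in `[0, 1]`, same dimnames.
#' @export
rescale_barcode_channels <- function(transformed, lo_pct = 1, hi_pct = 99) {
  if (!(lo_pct >= 0 && lo_pct < hi_pct && hi_pct <= 100)) {
    stop_cb("need 0 <= lo_pct < hi_pct <= 100",
            class = "cytobarcode_parameter_error")
  }
  m <- as.matrix(as.data.frame(transformed))
  if (nrow(m) < 2L) {
    stop_cb("rescaling needs at least 2 events",
            class = "cytobarcode_insufficient_data_error")
  }
  out <- m
  for (j in seq_len(ncol(m))) {
    q <- quantile(m[, j], probs = c(lo_pct, hi_pct) / 100, names = FALSE, type = 7)
    if (q[2] - q[1] <= 0) {
      rlang::warn(sprintf("channel %s is constant over the rescale window; set to 0",
                          colnames(m)[j] %||% as.character(j)))
      out[, j] <- 0
    } else {
      out[, j] <- pmin(1, pmax(0, (m[, j] - q[1]) / (q[2] - q[1])))
    }
  }
  out
}
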