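#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble is_tibble
#' @import dplyr
#' @importFrom stats rlnorm rnorm rbinom quantile median setNames
#' @importFrom graphics hist
#' @importFrom utils head tail
NULL

stop_cb <- function(msg, class, ...) {
  rlang::abort(msg, class = c(class, "cytobarcode_error"), ...)
}

#' Resolve a channel reference against an event table
#'
#' Channels are matched by column (short) name first, exactly and then
#' case-insensitively, and finally against the channel `label` stored in the
#' table's channel metadata. Ambiguous matches are errors.
#'
#' @param events An `fcs_events` table (or any data frame of channels).
#' @param ref A single channel reference (short name or label).
#' @return The matching column index.
#' @keywords internal
match_channel <- function(events, ref) {
  stopifnot(length(ref) == 1L, is.character(ref))
  nms <- names(events)
  hit <- which(nms == ref)
  if (length(hit) == 0L) hit <- which(tolower(nms) == tolower(ref))
  if (length(hit) == 0L) {
    info <- attr(events, "channel_info")
    if (!is.null(info) && "label" %in% names(info)) {
      lab <- which(tolower(info$label) == tolower(ref))
      if (length(lab) > 0L) hit <- match(info$short_name[lab], nms)
    }
  }
  if (length(hit) == 0L) {
    stop_cb(sprintf("channel '%s' not found (have: %s)", ref,
                    paste(nms, collapse = ", ")),
            class = "cytobarcode_channel_error")
  }
  if (length(hit) > 1L) {
    stop_cb(sprintf("channel reference '%s' is ambiguous", ref),
            class = "cytobarcode_channel_error")
  }
  hit
}

# Row-subset an fcs_events table, preserving channel metadata and class.
events_subset <- function(x, idx) {
  out <- dplyr::slice(tibble::as_tibble(unclass_events(x)), idx)
  restore_events(out, x)
}

unclass_events <- function(x) {
  class(x) <- setdiff(class(x), "fcs_events")
  x
}

restore_events <- function(out, template) {
  attr(out, "channel_info") <- attr(template, "channel_info")
  attr(out, "metadata") <- attr(template, "metadata")
  class(out) <- c("fcs_events", class(out))
  out
}
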