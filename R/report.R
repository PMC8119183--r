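#' Yield and QC summary of a debarcoded batch
#'
#' Summarizes how many events survived each stage and how the assigned events
#' distribute over barcodes. The capture rate is the fraction of live gated
#' cells successfully assigned to a barcode (the "% of all cells captured"
#' statistic of a 10-plex validation run); per-sample fractions over assigned
#' events are the per-barcode distribution view, which for an even 10-plex
#' should sit near 10% per barcode.
#'
#' @param assignment A final (thresholded or gated) `debarcode_assignment`.
#' @param total_events Event count before any gating; defaults to
#'   `gated_cells`.
#' @param gated_cells Events surviving the cell-identification gate; defaults
#'   to `live_cells`.
#' @param live_cells Events surviving the viability gate (the capture-rate
#'   denominator); defaults to the assignment length.
#' @param histogram_binwidth Separation histogram bin width over `[0, 1]`.
#' @return A `yield_report` object (list) with counts, `capture_rate`,
#'   `per_sample` tibble (one row per scheme sample plus `unassigned`) and a
#'   `separation_histogram` tibble.
#' @export
compute_yield <- function(assignment, total_events = NULL, gated_cells = NULL,
                          live_cells = NULL, histogram_binwidth = 0.02) {
  live_cells <- live_cells %||% nrow(assignment)
  gated_cells <- gated_cells %||% live_cells
  total_events <- total_events %||% gated_cells
  scheme <- attr(assignment, "scheme")
  samples <- if (!is.null(scheme)) scheme$sample else
    sort(unique(assignment$sample[!is.na(assignment$sample)]))
  assigned <- sum(!is.na(assignment$sample))
  empty <- live_cells == 0L

  counts <- table(factor(assignment$sample, levels = samples))
  per_sample <- tibble::tibble(
    sample = c(samples, "unassigned"),
    count = c(as.integer(counts), nrow(assignment) - assigned),
    fraction_of_assigned = if (assigned > 0) {
      c(as.integer(counts) / assigned, NA_real_)
    } else rep(NA_real_, length(samples) + 1L),
    fraction_of_live = if (!empty) {
      c(as.integer(counts), nrow(assignment) - assigned) / live_cells
    } else rep(NA_real_, length(samples) + 1L))

  breaks <- seq(0, 1, by = histogram_binwidth)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  h <- hist(pmin(assignment$separation, 1), breaks = breaks, plot = FALSE)
  structure(list(
    total_events = as.integer(total_events),
    gated_cells = as.integer(gated_cells),
    live_cells = as.integer(live_cells),
    assigned = as.integer(assigned),
    capture_rate = if (empty) NA_real_ else assigned / live_cells,
    empty = empty,
    per_sample = per_sample,
    separation_histogram = tibble::tibble(bin_lo = head(h$breaks, -1L),
                                          bin_hi = tail(h$breaks, -1L),
                                          count = h$counts)),
    class = "yield_report")
}

#' Score a debarcoding against simulator ground truth
#'
#' Builds the truth-by-call confusion table (rows: each sample plus
#' `doublet`; columns: each sample plus `unassigned`) and two headline
#' fractions: `singlet_accuracy`, the fraction of *assigned* singlets whose
#' call matches their true sample, and `doublet_rejection`, the fraction of
#' true doublets left unassigned. With no assigned singlets the accuracy is
#' reported as `NA` (not applicable).
#'
#' @param assignment A `debarcode_assignment`.
#' @param truth Ground-truth tibble from [simulate_barcoded_events()] (needs
#'   `true_sample`; `is_dead` is carried through when present).
#' @return A `concordance_report` object.
#' @export
score_concordance <- function(assignment, truth) {
  if (nrow(assignment) != nrow(truth)) {
    stop_cb(sprintf("assignment has %d events but truth has %d",
                    nrow(assignment), nrow(truth)),
            class = "cytobarcode_input_error")
  }
  scheme <- attr(assignment, "scheme")
  samples <- if (!is.null(scheme)) scheme$sample else
    sort(setdiff(unique(truth$true_sample), DOUBLET))
  truth_f <- factor(truth$true_sample, levels = c(samples, DOUBLET))
  call_f <- factor(ifelse(is.na(assignment$sample), "unassigned",
                          assignment$sample),
                   levels = c(samples, "unassigned"))
  confusion <- table(truth = truth_f, call = call_f)

  is_singlet <- truth$true_sample != DOUBLET
  asg_singlet <- is_singlet & !is.na(assignment$sample)
  singlet_accuracy <- if (any(asg_singlet)) {
    mean(assignment$sample[asg_singlet] == truth$true_sample[asg_singlet])
  } else NA_real_
  n_doub <- sum(!is_singlet)
  doublet_rejection <- if (n_doub > 0) {
    mean(is.na(assignment$sample[!is_singlet]))
  } else NA_real_
  structure(list(singlet_accuracy = singlet_accuracy,
                 doublet_rejection = doublet_rejection,
                 n_singlets = sum(is_singlet),
                 n_doublets = n_doub,
                 confusion = confusion),
            class = "concordance_report")
}

#' Render a machine- and human-readable debarcoding report
#'
#' @param yield A `yield_report`.
#' @param concordance Optional `concordance_report`.
#' @param path Optional file to write the JSON to.
#' @return The JSON string, invisibly; the human-readable table is printed.
#' @export
render_report <- function(yield, concordance = NULL, path = NULL) {
  payload <- list(
    schema_version = "1.0",
    total_events = yield$total_events,
    gated_cells = yield$gated_cells,
    live_cells = yield$live_cells,
    assigned = yield$assigned,
    capture_rate = yield$capture_rate,
    per_sample = yield$per_sample,
    separation_histogram = yield$separation_histogram)
  if (!is.null(concordance)) {
    cm <- as.data.frame.matrix(concordance$confusion)
    payload$concordance <- list(
      singlet_accuracy = concordance$singlet_accuracy,
      doublet_rejection = concordance$doublet_rejection,
      confusion = cbind(truth = rownames(cm), tibble::as_tibble(cm)))
  }
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           na = "null", pretty = TRUE)
  if (!is.null(path)) writeLines(json, path)
  print_yield_table(yield, concordance)
  invisible(as.character(json))
}

print_yield_table <- function(yield, concordance = NULL) {
  cat(sprintf("events: %d total, %d gated cells, %d live\n",
              yield$total_events, yield$gated_cells, yield$live_cells))
  if (yield$empty) {
    cat("no live cells: empty report\n")
    return(invisible(NULL))
  }
  cat(sprintf("assigned: %d of %d live cells (capture rate %.2f%%)\n",
              yield$assigned, yield$live_cells, 100 * yield$capture_rate))
  ps <- yield$per_sample
  for (i in seq_len(nrow(ps))) {
    fr <- ps$fraction_of_assigned[i]
    cat(sprintf("  %-12s %8d  %s\n", ps$sample[i], ps$count[i],
                if (is.na(fr)) "" else sprintf("%5.2f%% of assigned", 100 * fr)))
  }
  if (!is.null(concordance)) {
    acc <- concordance$singlet_accuracy
    rej <- concordance$doublet_rejection
    cat(sprintf("concordance: singlet accuracy %s, doublet rejection %s\n",
                if (is.na(acc)) "n/a" else sprintf("%.2f%%", 100 * acc),
                if (is.na(rej)) "n/a" else sprintf("%.2f%%", 100 * rej)))
  }
  invisible(NULL)
}

#' @export
print.yield_report <- function(x, ...) {
  print_yield_table(x)
  invisible(x)
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("<concordance_report> singlet accuracy: %s; doublet rejection: %s\n",
              if (is.na(x$singlet_accuracy)) "n/a" else sprintf("%.4f", x$singlet_accuracy),
              if (is.na(x$doublet_rejection)) "n/a" else sprintf("%.4f", x$doublet_rejection)))
  print(x$confusion)
  invisible(x)
}

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy and glance methods for reports
#'
#' `tidy()` on a `yield_report` returns the per-sample table;
#' `glance()` returns a one-row summary. On a `concordance_report`, `tidy()`
#' returns the confusion table in long form and `glance()` the two headline
#' fractions.
#'
#' @param x A `yield_report` or `concordance_report`.
#' @param ... Unused.
#' @name report-tidiers
NULL

#' @rdname report-tidiers
#' @export
tidy.yield_report <- function(x, ...) x$per_sample

#' @rdname report-tidiers
#' @export
glance.yield_report <- function(x, ...) {
  tibble::tibble(total_events = x$total_events, gated_cells = x$gated_cells,
                 live_cells = x$live_cells, assigned = x$assigned,
                 capture_rate = x$capture_rate)
}

#' @rdname report-tidiers
#' @export
tidy.concordance_report <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x$confusion, responseName = "count"))
}

#' @rdname report-tidiers
#' @export
glance.concordance_report <- function(x, ...) {
  tibble::tibble(singlet_accuracy = x$singlet_accuracy,
                 doublet_rejection = x$doublet_rejection,
                 n_singlets = x$n_singlets, n_doublets = x$n_doublets)
}

#' Plot the per-barcode distribution of a yield report
#'
#' Bar chart of each barcode's share of assigned events -- the standard view
#' for judging whether a multiplexed batch debarcodes evenly.
#'
#' @param object A `yield_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.yield_report <- function(object, ...) {
  df <- dplyr::filter(object$per_sample, .data$sample != "unassigned")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$fraction_of_assigned)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = NULL, y = "share of assigned events",
                  title = "Per-barcode distribution of assigned events") +
    ggplot2::theme_minimal()
}

#' Plot the separation-score histogram of an assignment
#'
#' @param object A `debarcode_assignment`.
#' @param binwidth Histogram bin width.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.debarcode_assignment <- function(object, binwidth = 0.02, ...) {
  df <- tibble::tibble(separation = object$separation,
                       assigned = !is.na(object$sample))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$separation, fill = .data$assigned)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0) +
    ggplot2::labs(x = "separation score", y = "events") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
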