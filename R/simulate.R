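#' Simulation settings for synthetic barcoded batches
#'
#' The signal model is the standard lognormal stain-intensity model: within a
#' sample, a barcode-positive channel is LogNormal(log(pos_median), log_cv)
#' and a barcode-negative channel LogNormal(log(neg_median), log_cv)
#' (`neg_median = 0` gives exact zeros). Doublets are the channelwise sum of
#' two independent singlets from distinct samples (ion clouds add). Dead
#' events keep their sample label, with the palladium viability channel drawn
#' from the dead distribution; rhodium (DNA) and event length are drawn for
#' every event, with doublets getting longer, wider event-length pulses.
#'
#' @param events_per_sample Singlets simulated per sample.
#' @param pos_median,neg_median Raw-intensity medians of barcode-positive /
#'   -negative channels (`pos_median > neg_median >= 0`).
#' @param log_cv Lognormal spread (sd of natural-log intensity).
#' @param doublet_rate Target fraction of all events that are doublets, in
#'   `[0, 1)`.
#' @param dead_rate Fraction of singlets that are dead, in `[0, 1)`.
#' @param pd_dead_median,pd_live_median Viability (Pd) channel medians for
#'   dead and live events.
#' @param rh_cell_median DNA (Rh) channel median for cell events.
#' @param length_mean,length_sd Event-length pulse for singlets.
#' @param doublet_length_factor,doublet_length_sd Event-length pulse scaling
#'   for doublets.
#' @param seed Integer seed; all randomness flows from one generator.
#' @return A `sim_config` list.
#' @export
sim_config <- function(events_per_sample = 1000,
                       pos_median = 200, neg_median = 2, log_cv = 0.5,
                       doublet_rate = 0.05, dead_rate = 0.02,
                       pd_dead_median = 250, pd_live_median = 5,
                       rh_cell_median = 150,
                       length_mean = 30, length_sd = 3,
                       doublet_length_factor = 1.5, doublet_length_sd = 6,
                       seed = NULL) {
  cfg <- list(events_per_sample = as.integer(events_per_sample),
              pos_median = pos_median, neg_median = neg_median,
              log_cv = log_cv, doublet_rate = doublet_rate,
              dead_rate = dead_rate,
              pd_dead_median = pd_dead_median, pd_live_median = pd_live_median,
              rh_cell_median = rh_cell_median,
              length_mean = length_mean, length_sd = length_sd,
              doublet_length_factor = doublet_length_factor,
              doublet_length_sd = doublet_length_sd,
              seed = if (is.null(seed)) NULL else as.integer(seed))
  bad <- function(msg) stop_cb(msg, class = "cytobarcode_parameter_error")
  if (cfg$events_per_sample < 0L) bad("events_per_sample must be >= 0")
  if (!(cfg$pos_median > cfg$neg_median && cfg$neg_median >= 0)) {
    bad("need pos_median > neg_median >= 0")
  }
  if (cfg$log_cv < 0) bad("log_cv must be >= 0")
  if (cfg$doublet_rate < 0 || cfg$doublet_rate >= 1) bad("doublet_rate must be in [0, 1)")
  if (cfg$dead_rate < 0 || cfg$dead_rate >= 1) bad("dead_rate must be in [0, 1)")
  structure(cfg, class = "sim_config")
}

#' Sentinel label used for doublet events in ground truth
#' @export
DOUBLET <- "doublet"

# LogNormal(log(median), sdlog) draw with an exact-zero branch for median 0
rln <- function(n, med, sdlog) {
  if (med <= 0) return(rep(0, n))
  if (sdlog <= 0) return(rep(med, n))
  rlnorm(n, meanlog = log(med), sdlog = sdlog)
}

#' Simulate a barcoded CyTOF batch with ground truth
#'
#' Generates `S * events_per_sample` singlets plus doublets such that the
#' realized doublet fraction of all events equals `doublet_rate`, shuffles
#' acquisition order, and returns the event table alongside a per-event
#' ground-truth tibble so downstream debarcoding and QC can be scored.
#'
#' @param scheme A [barcode_scheme].
#' @param config A [sim_config].
#' @return A list with `events` (an [fcs_events] table whose channels are the
#'   scheme's barcode channels plus `Rh103Di`, `Pd106Di` and `Event_length`)
#'   and `truth` (tibble with `event`, `true_sample` -- a sample name or
#'   [DOUBLET] -- and `is_dead`).
#' @examples
#' sch <- generate_complete_scheme(k = 3)
#' sim <- simulate_barcoded_events(sch, sim_config(events_per_sample = 50, seed = 1))
#' @export
simulate_barcoded_events <- function(scheme, config = sim_config()) {
  if (!inherits(scheme, "barcode_scheme")) {
    stop_cb("scheme must be a barcode_scheme", class = "cytobarcode_parameter_error")
  }
  if (!inherits(config, "sim_config")) {
    stop_cb("config must be built with sim_config()", class = "cytobarcode_parameter_error")
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  key <- scheme_key_matrix(scheme)
  S <- nrow(key)
  B <- ncol(key)
  n_per <- config$events_per_sample
  n_sing <- S * n_per
  # spec'd as round(doublet_rate x total events); solving with total =
  # singlets + doublets gives the realized doublet share = doublet_rate
  n_doub <- round(config$doublet_rate / (1 - config$doublet_rate) * n_sing)
  if (n_sing == 0L) n_doub <- 0L

  draw_singlet_barcodes <- function(sample_idx) {
    out <- matrix(0, nrow = length(sample_idx), ncol = B)
    for (j in seq_len(B)) {
      pos <- key[sample_idx, j] == 1L
      out[pos, j] <- rln(sum(pos), config$pos_median, config$log_cv)
      out[!pos, j] <- rln(sum(!pos), config$neg_median, config$log_cv)
    }
    out
  }

  sing_sample <- rep(seq_len(S), each = n_per)
  bc <- draw_singlet_barcodes(sing_sample)
  is_dead <- rbinom(n_sing, 1L, config$dead_rate) == 1L
  pd <- numeric(n_sing)
  pd[is_dead] <- rln(sum(is_dead), config$pd_dead_median, config$log_cv)
  pd[!is_dead] <- rln(sum(!is_dead), config$pd_live_median, config$log_cv)
  rh <- rln(n_sing, config$rh_cell_median, config$log_cv)
  len <- pmax(0, rnorm(n_sing, config$length_mean, config$length_sd))

  if (n_doub > 0L) {
    a <- sample.int(S, n_doub, replace = TRUE)
    shift <- sample.int(S - 1L, n_doub, replace = TRUE)
    b <- ((a - 1L + shift) %% S) + 1L          # uniform over samples != a
    bc_d <- draw_singlet_barcodes(a) + draw_singlet_barcodes(b)
    pd_d <- rln(n_doub, config$pd_live_median, config$log_cv) +
      rln(n_doub, config$pd_live_median, config$log_cv)
    rh_d <- rln(n_doub, config$rh_cell_median, config$log_cv) +
      rln(n_doub, config$rh_cell_median, config$log_cv)
    len_d <- pmax(0, rnorm(n_doub,
                           config$length_mean * config$doublet_length_factor,
                           config$doublet_length_sd))
    bc <- rbind(bc, bc_d)
    pd <- c(pd, pd_d)
    rh <- c(rh, rh_d)
    len <- c(len, len_d)
    truth_sample <- c(scheme$sample[sing_sample], rep(DOUBLET, n_doub))
    is_dead <- c(is_dead, rep(FALSE, n_doub))
  } else {
    truth_sample <- scheme$sample[sing_sample]
  }

  n_tot <- n_sing + n_doub
  ord <- if (n_tot > 0L) sample.int(n_tot) else integer(0)
  mat <- cbind(bc, rh, pd, len)[ord, , drop = FALSE]

  ch <- scheme_channels(scheme)
  info <- tibble::tibble(
    short_name = c(isotope_short_name(ch), "Rh103Di", "Pd106Di", "Event_length"),
    label = c(ch, "103Rh_DNA", "106Pd_viability", "Event_length"),
    mass = c(parse_mass(ch), 103L, 106L, NA_integer_))
  colnames(mat) <- info$short_name
  events <- fcs_events(mat, channel_info = info,
                       metadata = list(SIM = "cytobarcode",
                                       SIMSEED = as.character(config$seed %||% NA)))
  truth <- tibble::tibble(event = seq_len(n_tot),
                          true_sample = truth_sample[ord],
                          is_dead = is_dead[ord])
  list(events = events, truth = truth)
}

# "112Cd" -> "Cd112Di"; names already in short form pass through
isotope_short_name <- function(x) {
  g <- regmatches(x, regexec("^([0-9]{2,3})([A-Za-z]+)$", x))
  vapply(seq_along(x), function(i) {
    if (length(g[[i]]) == 3L) paste0(g[[i]][3], g[[i]][2], "Di") else x[i]
  }, "")
}
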