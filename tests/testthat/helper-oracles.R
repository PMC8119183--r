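# Independent oracles and small fixtures shared across test files.

# Brute-force key scorer: per-event loop over every key, computing
# min(positives) - max(negatives) directly. Deliberately written without any
# package internals so it can arbitrate assign_events().
brute_force_assign <- function(rescaled, key, sample_names) {
  n <- nrow(rescaled)
  out_sample <- character(n)
  out_sep <- numeric(n)
  for (e in seq_len(n)) {
    v <- rescaled[e, ]
    sc <- vapply(seq_len(nrow(key)), function(s) {
      min(v[key[s, ] == 1]) - max(v[key[s, ] == 0])
    }, 0)
    best <- max(sc)
    winners <- which(sc == best)
    if (length(winners) > 1L) {
      out_sample[e] <- NA_character_
      out_sep[e] <- 0
    } else {
      out_sample[e] <- sample_names[winners]
      out_sep[e] <- max(best, 0)
    }
  }
  list(sample = out_sample, separation = out_sep)
}

# Top-k rule: assign to the key whose positive set is the k highest channels;
# separation is the gap between the k-th and (k+1)-th highest values. Only
# meaningful for complete constant-weight schemes.
top_k_assign <- function(rescaled, key, sample_names, k) {
  n <- nrow(rescaled)
  keystr <- apply(key, 1L, paste, collapse = "")
  out_sample <- character(n)
  out_sep <- numeric(n)
  for (e in seq_len(n)) {
    v <- rescaled[e, ]
    ord <- order(v, decreasing = TRUE)
    sep <- v[ord[k]] - v[ord[k + 1L]]
    if (sep <= 0) {              # tie at the k / k+1 boundary: ambiguous
      out_sample[e] <- NA_character_
      out_sep[e] <- 0
    } else {
      pos <- rep(0L, ncol(key))
      pos[ord[seq_len(k)]] <- 1L
      out_sample[e] <- sample_names[match(paste(pos, collapse = ""), keystr)]
      out_sep[e] <- sep
    }
  }
  list(sample = out_sample, separation = out_sep)
}

# default 10-plex used throughout
scheme10 <- generate_complete_scheme(k = 3)

quick_sim <- function(events_per_sample = 200, seed = 11, ...) {
  simulate_barcoded_events(scheme10,
                           sim_config(events_per_sample = events_per_sample,
                                      seed = seed, ...))
}

# random nonnegative event table for I/O tests
random_events <- function(n = 100, p = 4, seed = 1) {
  set.seed(seed)
  m <- matrix(rexp(n * p, rate = 1 / 100), nrow = n)
  colnames(m) <- sprintf("Ch%d", seq_len(p))
  fcs_events(m)
}
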