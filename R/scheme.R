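#' Combinatorial k-of-n barcode schemes
#'
#' A barcode scheme is a binary key matrix with one row per sample and one
#' column per barcode channel; every key has exactly `k` positive channels
#' (constant weight). Distinct constant-weight keys differ in at least two
#' positions, which is what makes cell doublets -- whose barcode signal is the
#' union of two keys -- unassignable rather than silently miscalled.
#'
#' The scheme is stored as a tibble with a `sample` column followed by one
#' integer 0/1 column per channel, plus attributes `k` and `channels`.
#'
#' @name barcode_scheme
NULL

new_barcode_scheme <- function(key, channel_ids, sample_names, k) {
  key <- as.matrix(key)
  storage.mode(key) <- "integer"
  out <- tibble::tibble(sample = as.character(sample_names))
  for (j in seq_along(channel_ids)) out[[channel_ids[j]]] <- key[, j]
  attr(out, "k") <- as.integer(k)
  attr(out, "channels") <- as.character(channel_ids)
  class(out) <- c("barcode_scheme", class(out))
  out
}

#' Default barcode channel labels
#'
#' The five cadmium/indium isotopes used for CD29/CD98/CD45 live-cell
#' barcoding, in ascending mass order.
#'
#' @return Character vector of channel labels.
#' @export
default_barcode_channels <- function() {
  c("112Cd", "113In", "114Cd", "115In", "116Cd")
}

#' Generate the complete k-of-n barcode scheme
#'
#' Enumerates all `choose(B, k)` constant-weight-`k` binary keys over `B`
#' barcode channels, in lexicographic order of the positive-channel index
#' sets. Five channels with `k = 3` give the 10-plex design; six channels
#' give a 20-plex.
#'
#' @param channel_ids Ordered character vector of barcode channel labels.
#' @param k Number of positive channels per key (`1 <= k <= length(channel_ids)`).
#' @param sample_names Optional sample labels; default `"BC01"..."BCnn"`.
#' @return A [barcode_scheme] tibble with `choose(B, k)` rows.
#' @examples
#' generate_complete_scheme(default_barcode_channels(), k = 3)
#' @export
generate_complete_scheme <- function(channel_ids = default_barcode_channels(),
                                     k = 3, sample_names = NULL) {
  B <- length(channel_ids)
  if (B < 1L || anyDuplicated(channel_ids)) {
    stop_cb("channel_ids must be a non-empty vector of unique labels",
            class = "cytobarcode_parameter_error")
  }
  if (!is.numeric(k) || length(k) != 1L || k != round(k) || k < 1 || k > B) {
    stop_cb(sprintf("k must be an integer in [1, %d]", B),
            class = "cytobarcode_parameter_error")
  }
  k <- as.integer(k)
  subsets <- utils::combn(B, k)          # columns already in lexicographic order
  S <- ncol(subsets)
  key <- matrix(0L, nrow = S, ncol = B)
  for (s in seq_len(S)) key[s, subsets[, s]] <- 1L
  if (is.null(sample_names)) sample_names <- sprintf("BC%02d", seq_len(S))
  if (length(sample_names) != S || anyDuplicated(sample_names)) {
    stop_cb("sample_names must be unique and match the number of keys",
            class = "cytobarcode_parameter_error")
  }
  new_barcode_scheme(key, channel_ids, sample_names, k)
}

#' Extract the binary key matrix of a scheme
#'
#' @param scheme A [barcode_scheme].
#' @return Integer matrix (samples x channels) with dimnames.
#' @export
scheme_key_matrix <- function(scheme) {
  ch <- scheme_channels(scheme)
  m <- as.matrix(scheme[, ch, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- scheme$sample
  m
}

#' @rdname scheme_key_matrix
#' @export
scheme_channels <- function(scheme) attr(scheme, "channels")

#' @rdname scheme_key_matrix
#' @export
scheme_k <- function(scheme) attr(scheme, "k")

#' Validate a barcode scheme
#'
#' Checks the scheme invariants and returns violations as data rather than
#' raising: every row sums to `k`, entries are binary, rows are pairwise
#' distinct, the row count does not exceed `choose(B, k)`, and every pair of
#' rows is at Hamming distance >= 2.
#'
#' @param scheme A [barcode_scheme].
#' @return A tibble with columns `rule`, `detail`, `rows` (list of offending
#'   row indices); zero rows iff the scheme is valid.
#' @export
validate_scheme <- function(scheme) {
  key <- scheme_key_matrix(scheme)
  k <- scheme_k(scheme)
  B <- ncol(key)
  viol <- list()
  add <- function(rule, detail, rows) {
    viol[[length(viol) + 1L]] <<- tibble::tibble(
      rule = rule, detail = detail, rows = list(as.integer(rows)))
  }
  if (!all(key %in% c(0L, 1L))) {
    bad <- which(rowSums(!(key == 0L | key == 1L)) > 0)
    add("non-binary entry", "key matrix entries must be 0 or 1", bad)
  }
  w <- rowSums(key)
  if (any(w != k)) {
    bad <- which(w != k)
    add("row weight != k",
        sprintf("rows with weight != %d: %s", k, paste(bad, collapse = ",")), bad)
  }
  keystr <- apply(key, 1L, paste, collapse = "")
  dup <- which(duplicated(keystr) | duplicated(keystr, fromLast = TRUE))
  if (length(dup) > 0L) {
    add("duplicate key", "two or more samples share the same key", dup)
  }
  if (k < 1L || k > B) {
    add("k out of range", sprintf("k = %d not in [1, %d]", k, B), integer(0))
  }
  if (nrow(key) > choose(B, k)) {
    add("too many rows",
        sprintf("%d rows exceed C(%d, %d) = %d", nrow(key), B, k, choose(B, k)),
        seq_len(nrow(key)))
  }
  if (nrow(key) >= 2L) {
    pairs <- utils::combn(nrow(key), 2L)
    hd <- apply(pairs, 2L, function(p) sum(key[p[1], ] != key[p[2], ]))
    # distance 0 is already reported as a duplicate; distance 1 cannot occur
    # between constant-weight rows but is asserted for hand-built schemes
    bad <- which(hd == 1L)
    if (length(bad) > 0L) {
      add("Hamming distance < 2",
          "constant-weight keys must differ in >= 2 positions",
          unique(as.integer(pairs[, bad])))
    }
  }
  if (length(viol) == 0L) {
    tibble::tibble(rule = character(), detail = character(), rows = list())
  } else {
    dplyr::bind_rows(viol)
  }
}

#' Read and write barcode key files
#'
#' The key CSV dialect is the one used by single-cell debarcoder tools:
#' a header row of channel labels with a leading `sample` column, and a 0/1
#' body. `read_key_file(write_key_file(s))` reproduces the scheme exactly.
#'
#' @param scheme A valid [barcode_scheme].
#' @param path File path.
#' @return `read_key_file` returns a [barcode_scheme]; `write_key_file`
#'   returns `path` invisibly.
#' @export
write_key_file <- function(scheme, path) {
  v <- validate_scheme(scheme)
  if (nrow(v) > 0L) {
    stop_cb(paste0("refusing to write an invalid scheme: ",
                   paste(v$rule, collapse = "; ")),
            class = "cytobarcode_scheme_error")
  }
  df <- as.data.frame(scheme[, c("sample", scheme_channels(scheme))])
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_key_file
#' @export
read_key_file <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (ncol(df) < 2L || tolower(names(df)[1]) != "sample") {
    stop_cb("key file must have a leading 'sample' column and >= 1 channel column",
            class = "cytobarcode_parse_error")
  }
  channel_ids <- names(df)[-1]
  body <- as.matrix(df[, -1, drop = FALSE])
  ok <- body %in% c("0", "1")
  if (!all(ok)) {
    bad <- which(!ok)[1]
    r <- ((bad - 1L) %% nrow(body)) + 1L
    cidx <- ((bad - 1L) %/% nrow(body)) + 1L
    stop_cb(sprintf("key file cell at row %d, column '%s' is '%s' (must be 0 or 1)",
                    r, channel_ids[cidx], body[bad]),
            class = "cytobarcode_parse_error")
  }
  key <- matrix(as.integer(body), nrow = nrow(body))
  k <- sum(key[1L, ])
  scheme <- new_barcode_scheme(key, channel_ids, df[[1]], k)
  full <- choose(length(channel_ids), k)
  if (nrow(key) < full) {
    rlang::inform(sprintf(
      "partial scheme: %d of C(%d, %d) = %d possible keys present",
      nrow(key), length(channel_ids), k, full))
  }
  scheme
}

#' @export
print.barcode_scheme <- function(x, ...) {
  cat(sprintf("<barcode_scheme> %d samples, %d channels, k = %d\n",
              nrow(x), length(scheme_channels(x)), scheme_k(x)))
  NextMethod()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' Tidy a barcode scheme into long form
#'
#' @param x A [barcode_scheme].
#' @param ... Unused.
#' @return Tibble with columns `sample`, `channel`, `positive`.
#' @export
tidy.barcode_scheme <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(unclass_scheme(x)),
                      cols = dplyr::all_of(scheme_channels(x)),
                      names_to = "channel", values_to = "positive")
}

unclass_scheme <- function(x) {
  class(x) <- setdiff(class(x), "barcode_scheme")
  x
}
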