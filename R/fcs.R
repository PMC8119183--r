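#' List-mode cytometry event tables
#'
#' Events are held as a tibble with one numeric column per channel (named by
#' the channel short name, e.g. `Cd112Di`), a `channel_info` attribute tibble
#' with columns `short_name`, `label`, `mass`, and a `metadata` attribute with
#' the FCS TEXT keywords. All intensities must be nonnegative and finite.
#'
#' @param values Events x channels numeric matrix or data frame.
#' @param channel_info Optional tibble with `short_name`, `label`, `mass`
#'   columns (one row per channel). Defaults are derived from column names.
#' @param metadata Named list of keyword/value text pairs.
#' @return An `fcs_events` tibble.
#' @export
fcs_events <- function(values, channel_info = NULL, metadata = list()) {
  if (is.matrix(values)) {
    if (is.null(colnames(values))) {
      colnames(values) <- sprintf("P%d", seq_len(ncol(values)))
    }
    values <- tibble::as_tibble(values)
  } else {
    values <- tibble::as_tibble(values)
  }
  if (is.null(channel_info)) {
    channel_info <- tibble::tibble(short_name = names(values),
                                   label = names(values),
                                   mass = parse_mass(names(values)))
  }
  channel_info <- tibble::as_tibble(channel_info)
  if (!all(c("short_name", "label") %in% names(channel_info))) {
    stop_cb("channel_info needs 'short_name' and 'label' columns",
            class = "cytobarcode_parameter_error")
  }
  if (!"mass" %in% names(channel_info)) {
    channel_info$mass <- parse_mass(channel_info$short_name)
  }
  if (nrow(channel_info) != ncol(values)) {
    stop_cb("channel_info rows must match the number of value columns",
            class = "cytobarcode_parameter_error")
  }
  if (any(!nzchar(channel_info$short_name)) || anyDuplicated(channel_info$short_name)) {
    stop_cb("channel short names must be nonempty and unique",
            class = "cytobarcode_parameter_error")
  }
  names(values) <- channel_info$short_name
  validate_event_values(values)
  attr(values, "channel_info") <- channel_info
  attr(values, "metadata") <- metadata
  class(values) <- c("fcs_events", class(values))
  values
}

validate_event_values <- function(values) {
  for (nm in names(values)) {
    v <- values[[nm]]
    if (!is.numeric(v)) {
      stop_cb(sprintf("channel '%s' is not numeric", nm),
              class = "cytobarcode_validation_error")
    }
    if (length(v) > 0L && (anyNA(v) || any(!is.finite(v)) || any(v < 0))) {
      stop_cb(sprintf("channel '%s' has negative or non-finite intensities", nm),
              class = "cytobarcode_validation_error")
    }
  }
  invisible(TRUE)
}

# "Cd112Di" / "112Cd" -> 112; NA when no mass is embedded in the name
parse_mass <- function(x) {
  m <- regmatches(x, regexpr("[0-9]{2,3}", x))
  out <- rep(NA_integer_, length(x))
  has <- vapply(regmatches(x, gregexpr("[0-9]{2,3}", x)), length, 1L) > 0
  out[has] <- as.integer(m)
  out
}

#' @rdname fcs_events
#' @param x An `fcs_events` table.
#' @export
channel_info <- function(x) attr(x, "channel_info")

#' @export
print.fcs_events <- function(x, ...) {
  cat(sprintf("<fcs_events> %d events x %d channels\n", nrow(x), ncol(x)))
  NextMethod()
}

# ---------------------------------------------------------------------------
# FCS 3.0/3.1 binary I/O. No cytometry I/O package ships with this toolchain,
# so the subset of the standard needed here (list mode, $DATATYPE F/D/I) is
# implemented directly over binary connections.
# ---------------------------------------------------------------------------

FCS_DELIM <- "|"

fcs_escape <- function(x) gsub(FCS_DELIM, paste0(FCS_DELIM, FCS_DELIM), x, fixed = TRUE)

#' Write events to an FCS 3.1 file
#'
#' Emits single-precision float ($DATATYPE=F), list mode ($MODE=L),
#' little-endian. Channel short names go to $PnN and labels to $PnS.
#'
#' @param x An [fcs_events] table (all intensities nonnegative and finite).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(x, path) {
  if (!inherits(x, "fcs_events")) x <- fcs_events(x)
  validate_event_values(x)
  info <- channel_info(x)
  p <- nrow(info)
  n <- nrow(x)
  mat <- as.matrix(tibble::as_tibble(unclass_events(x)))

  kw <- c(
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
    "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
    "$NEXTDATA" = "0",
    "$TOT" = as.character(n), "$PAR" = as.character(p)
  )
  for (j in seq_len(p)) {
    rng <- if (n > 0L) max(mat[, j]) else 0
    kw[sprintf("$P%dN", j)] <- fcs_escape(info$short_name[j])
    kw[sprintf("$P%dS", j)] <- fcs_escape(info$label[j])
    kw[sprintf("$P%dB", j)] <- "32"
    kw[sprintf("$P%dE", j)] <- "0,0"
    kw[sprintf("$P%dR", j)] <- as.character(max(1, ceiling(rng) + 1))
  }
  meta <- attr(x, "metadata") %||% list()
  meta <- meta[!grepl("^\\$", names(meta))]       # user keywords only
  for (nm in names(meta)) kw[nm] <- fcs_escape(as.character(meta[[nm]]))

  # data offsets use fixed-width fields so the TEXT length is known up front
  kw["$BEGINDATA"] <- strrep("0", 12)
  kw["$ENDDATA"] <- strrep("0", 12)
  text_body <- paste0(FCS_DELIM,
                      paste0(names(kw), FCS_DELIM, unname(kw), FCS_DELIM,
                             collapse = ""))
  text_start <- 256L
  text_end <- text_start + nchar(text_body, type = "bytes") - 1L
  data_start <- text_end + 1L
  data_end <- data_start + 4L * n * p - 1L
  if (n * p == 0L) { data_start <- 0L; data_end <- 0L }
  kw["$BEGINDATA"] <- sprintf("%012d", data_start)
  kw["$ENDDATA"] <- sprintf("%012d", max(data_end, 0L))
  text_body <- paste0(FCS_DELIM,
                      paste0(names(kw), FCS_DELIM, unname(kw), FCS_DELIM,
                             collapse = ""))

  header <- paste0("FCS3.1    ",
                   sprintf("%8d", text_start), sprintf("%8d", text_end),
                   sprintf("%8d", data_start), sprintf("%8d", data_end),
                   sprintf("%8d", 0L), sprintf("%8d", 0L))

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(strrep(" ", text_start - 58L)), con)   # pad to TEXT start
  writeBin(charToRaw(text_body), con)
  if (n * p > 0L) {
    writeBin(as.numeric(t(mat)), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Read an FCS 3.0/3.1 list-mode file
#'
#' Supports $DATATYPE F (float32), D (float64) and I (unsigned integers of a
#' uniform byte width; promoted to double, with legacy log amplification
#' applied when $PnE is non-linear). Multi-dataset files and $MODE other than
#' L are rejected.
#'
#' @param path Input file path.
#' @return An [fcs_events] table; FCS TEXT keywords are kept in the
#'   `metadata` attribute.
#' @export
read_fcs <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 58) {
    stop_cb(sprintf("'%s' is missing or truncated", path),
            class = "cytobarcode_io_error")
  }
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  header <- readChar(con, 58L, useBytes = TRUE)
  if (!grepl("^FCS3\\.[01]", header)) {
    stop_cb(sprintf("unsupported FCS version '%s' (need 3.0/3.1)",
                    trimws(substr(header, 1, 10))),
            class = "cytobarcode_format_error")
  }
  off <- suppressWarnings(as.integer(substring(header,
                                               10 + 8 * (0:5) + 1, 10 + 8 * (1:6))))
  text_start <- off[1]; text_end <- off[2]
  if (is.na(text_start) || is.na(text_end) || text_end <= text_start) {
    stop_cb("corrupt FCS header (TEXT offsets)", class = "cytobarcode_format_error")
  }
  if (text_end >= sz) {
    stop_cb("truncated FCS file: TEXT segment extends past end of file",
            class = "cytobarcode_io_error")
  }
  seek(con, text_start)
  text <- readChar(con, text_end - text_start + 1L, useBytes = TRUE)
  kw <- parse_fcs_text(text)
  get <- function(name, default = NULL) {
    v <- kw[[name]]
    if (is.null(v)) default else v
  }

  if (!identical(toupper(get("$MODE", "L")), "L")) {
    stop_cb("only list-mode ($MODE=L) FCS files are supported",
            class = "cytobarcode_format_error")
  }
  dtype <- toupper(get("$DATATYPE", ""))
  if (!dtype %in% c("F", "D", "I")) {
    stop_cb(sprintf("unsupported $DATATYPE '%s'", dtype),
            class = "cytobarcode_format_error")
  }
  byteord <- get("$BYTEORD", "1,2,3,4")
  endian <- if (identical(byteord, "4,3,2,1")) "big" else "little"
  p <- as.integer(get("$PAR"))
  n <- as.integer(get("$TOT"))
  if (is.na(p) || is.na(n)) {
    stop_cb("FCS TEXT lacks $PAR/$TOT", class = "cytobarcode_format_error")
  }
  data_start <- as.numeric(get("$BEGINDATA", "0"))
  data_end <- as.numeric(get("$ENDDATA", "0"))
  if (data_start <= 0 && n * p > 0) { data_start <- off[3]; data_end <- off[4] }

  bits <- vapply(seq_len(p), function(j) as.integer(get(sprintf("$P%dB", j), "32")), 1L)
  short <- vapply(seq_len(p), function(j) get(sprintf("$P%dN", j), sprintf("P%d", j)), "")
  label <- vapply(seq_len(p), function(j) get(sprintf("$P%dS", j), NA_character_), "")
  label <- ifelse(is.na(label), short, label)

  if (n * p > 0L) {
    need_bytes <- switch(dtype, F = 4L, D = 8L, I = unique(bits) / 8L)
    if (dtype == "I" && length(unique(bits)) != 1L) {
      stop_cb("integer FCS with mixed $PnB widths is not supported",
              class = "cytobarcode_format_error")
    }
    total <- as.numeric(n) * p * need_bytes
    if (data_start + total - 1 > sz) {
      stop_cb("truncated FCS file: DATA segment extends past end of file",
              class = "cytobarcode_io_error")
    }
    seek(con, data_start)
    vals <- switch(dtype,
      F = readBin(con, what = "numeric", n = n * p, size = 4L, endian = endian),
      D = readBin(con, what = "numeric", n = n * p, size = 8L, endian = endian),
      I = {
        w <- need_bytes
        if (!w %in% c(1L, 2L, 4L)) {
          stop_cb(sprintf("unsupported integer width %d bits", w * 8L),
                  class = "cytobarcode_format_error")
        }
        v <- readBin(con, what = "integer", n = n * p, size = w,
                     signed = w == 4L, endian = endian)
        v <- as.numeric(v)
        v[v < 0] <- v[v < 0] + 2^32          # recover unsigned 32-bit values
        v
      })
    mat <- matrix(vals, nrow = n, ncol = p, byrow = TRUE)
    if (dtype == "I") {
      for (j in seq_len(p)) {
        pe <- strsplit(get(sprintf("$P%dE", j), "0,0"), ",", fixed = TRUE)[[1]]
        f1 <- suppressWarnings(as.numeric(pe[1]))
        f2 <- suppressWarnings(as.numeric(pe[2]))
        if (isTRUE(f1 > 0)) {
          rng <- as.numeric(get(sprintf("$P%dR", j), "1024"))
          if (is.na(f2) || f2 <= 0) f2 <- 1
          mat[, j] <- f2 * 10^(f1 * mat[, j] / rng)
        }
      }
    }
  } else {
    mat <- matrix(numeric(0), nrow = max(n, 0L), ncol = p)
  }
  colnames(mat) <- short
  fcs_events(mat,
             channel_info = tibble::tibble(short_name = short, label = label,
                                           mass = parse_mass(short)),
             metadata = as.list(kw))
}

# TEXT segment parser: first byte is the delimiter; a doubled delimiter inside
# a token is an escaped literal.
parse_fcs_text <- function(text) {
  delim <- substr(text, 1L, 1L)
  body <- substring(text, 2L)
  raw_tokens <- strsplit(body, delim, fixed = TRUE)[[1]]
  tokens <- character(0)
  cur <- NULL
  i <- 1L
  while (i <= length(raw_tokens)) {
    piece <- raw_tokens[i]
    if (is.null(cur)) cur <- piece else cur <- paste0(cur, delim, piece)
    # an escaped delimiter shows up as an empty next raw token
    if (i < length(raw_tokens) && raw_tokens[i + 1L] == "") {
      i <- i + 1L     # swallow the empty marker; keep accumulating
    } else {
      tokens <- c(tokens, cur)
      cur <- NULL
    }
    i <- i + 1L
  }
  if (!is.null(cur)) tokens <- c(tokens, cur)
  tokens <- tokens[seq_len(2L * (length(tokens) %/% 2L))]
  keys <- tokens[seq(1L, length(tokens), by = 2L)]
  vals <- tokens[seq(2L, length(tokens), by = 2L)]
  names(vals) <- trimws(keys)
  as.list(vals)
}
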