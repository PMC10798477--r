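#' Construct a binary series
#'
#' One participant's ordered binary responses plus metadata.  Symbols may be
#' given as 0/1 integers, a single string such as `"010011"`, or O/R letters
#' (heads/tails), which are transcoded at this boundary only.
#'
#' @param symbols the response sequence.
#' @param participant_id opaque identifier.
#' @param condition `"visible"`, `"invisible"`, or `"none"`.
#' @return an object of class `binary_series`.
#' @export
binary_series <- function(symbols, participant_id = NA_character_,
                          condition = c("none", "visible", "invisible")) {
  condition <- match.arg(condition)
  bits <- as_binary_symbols(symbols)
  if (!length(bits)) stop_validation("a binary series needs at least 1 symbol")
  structure(list(participant_id = as.character(participant_id),
                 condition = condition, symbols = bits,
                 length = length(bits)),
            class = "binary_series")
}

#' @export
print.binary_series <- function(x, ...) {
  cat(sprintf("binary series: %s (%s), %d symbols\n", x$participant_id,
              x$condition, x$length))
  s <- symbols_to_string(x$symbols)
  if (nchar(s) > 60) s <- paste0(substr(s, 1, 60), "...")
  cat("  ", s, "\n", sep = "")
  invisible(x)
}

series_bits <- function(series) {
  if (inherits(series, "binary_series")) series$symbols
  else as_binary_symbols(series)
}

# codes of all step-1 windows of width w over a bit vector
rolling_codes <- function(bits, w) {
  n <- length(bits)
  stopifnot(n >= w)
  out <- numeric(n - w + 1)
  code <- bits_to_code(bits[seq_len(w)])
  out[1] <- code
  top <- 2^(w - 1)
  if (n > w) {
    for (i in seq_len(n - w)) {
      code <- (code - bits[i] * top) * 2 + bits[i + w]
      out[i + 1] <- code
    }
  }
  out
}

#' Algorithmic complexity of a short binary string (CTM lookup)
#'
#' Exact lookup of the Coding-Theorem complexity value, in bits.  Only
#' strings up to the table's maximum length (12 for the packaged table) are
#' defined; longer strings go through [bdm()].
#'
#' @param s binary string (string, 0/1 vector, or O/R letters).
#' @param table a [ctm_table][load_ctm_table()]; defaults to the packaged one.
#' @return complexity in bits.
#' @export
ctm <- function(s, table = ctm_table_default()) {
  bits <- series_bits(s)
  n <- length(bits)
  if (n < 1 || n > table$max_len) {
    stop_validation("ctm() is defined for lengths 1..", table$max_len,
                    ", got ", n)
  }
  table$values[[n]][bits_to_code(bits) + 1]
}

#' Block Decomposition Method complexity
#'
#' Extends the CTM lookup to longer strings: the string is cut into
#' consecutive non-overlapping blocks of `block_size` symbols (a trailing
#' remainder shorter than `block_size` is discarded — the "ignore" boundary
#' dialect), and `BDM = sum over distinct blocks (ctm(block) +
#' log2(multiplicity))`.  For strings no longer than `block_size` this
#' reduces to [ctm()].
#'
#' @inheritParams ctm
#' @param block_size block length, 1..table maximum (default 12).
#' @return complexity in bits.
#' @export
bdm <- function(s, block_size = 12L, table = ctm_table_default()) {
  bits <- series_bits(s)
  n <- length(bits)
  if (n < 1) stop_validation("bdm() of an empty string is undefined")
  block_size <- as.integer(block_size)
  if (block_size < 1 || block_size > table$max_len) {
    stop_validation("block_size must be in 1..", table$max_len)
  }
  if (n <= block_size) return(ctm(bits, table))
  nb <- n %/% block_size
  starts <- (seq_len(nb) - 1) * block_size
  codes <- vapply(starts, function(st)
    bits_to_code(bits[(st + 1):(st + block_size)]), numeric(1))
  mult <- table(codes)
  vals <- table$values[[block_size]][as.numeric(names(mult)) + 1]
  sum(vals + log2(as.numeric(mult)))
}

# raw BDM of the constant (all-zero) string of a given length under the
# same dialect, and the maximal achievable raw BDM; both are the anchors of
# the min-max normalization.
ctm_norm_range <- function(length, block_size = 12L,
                           table = ctm_table_default()) {
  if (length <= table$max_len && length <= block_size) {
    v <- table$values[[length]]
    return(c(min = v[1], max = max(v)))
  }
  nb <- length %/% block_size
  if (nb < 1) stop_validation("length shorter than one block")
  v <- table$values[[block_size]]
  lo <- v[1] + log2(nb)                       # one distinct constant block
  # maximum: the nb largest distinct block values, multiplicity 1 each
  # (log2(1) = 0; spreading over distinct blocks dominates log2 credits for
  # any nb <= number of distinct blocks)
  hi <- sum(sort(v, decreasing = TRUE)[seq_len(min(nb, length(v)))])
  c(min = lo, max = hi)
}

#' Normalize a raw CTM/BDM value to the unit interval
#'
#' Min-max normalization in the style used for short-string complexity: 0
#' is the all-constant string of that length, 1 the most complex string of
#' that length achievable under the same decomposition, values clamped to
#' \[0, 1\].
#'
#' @param raw raw complexity in bits (from [ctm()] or [bdm()]).
#' @param length length of the string the raw value came from.
#' @param block_size block length used for the raw value.
#' @param table the lookup table.
#' @return normalized complexity in \[0, 1\].
#' @export
normalize_complexity <- function(raw, length, block_size = 12L,
                                 table = ctm_table_default()) {
  rng <- ctm_norm_range(length, block_size, table)
  if (rng["max"] - rng["min"] < 1e-12) {
    stop_validation("degenerate normalization range at length ", length,
                    " (min == max)")
  }
  pmin(1, pmax(0, (raw - rng[["min"]]) / (rng[["max"]] - rng[["min"]])))
}

# normalized complexities of all width-w windows, vectorized (internal
# workhorse behind overall_complexity / rolling_complexity)
window_complexities <- function(bits, w, table) {
  codes <- rolling_codes(bits, w)
  v <- table$values[[w]]
  rng_min <- v[1]
  rng_max <- max(v)
  pmin(1, pmax(0, (v[codes + 1] - rng_min) / (rng_max - rng_min)))
}

#' Overall complexity of a series
#'
#' The mean normalized CTM complexity of all length-11 chunks of the series.
#' Chunks are step-1 sliding windows by default; a disjoint partition (with
#' trailing remainder discarded) is available as a dialect switch.
#'
#' @param series a [binary_series()] or binary vector/string.
#' @param table the lookup table.
#' @param chunk_len chunk length (default 11, just under the table maximum).
#' @param chunks `"sliding"` (default) or `"disjoint"`.
#' @return overall normalized complexity in \[0, 1\].
#' @export
overall_complexity <- function(series, table = ctm_table_default(),
                               chunk_len = 11L,
                               chunks = c("sliding", "disjoint")) {
  chunks <- match.arg(chunks)
  bits <- series_bits(series)
  chunk_len <- as.integer(chunk_len)
  if (chunk_len < 2 || chunk_len > table$max_len) {
    stop_validation("chunk_len must be in 2..", table$max_len)
  }
  if (length(bits) < chunk_len) {
    stop_validation("series shorter than one chunk (", length(bits), " < ",
                    chunk_len, ")")
  }
  nc <- window_complexities(bits, chunk_len, table)
  if (chunks == "disjoint") {
    nc <- nc[seq(1, length(bits) - chunk_len + 1, by = chunk_len)]
  }
  mean(nc)
}

#' Rolling-window complexity profile
#'
#' The normalized CTM complexity of every step-1 window of width
#' `window_w`, the dynamic measure of series randomness.
#' Window widths 5 to 9 match the usual working-memory capacity range
#' (7 +/- 2); width 7 is the reporting default.
#'
#' @inheritParams overall_complexity
#' @param window_w window width, 5..9.
#' @return an object of class `complexity_profile` with fields
#'   `participant_id`, `condition`, `window_w`, `positions` (0-based window
#'   END indices), `values` (normalized complexities) and `overall` (the
#'   length-11 overall measure, `NA` for series shorter than 11).
#' @export
rolling_complexity <- function(series, window_w = 7L,
                               table = ctm_table_default()) {
  window_w <- as.integer(window_w)
  if (window_w < 5L || window_w > 9L) {
    stop_validation("window_w must be in 5..9, got ", window_w)
  }
  bits <- series_bits(series)
  if (length(bits) < window_w) {
    stop_validation("series shorter than the window")
  }
  pid <- if (inherits(series, "binary_series")) series$participant_id
         else NA_character_
  cond <- if (inherits(series, "binary_series")) series$condition else "none"
  vals <- window_complexities(bits, window_w, table)
  overall <- if (length(bits) >= 11L) overall_complexity(bits, table) else NA_real_
  structure(list(participant_id = pid, condition = cond,
                 window_w = window_w,
                 positions = seq.int(window_w - 1L, length(bits) - 1L),
                 values = vals, overall = overall),
            class = "complexity_profile")
}

#' @export
print.complexity_profile <- function(x, ...) {
  cat(sprintf(
    "complexity profile: %s (%s), w = %d, %d windows, overall = %s\n",
    x$participant_id, x$condition, x$window_w, length(x$values),
    ifelse(is.na(x$overall), "NA", sprintf("%.3f", x$overall))))
  invisible(x)
}

#' @export
plot.complexity_profile <- function(x, ...) {
  graphics::plot(x$positions, x$values, type = "l",
                 xlab = "window end index (0-based)",
                 ylab = "normalized complexity",
                 ylim = c(0, 1),
                 main = sprintf("rolling complexity (w = %d)", x$window_w),
                 ...)
  invisible(x)
}

# ---- series / profile CSV plumbing (interface module) ----------------------

#' Read binary series from CSV
#'
#' Expects columns `participant_id`, `condition`, `position` (0-based) and
#' `symbol` (0/1 or O/R letters).
#'
#' @param path CSV file.
#' @return a list of [binary_series()] objects.
#' @export
read_series_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "condition", "position", "symbol")
  if (!all(need %in% names(df))) {
    stop_validation("series CSV needs columns: ", paste(need, collapse = ", "),
                    " (file ", path, ")")
  }
  lapply(split(df, df$participant_id), function(d) {
    d <- d[order(d$position), ]
    binary_series(as_binary_symbols(as.character(d$symbol)),
                  participant_id = d$participant_id[[1]],
                  condition = as.character(d$condition[[1]]))
  })
}

#' Write binary series to CSV
#'
#' @param series_list list of [binary_series()].
#' @param path output CSV (columns `participant_id`, `condition`,
#'   `position`, `symbol`; 0-based positions).
#' @export
write_series_csv <- function(series_list, path) {
  rows <- do.call(rbind, lapply(series_list, function(s) {
    data.frame(participant_id = s$participant_id, condition = s$condition,
               position = seq_along(s$symbols) - 1L, symbol = s$symbols)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write rolling-complexity profiles to CSV
#'
#' One row per window; `position` is the 0-based index of the window END.
#'
#' @param profiles list of [rolling_complexity()] profiles.
#' @param path output CSV.
#' @export
write_profiles_csv <- function(profiles, path) {
  rows <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(participant_id = p$participant_id, condition = p$condition,
               window_w = p$window_w, position = p$positions,
               normalized_complexity = p$values)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write per-participant overall-complexity summaries to CSV
#'
#' @param profiles list of [rolling_complexity()] profiles.
#' @param path output CSV.
#' @export
write_summary_csv <- function(profiles, path) {
  rows <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(participant_id = p$participant_id, condition = p$condition,
               overall_complexity = p$overall)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
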