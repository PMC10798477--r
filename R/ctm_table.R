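#' Enumerate small binary Turing machines (Coding Theorem Method)
#'
#' Runs an exhaustive enumeration of all `n_states`-state, 2-symbol Turing
#' machines in the Wolfram formalism (each (state, symbol) cell either halts
#' writing 0 or 1, or writes a symbol, moves left/right and changes state)
#' and tallies the output-frequency distribution of the halting machines.
#' Machines start on a blank tape; the distribution is symmetrised over
#' string reversal and bit complementation, which correspond to mirror
#' machines and blank-1 runs respectively.  A reduced enumeration (first
#' transition fixed up to symmetry and state relabelling) makes the full
#' space tractable: only `2 * (4 n + 2)^(2 n - 1)` machines are actually run.
#'
#' The Coding Theorem Method turns these output frequencies into algorithmic
#' complexity estimates: `K(s) = -log2(freq(s))`, where `freq(s)` is the
#' fraction of halting machines that output `s`.
#'
#' @param n_states number of machine states (2 or more; 4 is the scale used
#'   for the packaged table, 2 gives an instant miniature space useful for
#'   validating the construction logic).
#' @param max_steps runtime cap per machine.  Defaults to the busy-beaver
#'   bound where known (6, 21 and 107 steps for 2, 3 and 4 states), so no
#'   halting machine is missed.
#' @param max_len_keep longest output string tallied individually; longer
#'   outputs only contribute to the halting total.
#' @return an object of class `ctm_enumeration`: per-length output counts,
#'   the halting total, and enumeration metadata.
#' @seealso [ctm_build_table()] to turn the counts into a lookup table.
#' @export
ctm_enumerate <- function(n_states = 2L, max_steps = NULL, max_len_keep = 14L) {
  n_states <- as.integer(n_states)
  if (is.null(max_steps)) {
    bb <- c(`2` = 6L, `3` = 21L, `4` = 107L)
    max_steps <- if (as.character(n_states) %in% names(bb))
      bb[[as.character(n_states)]] else 500L
  }
  res <- ctm_enum_cpp(n_states, as.integer(max_steps), as.integer(max_len_keep))
  structure(res, class = "ctm_enumeration")
}

#' @export
print.ctm_enumeration <- function(x, ...) {
  cat(sprintf("Coding-Theorem enumeration of (%d,2) Turing machines\n",
              x$n_states))
  cat(sprintf("  machines run: %.0f (reduced), halting total: %.0f\n",
              x$machines_run, x$total_halting))
  cov <- vapply(seq_along(x$counts),
                function(L) sum(x$counts[[L]] > 0) / 2^L, numeric(1))
  cat("  coverage by length: ",
      paste(sprintf("%d:%.0f%%", seq_along(cov), 100 * cov), collapse = " "),
      "\n", sep = "")
  invisible(x)
}

#' Build a CTM lookup table from an enumeration
#'
#' Converts symmetrised output counts into complexity values
#' `K(s) = -log2(count(s) / total_halting)` (bits).  Strings that the
#' machine space never outputs are completed in two steps: a two-split
#' block decomposition rule (the minimum of `K(u) + K(v)` over all splits
#' `s = uv`, computed recursively over increasing length) orders them
#' among themselves, and the whole unobserved set is then shifted to sit
#' just above the largest observed value of its length class — an
#' unobserved output has frequency below that of every observed string,
#' so its complexity must exceed all of theirs.  The completion preserves
#' the reversal and complement symmetry of the enumerated counts and
#' keeps every length class complete, which downstream normalization
#' requires.
#'
#' @param enum a [ctm_enumerate()] result.
#' @param max_len largest string length retained in the table (at most the
#'   enumeration's `max_len_keep`; 12 for the packaged table).
#' @param source_label free-text provenance recorded in the table.
#' @return an object of class `ctm_table`.
#' @export
ctm_build_table <- function(enum, max_len = 12L, source_label = NULL) {
  stopifnot(inherits(enum, "ctm_enumeration"))
  max_len <- as.integer(max_len)
  if (max_len < 1L || max_len > length(enum$counts)) {
    stop("max_len must be in 1..", length(enum$counts))
  }
  if (is.null(source_label)) {
    source_label <- sprintf(
      "randser exhaustive (%d,2) Turing-machine enumeration (cap %d steps), two-split completion",
      enum$n_states, enum$max_steps)
  }
  total <- enum$total_halting
  values <- vector("list", max_len)
  covered <- vector("list", max_len)
  for (L in seq_len(max_len)) {
    cnt <- enum$counts[[L]]
    cov <- cnt > 0
    val <- rep(NA_real_, length(cnt))
    val[cov] <- -log2(cnt[cov] / total)
    if (any(!cov)) {
      if (L == 1L) stop("length-1 outputs missing from enumeration")
      best <- rep(Inf, length(cnt))
      for (j in seq_len(L - 1L)) {
        hi <- 0:(2^L - 1) %/% 2^(L - j)   # leading j bits
        lo <- 0:(2^L - 1) %% 2^(L - j)    # trailing L-j bits
        best <- pmin(best, values[[j]][hi + 1] + values[[L - j]][lo + 1])
      }
      # a string the machine space never outputs has frequency below that
      # of every observed string of its length, hence larger complexity
      # than all of them; the two-split sums only order the unobserved
      # strings among themselves.  Shift them to sit just above the
      # observed maximum (quarter-bit margin).
      if (any(cov)) {
        shift <- max(0, max(val[cov]) + 0.25 - min(best[!cov]))
        best <- best + shift
      }
      val[!cov] <- best[!cov]
    }
    values[[L]] <- val
    covered[[L]] <- cov
  }
  structure(list(values = values, covered = covered, max_len = max_len,
                 source_label = source_label, n_states = enum$n_states,
                 total_halting = total),
            class = "ctm_table")
}

#' @export
print.ctm_table <- function(x, ...) {
  cat("CTM lookup table, binary strings of length 1..", x$max_len, "\n",
      sep = "")
  cat("  source: ", x$source_label, "\n", sep = "")
  cat(sprintf("  entries: %d, enumerated (non-completed): %d\n",
              sum(2^seq_len(x$max_len)),
              sum(vapply(x$covered, sum, numeric(1)))))
  invisible(x)
}

#' Write a CTM table to a text resource
#'
#' Compact tab-separated format: values are stored only for strings whose
#' first bit is 0, in ascending code order within each length; complements
#' carry equal values by the table's symmetry (asserted before writing).
#'
#' @param table a `ctm_table`.
#' @param path output file.
#' @param digits decimal digits stored.
#' @return `path`, invisibly.
#' @export
write_ctm_table <- function(table, path, digits = 6) {
  stopifnot(inherits(table, "ctm_table"))
  lines <- c("# randser CTM table (compact: leading-bit-0 codes only)",
             paste0("# source_label: ", table$source_label),
             paste0("# n_states: ", table$n_states),
             paste0("# max_len: ", table$max_len),
             sprintf("# total_halting: %.0f", table$total_halting),
             "# columns: length value covered")
  for (L in seq_len(table$max_len)) {
    half <- seq_len(2^(L - 1))          # codes 0 .. 2^(L-1)-1 (first bit 0)
    v <- table$values[[L]][half]
    vc <- table$values[[L]][2^L + 1 - half]  # complement = bitwise NOT
    # vc[i] is the value at the complement of half code i
    if (max(abs(v - vc)) > 1e-9) {
      stop("table is not complement-symmetric; refusing to write compact form")
    }
    lines <- c(lines, sprintf("%d\t%.*f\t%d", L, digits, v,
                              as.integer(table$covered[[L]][half])))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Load a CTM lookup table
#'
#' Reads either the packaged table resource or a user-supplied file.  Two
#' formats are understood: the package's compact format written by
#' [write_ctm_table()], and a plain two-column `string<TAB>value` table.
#' After parsing, the loader validates the table: every length class present
#' must be complete (all `2^n` strings), all values must be finite and
#' positive, and values must be invariant under bit complementation (a
#' violation is reported as a warning and the table is kept as given).  A
#' sidecar `<name>.manifest.json` with an md5 checksum, if present, is
#' verified.
#'
#' @param resource name of a packaged resource (default: the shipped
#'   `ctm-b2-d12-m4` table, computed from the exhaustive (4,2) machine
#'   enumeration) or a path to a table file.
#' @return a `ctm_table`.
#' @export
load_ctm_table <- function(resource = "ctm-b2-d12-m4") {
  path <- if (file.exists(resource)) {
    resource
  } else {
    p <- system.file("extdata", paste0(resource, ".tsv"), package = "randser")
    if (!nzchar(p)) {
      stop_config("CTM table resource not found: ", resource)
    }
    p
  }
  manifest_path <- sub("\\.tsv$", ".manifest.json", path)
  if (file.exists(manifest_path)) {
    manifest <- jsonlite::read_json(manifest_path)
    md5 <- unname(tools::md5sum(path))
    if (!identical(md5, manifest$md5)) {
      stop_config("CTM table checksum mismatch for ", basename(path),
                  " (expected ", manifest$md5, ", got ", md5, ")")
    }
  }
  lines <- readLines(path, warn = FALSE)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(body)) stop_validation("empty CTM table file: ", path)
  get_meta <- function(key, default = NULL) {
    hit <- grep(paste0("^# ", key, ": "), meta, value = TRUE)
    if (length(hit)) sub(paste0("^# ", key, ": "), "", hit[[1]]) else default
  }
  first <- strsplit(body[[1]], "\t", fixed = TRUE)[[1]]
  compact <- !grepl("^[01]{1,12}$", first[[1]]) || length(first) != 2L

  if (compact) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    if (any(lengths(parts) != 3L)) {
      stop_validation("corrupt CTM table (compact rows need 3 fields): ", path)
    }
    len <- as.integer(vapply(parts, `[[`, "", 1L))
    val <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
    cov <- as.integer(vapply(parts, `[[`, "", 3L)) == 1L
    if (anyNA(len) || anyNA(val)) stop_validation("corrupt CTM table: ", path)
    max_len <- max(len)
    values <- vector("list", max_len)
    covered <- vector("list", max_len)
    for (L in seq_len(max_len)) {
      idx <- which(len == L)
      if (length(idx) != 2^(L - 1)) {
        stop_validation(sprintf(
          "CTM table incomplete at length %d: %d of %d leading-bit-0 strings",
          L, length(idx), 2^(L - 1)))
      }
      v <- rep(NA_real_, 2^L)
      v[seq_len(2^(L - 1))] <- val[idx]
      v[2^L:(2^(L - 1) + 1)] <- val[idx]       # complements, reversed order
      cv <- rep(NA, 2^L)
      cv[seq_len(2^(L - 1))] <- cov[idx]
      cv[2^L:(2^(L - 1) + 1)] <- cov[idx]
      values[[L]] <- v
      covered[[L]] <- cv
    }
  } else {
    parts <- strsplit(body, "\t", fixed = TRUE)
    if (any(lengths(parts) != 2L)) {
      stop_validation("corrupt CTM table (rows need string<TAB>value): ", path)
    }
    str <- vapply(parts, `[[`, "", 1L)
    val <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
    if (anyNA(val) || !all(grepl("^[01]+$", str))) {
      stop_validation("corrupt CTM table: ", path)
    }
    len <- nchar(str)
    max_len <- max(len)
    values <- vector("list", max_len)
    covered <- vector("list", max_len)
    for (L in sort(unique(len))) {
      idx <- which(len == L)
      if (length(idx) != 2^L) {
        stop_validation(sprintf(
          "CTM table incomplete at length %d: %d of %d strings", L,
          length(idx), 2^L))
      }
      code <- vapply(str[idx], function(s) strtoi(s, base = 2L), numeric(1))
      v <- rep(NA_real_, 2^L)
      v[code + 1] <- val[idx]
      values[[L]] <- v
      covered[[L]] <- rep(TRUE, 2^L)
    }
    if (any(vapply(values, is.null, logical(1)))) {
      stop_validation("CTM table misses whole length classes: ",
                      paste(which(vapply(values, is.null, logical(1))),
                            collapse = ", "))
    }
  }

  for (L in seq_len(max_len)) {
    v <- values[[L]]
    if (anyNA(v) || any(!is.finite(v)) || any(v <= 0)) {
      stop_validation("CTM table has missing/non-positive values at length ", L)
    }
    comp <- rev(v)  # value at complement code (2^L-1)-c
    if (max(abs(v - comp)) > 1e-9) {
      warning("CTM table not complement-symmetric at length ", L,
              " (max |K(s) - K(complement)| = ", format(max(abs(v - comp))),
              "); keeping values as loaded")
    }
  }

  structure(list(values = values, covered = covered, max_len = max_len,
                 source_label = get_meta("source_label",
                                         paste0("loaded from ", path)),
                 n_states = as.integer(get_meta("n_states", "0")),
                 total_halting = as.numeric(get_meta("total_halting", "0"))),
            class = "ctm_table")
}

#' Default packaged CTM table (memoized)
#'
#' @return the packaged `ctm_table`, loaded once per session.
#' @export
ctm_table_default <- function() {
  if (is.null(.randser_env$default_table)) {
    .randser_env$default_table <- load_ctm_table()
  }
  .randser_env$default_table
}
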