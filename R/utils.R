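# internal helpers shared across modules

# Coerce a binary sequence to an integer vector of 0/1.
# Accepts: integer/numeric/logical vectors; a single string like "010101"
# (or "ORRRROO"); character vectors of single symbols.  Letters are mapped
# through `map` at the I/O boundary only (O = heads = 0, R = tails = 1 by
# convention).
as_binary_symbols <- function(x, map = c(O = 0L, R = 1L)) {
  if (is.logical(x)) x <- as.integer(x)
  if (is.character(x)) {
    if (length(x) == 1L && nchar(x) > 1L) x <- strsplit(x, "")[[1]]
    x <- toupper(x)
    out <- integer(length(x))
    known <- x %in% c("0", "1")
    out[known] <- as.integer(x[known])
    lettered <- x %in% names(map)
    out[lettered] <- as.integer(map[x[lettered]])
    if (!all(known | lettered)) {
      stop("illegal symbols in binary sequence: ",
           paste(unique(x[!(known | lettered)]), collapse = ", "))
    }
    x <- out
  }
  x <- as.integer(x)
  if (length(x) && !all(x %in% c(0L, 1L))) {
    stop("binary sequence may only contain 0 and 1")
  }
  x
}

symbols_to_string <- function(bits) paste(bits, collapse = "")

# bits (first element = most significant) <-> integer code
bits_to_code <- function(bits) {
  code <- 0
  for (b in bits) code <- code * 2 + b
  code
}

code_to_bits <- function(code, len) {
  bits <- integer(len)
  for (i in len:1) {
    bits[i] <- code %% 2
    code <- code %/% 2
  }
  bits
}

complement_code <- function(code, len) (2^len - 1) - code

reverse_code <- function(code, len) bits_to_code(rev(code_to_bits(code, len)))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(structure(class = c("randser_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_validation <- function(...) {
  stop(structure(class = c("randser_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
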