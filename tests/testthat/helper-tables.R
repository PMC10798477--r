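# shared fixtures, built in code and memoized for the session

.test_env <- new.env()

# the packaged (4,2)-derived table
tab <- function() ctm_table_default()

# miniature table from the instant (2,2) enumeration; structurally valid
# (complete to length 12 via completion) but very coarse — used to test
# construction logic independently of the packaged resource
mini_tab <- function() {
  if (is.null(.test_env$mini)) {
    .test_env$mini <- ctm_build_table(ctm_enumerate(2L), max_len = 12L)
  }
  .test_env$mini
}

random_bits <- function(n) sample(0:1, n, replace = TRUE)

# naive reference implementations, deliberately independent of the package
# internals (string-based, no code arithmetic): the oracle side of the
# dual-route complexity checks
naive_ctm <- function(s, table) {
  stopifnot(nchar(s) <= table$max_len)
  table$values[[nchar(s)]][strtoi(s, base = 2) + 1]
}

naive_normalize <- function(raw, len, table) {
  v <- table$values[[len]]
  lo <- v[1]
  hi <- max(v)
  min(1, max(0, (raw - lo) / (hi - lo)))
}

naive_overall <- function(s, table, chunk = 11) {
  vals <- vapply(seq_len(nchar(s) - chunk + 1), function(i) {
    naive_normalize(naive_ctm(substr(s, i, i + chunk - 1), table), chunk,
                    table)
  }, numeric(1))
  mean(vals)
}

naive_bdm <- function(s, block, table) {
  n <- nchar(s)
  if (n <= block) return(naive_ctm(s, table))
  nb <- n %/% block
  blocks <- vapply(seq_len(nb), function(i)
    substr(s, (i - 1) * block + 1, i * block), character(1))
  tb <- table(blocks)
  sum(vapply(names(tb), naive_ctm, numeric(1), table = table) +
        log2(as.numeric(tb)))
}

bits_string <- function(bits) paste(bits, collapse = "")
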