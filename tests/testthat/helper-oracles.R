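# Independent brute-force oracles, deliberately written without reference to
# the package internals.

# Character of the infinite AUUUA repeat at (possibly negative) index i.
oracle_pattern_char <- function(i) {
  ifelse(((i %% 4) + 4) %% 4 == 0, "A", "U")
}

oracle_pattern <- function(g, len) {
  paste(oracle_pattern_char(g + seq_len(len) - 1), collapse = "")
}

# Every maximal run matching the periodic AUUUA pattern with length >= 6 at
# any registration, or exactly AUUUA at length 5. Tests all substrings.
oracle_scan_ares <- function(s) {
  n <- nchar(s)
  rows <- list()
  for (L in 5:max(5, n)) {
    if (L > n) break
    starts <- 0:(n - L)
    subs <- substring(s, starts + 1, starts + L)
    for (g in 0:3) {
      pat <- oracle_pattern(g, L)
      hit <- subs == pat
      if (!any(hit)) next
      a <- starts[hit]
      left_open <- a == 0 |
        substring(s, a, a) != oracle_pattern_char(g - 1)
      right_open <- a + L == n |
        substring(s, a + L + 1, a + L + 1) != oracle_pattern_char(g + L)
      keep <- left_open & right_open & (L >= 6 | g == 0)
      for (ai in a[keep]) {
        rows[[length(rows) + 1]] <- data.frame(
          start = ai, length = L, start_registration = g
        )
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(start = integer(), length = integer(),
                      start_registration = integer()))
  }
  out <- do.call(rbind, rows)
  out[order(out$start), , drop = FALSE]
}

# Overlapping k-mer counts by dictionary lookup.
oracle_kmer_counts <- function(s, k) {
  n <- nchar(s)
  subs <- substring(s, 1:(n - k + 1), k:n)
  table(factor(subs, levels = sort(unique(subs))))
}

# All strings over {A, U} of lengths 1..max_len.
all_au_strings <- function(max_len) {
  unlist(lapply(1:max_len, function(l) {
    g <- do.call(expand.grid, rep(list(c("A", "U")), l))
    do.call(paste0, g)
  }))
}

random_rna <- function(n, len, seed = NULL, alphabet = c("A", "C", "G", "U")) {
  draw <- function() {
    vapply(seq_len(n), function(i) {
      paste(sample(alphabet, len, replace = TRUE), collapse = "")
    }, character(1))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

expect_same_matches <- function(s) {
  got <- scan_ares(s)
  want <- oracle_scan_ares(s)
  expect_equal(
    as.data.frame(got[c("start", "length", "start_registration")]),
    data.frame(want, row.names = NULL),
    info = paste("sequence:", s)
  )
}
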