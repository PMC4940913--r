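# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

# Random DNA strings of the given lengths, drawn in one pass for speed.
rand_dna <- function(lengths) {
  if (length(lengths) == 0L) return(character())
  total <- sum(lengths)
  pool <- intToUtf8(sample(c(65L, 67L, 71L, 84L), total, replace = TRUE))
  ends <- cumsum(lengths)
  starts <- ends - lengths + 1L
  substring(pool, starts, ends)
}

is_dna <- function(x) {
  grepl("^[ACGT]+$", x)
}

assert_dna <- function(x, what = "sequence") {
  bad <- which(!is_dna(x))
  if (length(bad)) {
    abort(sprintf(
      "%s %d is empty or contains characters other than A/C/G/T: '%s'",
      what, bad[1], x[bad[1]]
    ))
  }
  invisible(x)
}

# Length of the longest common prefix of a list of integer (utf8) vectors.
lcp_length <- function(ints) {
  p <- min(lengths(ints))
  if (p == 0L) return(0L)
  first <- ints[[1]]
  for (k in seq_along(ints)[-1]) {
    if (p == 0L) return(0L)
    d <- which(first[seq_len(p)] != ints[[k]][seq_len(p)])
    if (length(d)) p <- d[1] - 1L
  }
  p
}

# Leftmost insertion point of x in a sorted character vector (binary
# search); returns i such that sorted[i] == x, or 0 when absent.
bisect_find <- function(sorted, x) {
  lo <- 1L
  hi <- length(sorted)
  while (lo <= hi) {
    mid <- (lo + hi) %/% 2L
    if (sorted[mid] < x) {
      lo <- mid + 1L
    } else if (sorted[mid] > x) {
      hi <- mid - 1L
    } else {
      return(mid)
    }
  }
  0L
}

# pmin that treats NA as "no candidate" instead of poisoning the result.
pmin_na <- function(a, b) {
  out <- pmin(a, b, na.rm = TRUE)
  out[is.na(a) & is.na(b)] <- NA_integer_
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x
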