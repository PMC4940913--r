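# The matching engine: recursive indexing trees over expected barcode and
# tag sequences.  A read is matched by walking the tree from its first
# nucleotide one base at a time; anything after the end of the matched
# sequence is ignored, and the number of bases examined is bounded by the
# length of the longest stored sequence no matter how many sequences are
# stored.  Quality scores are ignored throughout; 'N' (or any non-ACGT
# symbol) never matches.

#' Build a sequence indexing tree
#'
#' @param sequences Character vector of distinct A/C/G/T strings.
#' @param payloads Integer payload per sequence (defaults to the
#'   sequence's position); payloads need not be unique, sequences must be.
#' @return A `seq_trie` object.
#' @examples
#' tr <- seq_trie(c("ACGT", "AC"), payloads = c(10L, 20L))
#' trie_match(tr, c("ACGTAA", "ACCCCC", "TTTT"))
#' @export
seq_trie <- function(sequences, payloads = seq_along(sequences)) {
  sequences <- toupper(as.character(sequences))
  payloads <- as.integer(payloads)
  ptr <- .trie_build(sequences, payloads)
  structure(list(ptr = ptr), class = "seq_trie")
}

#' @export
print.seq_trie <- function(x, ...) {
  cat(sprintf("<seq_trie: %d sequences, depth %d>\n",
              trie_size(x), trie_depth(x)))
  invisible(x)
}

#' @rdname seq_trie
#' @param trie A `seq_trie`.
#' @export
trie_depth <- function(trie) .trie_depth(trie$ptr)

#' @rdname seq_trie
#' @export
trie_size <- function(trie) .trie_size(trie$ptr)

#' Match reads against an indexing tree
#'
#' Walks the tree from position 1 of each read.  When one stored sequence
#' is a proper prefix of another, the deepest terminal reached wins
#' (longest match), so a read carrying the longer sequence is credited to
#' it rather than to its prefix.
#'
#' @param trie A `seq_trie`.
#' @param reads Character vector of reads (A/C/G/T/N; `N` never matches).
#' @return A tibble with one row per read: `payload` (the matched
#'   sequence's payload, `NA` for no match), `consumed` (bases covered by
#'   the match) and `steps` (read nucleotides examined; never more than
#'   the longest stored sequence's length).
#' @export
trie_match <- function(trie, reads) {
  stopifnot(inherits(trie, "seq_trie"))
  res <- .trie_match(trie$ptr, toupper(as.character(reads)))
  tibble(payload = res$payload, consumed = res$consumed,
         steps = res$steps)
}

#' Find the adapter trim position from the 3' end of reads
#'
#' Searches each read from its end for adapter content: either a full
#' internal occurrence of an adapter sequence, or a read suffix of at
#' least `min_overlap` bases equal to a prefix of an adapter (adapter
#' read-through truncated by the end of the read).  The returned position
#' is the 1-based start of the adapter content — the earliest such start
#' across all adapter sequences — so `substr(read, 1, p - 1)` is the
#' trimmed read.
#'
#' @param reads Character vector of reads.
#' @param adapters An `adapter_set`, a registered chemistry name, or a
#'   character vector of adapter sequences.
#' @param min_overlap Minimum read/adapter overlap (nt) for a suffix
#'   match; the default of 6 keeps the chance of trimming random 3'
#'   sequence at any one position to 4^-6.
#' @return Integer vector of trim positions, `NA` where no adapter
#'   content was found.
#' @export
find_adapter_trim <- function(reads, adapters, min_overlap = 6L) {
  stopifnot(min_overlap >= 1L)
  adapters <- get_adapters(adapters)
  reads <- toupper(as.character(reads))
  n <- nchar(reads)
  best <- rep(NA_integer_, length(reads))
  for (ad in adapters$sequences) {
    alen <- nchar(ad)
    if (min_overlap > alen) {
      abort("min_overlap exceeds the adapter length")
    }
    # leftmost full occurrence anywhere in the read
    full <- stringr::str_locate(reads, stringr::fixed(ad))[, 1]
    cand <- as.integer(full)
    # suffix overlaps, longest first so the earliest start wins; a full
    # occurrence always starts earlier than any proper suffix overlap,
    # so reads already matched above are skipped
    ks <- if (alen - 1L >= min_overlap) seq(alen - 1L, min_overlap) else integer()
    for (k in ks) {
      pre <- substr(ad, 1L, k)
      idx <- which(n >= k & is.na(cand))
      if (!length(idx)) next
      hit <- stringr::str_sub(reads[idx], n[idx] - k + 1L, n[idx]) == pre
      cand[idx[hit]] <- n[idx[hit]] - k + 1L
    }
    best <- pmin_na(best, cand)
  }
  best
}

#' Find an internal full restriction cut site
#'
#' Conventional text search for the leftmost occurrence of any of the
#' given sites at or after `search_from`.  A full site inside a read
#' suggests a re-ligation chimera of two genomic fragments.
#'
#' @param reads Character vector of reads.
#' @param sites Character vector of full recognition sites.
#' @param search_from 1-based position at which the search starts
#'   (scalar or one value per read).
#' @return A tibble with columns `position` (1-based start of the
#'   leftmost site, `NA` if none) and `site` (which site matched).
#' @export
find_full_cut_site <- function(reads, sites, search_from = 1L) {
  stopifnot(all(search_from >= 1L))
  reads <- toupper(as.character(reads))
  sites <- toupper(sites)
  assert_dna(sites, "cut site")
  search_from <- rep_len(as.integer(search_from), length(reads))
  tails <- stringr::str_sub(reads, search_from)
  pos <- rep(NA_integer_, length(reads))
  which_site <- rep(NA_character_, length(reads))
  for (s in sites) {
    p <- stringr::str_locate(tails, stringr::fixed(s))[, 1]
    p <- as.integer(p) + search_from - 1L
    better <- !is.na(p) & (is.na(pos) | p < pos)
    pos[better] <- p[better]
    which_site[better] <- s
  }
  tibble(position = pos, site = which_site)
}
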