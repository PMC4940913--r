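# Core domain types: markers, alleles, tag sequences, and the bracketed
# merged-tag notation ("prefix[A/T]suffix") used for compact storage of
# all alleles of a marker in a single string.

#' Merge allele tag sequences into bracket notation
#'
#' Collapses two or more allele tags of one marker into a merged tag: the
#' longest shared prefix, the per-allele variable middles in square
#' brackets separated by `/`, and the longest shared suffix.  Alleles of
#' unequal length are rendered with an empty side, e.g. `"AC[G/]TT"`, so
#' that markers with insertions/deletions (as mined by allele-block
#' pipelines) degrade gracefully.
#'
#' @param tag0,tag1 Allele tag sequences (A/C/G/T strings).
#' @return A `merged_tag` object; its `format()`/`print()` render the
#'   bracket string.  Use [expand_merged()] to recover the full alleles.
#' @examples
#' merge_alleles("ACAGACTTAGTACCCA", "ACAGACTTTGTACCCA")
#' @export
merge_alleles <- function(tag0, tag1) {
  merge_tags(c(tag0, tag1))
}

#' @param tags Character vector of two or more allele tag sequences.
#' @rdname merge_alleles
#' @export
merge_tags <- function(tags) {
  tags <- toupper(tags)
  assert_dna(tags, "tag")
  if (length(tags) < 2L) {
    abort("need at least two tag sequences to merge")
  }
  if (anyDuplicated(tags)) {
    abort("tags are identical; there is no variable site to merge")
  }
  ints <- lapply(tags, utf8ToInt)
  p <- lcp_length(ints)
  rem <- lapply(ints, function(v) {
    if (p < length(v)) v[(p + 1L):length(v)] else integer()
  })
  s <- lcp_length(lapply(rem, rev))
  variants <- vapply(rem, function(v) {
    m <- length(v) - s
    if (m > 0L) intToUtf8(v[seq_len(m)]) else ""
  }, character(1))
  prefix <- if (p > 0L) intToUtf8(ints[[1]][seq_len(p)]) else ""
  suffix <- if (s > 0L) {
    v <- rem[[1]]
    intToUtf8(v[(length(v) - s + 1L):length(v)])
  } else ""
  new_merged_tag(prefix, variants, suffix)
}

new_merged_tag <- function(prefix, variants, suffix) {
  structure(list(prefix = prefix, variants = variants, suffix = suffix),
            class = "merged_tag")
}

#' @export
#' @method format merged_tag
format.merged_tag <- function(x, ...) {
  paste0(x$prefix, "[", paste(x$variants, collapse = "/"), "]", x$suffix)
}

#' @export
print.merged_tag <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Render a merged tag as its bracket string
#'
#' @param merged A `merged_tag` object.
#' @return A string such as `"ACAGACTT[A/T]GTACCCA"`.
#' @export
render_merged <- function(merged) {
  stopifnot(inherits(merged, "merged_tag"))
  format(merged)
}

#' Parse bracket notation into a merged tag
#'
#' @param x A string such as `"CCGATTAG[C/T]AGGGGTT"`.  Lowercase input is
#'   accepted and normalised to uppercase.
#' @return A `merged_tag` object.
#' @export
parse_merged <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- toupper(x)
  m <- regmatches(x, regexec(
    "^([ACGT]*)\\[([ACGT]*(?:/[ACGT]*)+)\\]([ACGT]*)$", x
  ))[[1]]
  if (length(m) == 0L) {
    abort(sprintf("cannot parse merged tag notation: '%s'", x))
  }
  variants <- strsplit(m[3], "/", fixed = TRUE)[[1]]
  # strsplit drops a trailing empty field ("A/" -> "A"); restore it
  if (grepl("/$", m[3])) variants <- c(variants, "")
  expansions <- paste0(m[2], variants, m[4])
  if (any(expansions == "")) {
    abort(sprintf("merged tag '%s' expands to an empty sequence", x))
  }
  new_merged_tag(m[2], variants, m[4])
}

#' Expand a merged tag into full allele sequences
#'
#' @param merged A `merged_tag` object or a bracket-notation string.
#' @return Character vector of `prefix + variant + suffix` for each
#'   variant, order preserved.  Round-trips with [merge_alleles()].
#' @examples
#' expand_merged("CCGATTAG[C/T]AGGGGTT")
#' @export
expand_merged <- function(merged) {
  if (is.character(merged)) merged <- parse_merged(merged)
  stopifnot(inherits(merged, "merged_tag"))
  paste0(merged$prefix, merged$variants, merged$suffix)
}

#' Order allele tags alphabetically and number them
#'
#' For formats that do not fix the allele order themselves, the tag that
#' comes first alphabetically becomes allele `"0"`, the next `"1"`, and
#' so on.
#'
#' @param tags Character vector of two or more distinct tag sequences.
#' @return A tibble with columns `allele` (`"0"`, `"1"`, ...) and
#'   `sequence` (sorted tags).
#' @export
order_alleles <- function(tags) {
  tags <- toupper(tags)
  assert_dna(tags, "tag")
  if (length(tags) < 2L) {
    abort("a marker needs at least two distinct tags to order alleles")
  }
  if (anyDuplicated(tags)) {
    abort("duplicate tag sequences within a marker")
  }
  s <- sort(tags, method = "radix")
  tibble(allele = as.character(seq_along(s) - 1L), sequence = s)
}

#' Compose and parse tag column names
#'
#' Tag columns in the counts table are named
#' `marker_variableBases_alleleName` (e.g. `"TP1_A_0"`); an allele whose
#' variable region is empty (a deletion allele) renders the middle field
#' as `"-"`.  `parse_tag_column()` splits a column name back into its
#' parts from the right, so marker names may themselves contain
#' underscores.
#'
#' @param marker Marker name.
#' @param variable Variable-site nucleotides for this allele (may be `""`).
#' @param allele Final allele name (`"0"`, `"1"`, ... or a verbatim name).
#' @return `tag_column_name()`: a string.  `parse_tag_column()`: a tibble
#'   with columns `marker`, `variable`, `allele`.
#' @export
tag_column_name <- function(marker, variable, allele) {
  variable <- ifelse(variable == "", "-", variable)
  paste(marker, variable, allele, sep = "_")
}

#' @param x Character vector of tag column names.
#' @rdname tag_column_name
#' @export
parse_tag_column <- function(x) {
  m <- regmatches(x, regexec("^(.*)_([^_]*)_([^_]+)$", x))
  bad <- which(lengths(m) == 0L)
  if (length(bad)) {
    abort(sprintf("cannot parse tag column name: '%s'", x[bad[1]]))
  }
  tibble(
    marker = vapply(m, `[`, character(1), 2),
    variable = vapply(m, `[`, character(1), 3),
    allele = vapply(m, `[`, character(1), 4)
  )
}

#' Build a tag set
#'
#' A tag set is the searchable dictionary of markers and their allele tag
#' sequences.  It is stored as a tibble with one row per allele and
#' columns `marker`, `allele`, `variable` (the allele's variable-site
#' nucleotides, `"-"` when empty or monomorphic), `sequence`, and
#' `tag_name` (the counts-table column name).
#'
#' @param markers A data frame with columns `marker`, `allele` and
#'   `sequence` (one row per allele; allele order within a marker is
#'   preserved).
#' @param name_table Optional tibble mapping original SNP names to marker
#'   names (retained when importing from alignment-based pipelines).
#' @return A `tag_set` tibble.
#' @export
tag_set <- function(markers, name_table = NULL) {
  stopifnot(is.data.frame(markers))
  need <- c("marker", "allele", "sequence")
  miss <- setdiff(need, names(markers))
  if (length(miss)) {
    abort(sprintf("missing column in marker table: '%s'", miss[1]))
  }
  df <- as_tibble(markers)[need]
  df$sequence <- unname(toupper(df$sequence))
  df$allele <- unname(as.character(df$allele))
  df$marker <- unname(as.character(df$marker))
  assert_dna(df$sequence, "tag")
  if (nrow(df) == 0L) {
    out <- tibble(marker = character(), allele = character(),
                  variable = character(), sequence = character(),
                  tag_name = character())
    return(new_tag_set(out, name_table))
  }
  # per-marker checks and variable-site computation (marker order kept)
  df$marker <- factor(df$marker, levels = unique(df$marker))
  split_seq <- split(df$sequence, df$marker)
  for (mk in names(split_seq)) {
    if (anyDuplicated(split_seq[[mk]])) {
      abort(sprintf("marker '%s' has duplicate allele tag sequences", mk))
    }
  }
  per_marker <- lapply(split_seq, function(seqs) {
    if (length(seqs) < 2L) return("-")
    v <- merge_tags(seqs)$variants
    ifelse(v == "", "-", v)
  })
  df$variable <- unsplit(per_marker, df$marker)
  df$marker <- as.character(df$marker)
  df$tag_name <- tag_column_name(df$marker, df$variable, df$allele)
  df <- df[c("marker", "allele", "variable", "sequence", "tag_name")]
  new_tag_set(df, name_table)
}

new_tag_set <- function(df, name_table = NULL) {
  structure(df,
            name_table = name_table,
            class = c("tag_set", class(tibble())))
}

#' @rdname tag_set
#' @param tags A `tag_set`.
#' @export
tag_names <- function(tags) {
  tags$tag_name
}

#' Original-name correspondence retained by a reader
#'
#' @param tags A `tag_set`.
#' @return A tibble mapping `original_name` to `marker`, or `NULL` when
#'   the source format carried no separate SNP names.
#' @export
name_table <- function(tags) {
  attr(tags, "name_table")
}
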