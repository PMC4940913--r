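# Cross-project marker consolidation under stable universal names.  Two
# markers are the same marker exactly when their complete sorted sets of
# allele sequences are identical; a truncated tag is a different tag, so
# partial or truncated overlaps never merge.  Matching uses a binary
# search over the lexicographically sorted allele-set keys.

UNIVERSAL_PAD <- 6L

#' Create an empty marker database
#'
#' @param prefix Name prefix for universal marker names; names are the
#'   prefix followed by a zero-padded integer (e.g. `MyLabsTags000102`)
#'   and are stable across appends.
#' @return An empty `marker_db` tibble with columns `universal_name`,
#'   `tag_sequence` (merged bracket notation), `chromosome`, `position`
#'   and `alignment_quality`.
#' @export
marker_db <- function(prefix) {
  stopifnot(is.character(prefix), length(prefix) == 1L, nzchar(prefix))
  structure(
    tibble(universal_name = character(), tag_sequence = character(),
           chromosome = character(), position = integer(),
           alignment_quality = integer()),
    prefix = prefix,
    conflicts = tibble(project = character(), marker = character(),
                       universal_name = character(),
                       shared_sequence = character()),
    class = c("marker_db", class(tibble()))
  )
}

#' @rdname marker_db
#' @param db A `marker_db`.
#' @export
db_prefix <- function(db) attr(db, "prefix")

#' @rdname marker_db
#' @export
db_conflicts <- function(db) attr(db, "conflicts")

universal_name <- function(prefix, n) {
  paste0(prefix, formatC(n, width = UNIVERSAL_PAD, flag = "0",
                         format = "d"))
}

allele_key <- function(seq_list) {
  vapply(seq_list, function(s) paste(sort(s), collapse = ";"),
         character(1))
}

#' Consolidate a tag set into a marker database
#'
#' An incoming marker whose complete sorted allele-sequence set exactly
#' equals an existing record's set is merged into that record (the
#' project's original marker name is recorded as an alias in a column
#' named after the project).  An incoming marker that shares some but
#' not all alleles with an existing record is **not** merged; it gets a
#' new universal name and the overlap is recorded in the conflict report
#' (see [db_conflicts()]).  Unmatched markers receive the next
#' sequential universal names.  Re-consolidating a previously seen
#' project is idempotent.
#'
#' @param db An existing `marker_db`, or `NULL` to start a new one.
#' @param tags A `tag_set`; every marker must have at least two alleles.
#' @param project Project name (becomes the alias column).
#' @param prefix Universal-name prefix; required for a new database and,
#'   if given for an existing one, must agree with its stored prefix.
#' @return The updated `marker_db`.
#' @export
consolidate <- function(db, tags, project, prefix = NULL) {
  stopifnot(inherits(tags, "tag_set"))
  if (is.null(db)) {
    if (is.null(prefix)) abort("a new marker database needs a 'prefix'")
    db <- marker_db(prefix)
  }
  stopifnot(inherits(db, "marker_db"))
  if (!is.null(prefix) && !identical(prefix, attr(db, "prefix"))) {
    abort(sprintf("prefix '%s' does not match the database prefix '%s'",
                  prefix, attr(db, "prefix")))
  }
  prefix <- attr(db, "prefix")
  per <- split(tags$sequence, factor(tags$marker,
                                     levels = unique(tags$marker)))
  n_alleles <- lengths(per)
  if (any(n_alleles < 2L)) {
    abort(sprintf(
      "marker '%s' has fewer than two alleles; consolidation needs polymorphic markers",
      names(per)[n_alleles < 2L][1]))
  }
  in_keys <- allele_key(per)
  if (anyDuplicated(in_keys)) {
    abort(sprintf("markers '%s' and '%s' in the incoming set have identical allele sets",
                  names(per)[duplicated(in_keys)][1],
                  names(per)[in_keys == in_keys[duplicated(in_keys)][1]][1]))
  }
  ex_keys <- allele_key(lapply(db$tag_sequence, expand_merged))
  ord <- order(ex_keys, method = "radix")
  sorted_keys <- ex_keys[ord]
  # allele-level map for the conflict report
  ex_alleles <- lapply(db$tag_sequence, expand_merged)
  allele_owner <- tibble(
    sequence = as.character(unlist(ex_alleles)),
    universal_name = rep(db$universal_name, lengths(ex_alleles))
  )
  if (!project %in% names(db)) db[[project]] <- NA_character_
  conflicts <- attr(db, "conflicts")
  next_n <- if (nrow(db) == 0L) 1L else {
    max(as.integer(sub(paste0("^", prefix), "", db$universal_name))) + 1L
  }
  new_rows <- list()
  for (i in seq_along(per)) {
    pos <- bisect_find(sorted_keys, in_keys[i])
    if (pos > 0L) {
      j <- ord[pos]
      db[[project]][j] <- names(per)[i]
    } else {
      shared <- allele_owner[allele_owner$sequence %in% per[[i]], ,
                             drop = FALSE]
      uname <- universal_name(prefix, next_n)
      next_n <- next_n + 1L
      if (nrow(shared)) {
        conflicts <- bind_rows(conflicts, tibble(
          project = project, marker = names(per)[i],
          universal_name = shared$universal_name,
          shared_sequence = shared$sequence))
      }
      row <- tibble(universal_name = uname,
                    tag_sequence = render_merged(
                      merge_tags(sort(per[[i]]))),
                    chromosome = NA_character_, position = NA_integer_,
                    alignment_quality = NA_integer_)
      row[[project]] <- names(per)[i]
      new_rows[[length(new_rows) + 1L]] <- row
    }
  }
  if (length(new_rows)) {
    db <- bind_rows(db, bind_rows(new_rows))
  }
  structure(db, prefix = prefix, conflicts = conflicts,
            class = c("marker_db", class(tibble())))
}

#' Export the marker database as merged CSV
#'
#' Writes headers `"Marker name"` and `"Tag sequence"` (bracket
#' notation), optionally followed by alias and alignment columns.  The
#' file is re-importable with `read_tag_file(format = "csv_merged")`.
#'
#' @param db A `marker_db`.
#' @param path Output CSV.
#' @param extra_columns Include alias/alignment columns.
#' @export
export_merged_csv <- function(db, path, extra_columns = TRUE) {
  stopifnot(inherits(db, "marker_db"))
  out <- tibble(`Marker name` = db$universal_name,
                `Tag sequence` = db$tag_sequence)
  if (extra_columns) {
    extra <- db[setdiff(names(db), c("universal_name", "tag_sequence"))]
    keep <- vapply(extra, function(col) any(!is.na(col)), logical(1))
    out <- bind_cols(out, extra[keep])
  }
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Export marker consensus sequences as FASTA
#'
#' One record per marker named by its universal name.  At each
#' substitution site the IUPAC ambiguity code of the allele nucleotides
#' is emitted (C/T gives Y, A/T gives W, ...); markers whose alleles
#' differ in length cannot be expressed positionwise, so allele 0's full
#' sequence is written for those.
#'
#' @param db A `marker_db`.
#' @param path Output FASTA.
#' @export
export_fasta <- function(db, path) {
  stopifnot(inherits(db, "marker_db"))
  seqs <- vapply(db$tag_sequence, function(m) {
    alleles <- expand_merged(m)
    if (length(unique(nchar(alleles))) != 1L) return(alleles[1])
    chars <- strsplit(alleles, "")
    vapply(seq_len(nchar(alleles[1])), function(j) {
      nts <- unique(vapply(chars, `[`, character(1), j))
      if (length(nts) == 1L) nts else {
        Biostrings::mergeIUPACLetters(paste(sort(nts), collapse = ""))
      }
    }, character(1)) |> paste(collapse = "")
  }, character(1), USE.NAMES = FALSE)
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- db$universal_name
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Re-import an exported marker database
#'
#' Reads a CSV previously written by [export_merged_csv()] back into a
#' `marker_db`, so further projects can be consolidated against it.  The
#' universal-name prefix is inferred from the names (their common
#' non-numeric stem) unless given.
#'
#' @param path CSV with headers `"Marker name"` and `"Tag sequence"`;
#'   alias/alignment columns are restored when present.
#' @param prefix Universal-name prefix; inferred when `NULL`.
#' @return A `marker_db`.
#' @export
read_marker_db <- function(path, prefix = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = "c"))
  for (h in c("Marker name", "Tag sequence")) {
    if (!h %in% names(df)) {
      abort(sprintf("missing required column header '%s' in '%s'", h, path))
    }
  }
  stems <- unique(sub("[0-9]+$", "", df[["Marker name"]]))
  if (is.null(prefix)) {
    if (length(stems) != 1L || !nzchar(stems)) {
      abort("cannot infer a unique universal-name prefix; pass 'prefix'")
    }
    prefix <- stems
  }
  db <- tibble(universal_name = df[["Marker name"]],
               tag_sequence = df[["Tag sequence"]],
               chromosome = if ("chromosome" %in% names(df)) {
                 df$chromosome
               } else NA_character_,
               position = if ("position" %in% names(df)) {
                 as.integer(df$position)
               } else NA_integer_,
               alignment_quality = if ("alignment_quality" %in% names(df)) {
                 as.integer(df$alignment_quality)
               } else NA_integer_)
  extra <- setdiff(names(df), c("Marker name", "Tag sequence",
                                "chromosome", "position",
                                "alignment_quality"))
  for (col in extra) db[[col]] <- df[[col]]
  structure(db, prefix = prefix,
            conflicts = tibble(project = character(), marker = character(),
                               universal_name = character(),
                               shared_sequence = character()),
            class = c("marker_db", class(tibble())))
}

#' Annotate markers from a SAM alignment
#'
#' After aligning the exported FASTA to a reference, the resulting SAM
#' is read back and aligned markers gain `chromosome`, 1-based leftmost
#' `position` and `alignment_quality` (mapping quality).  Unmapped
#' records leave their marker blank; query names not in the database are
#' warned about and skipped.
#'
#' @param db A `marker_db` whose universal names were used as FASTA
#'   record names.
#' @param sam Path to the SAM file.
#' @return The annotated `marker_db`.
#' @export
annotate_from_sam <- function(db, sam) {
  stopifnot(inherits(db, "marker_db"))
  aln <- read_sam_records(sam)
  # primary alignments only
  aln <- aln[!bitwAnd(aln$flag, bitwOr(256L, 2048L)), , drop = FALSE]
  unknown <- setdiff(unique(aln$qname), db$universal_name)
  for (q in unknown) {
    warn(sprintf("SAM query name '%s' is not in the marker database; skipped", q))
  }
  aln <- aln[aln$qname %in% db$universal_name, , drop = FALSE]
  aln <- aln[!duplicated(aln$qname), , drop = FALSE]
  mapped <- aln[!bitwAnd(aln$flag, 4L), , drop = FALSE]
  idx <- match(mapped$qname, db$universal_name)
  db$chromosome[idx] <- mapped$rname
  db$position[idx] <- mapped$pos
  db$alignment_quality[idx] <- mapped$mapq
  db
}
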