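# Streaming tag counting: FASTQ files are processed record by record in
# chunks against one indexing tree of barcode+remnant concatenations and
# one of tag sequences, so memory use is independent of FASTQ size and no
# intermediate files are written.  Counts are plain integers with no
# upper cap.

FASTQ_CHUNK_LINES <- 400000L  # 100,000 reads per chunk

#' Read a counting key file
#'
#' The key file binds FASTQ files and in-line barcodes to sample names.
#' Required headers are `"File"`, `"Barcode"` and `"Sample"`; other
#' columns are ignored.  File names ending in `".gz"` are decompressed on
#' the fly.  A blank barcode is allowed only when it is the sole row for
#' that file (already-demultiplexed FASTQ, one sample per file).  The
#' same sample name may appear on several rows; its counts are summed.
#'
#' @param path Key CSV file.  Relative `File` entries are resolved
#'   against the key file's directory.
#' @param enzyme Optional enzyme (name or object).  When given, barcode
#'   ambiguity is checked at the barcode+remnant level: no concatenation
#'   may be a prefix of another within one file.
#' @return A `key_file` tibble with columns `file`, `barcode`, `sample`
#'   and resolved `path`.
#' @export
read_key_file <- function(path, enzyme = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = "c"))
  for (h in c("File", "Barcode", "Sample")) {
    if (!h %in% names(df)) {
      abort(sprintf("missing required column header '%s' in '%s'", h, path))
    }
  }
  key <- tibble(file = df$File,
                barcode = toupper(ifelse(is.na(df$Barcode), "", df$Barcode)),
                sample = df$Sample)
  key$path <- ifelse(grepl("^(/|[A-Za-z]:)", key$file), key$file,
                     file.path(dirname(path), key$file))
  validate_key(key, enzyme)
  structure(key, class = c("key_file", class(tibble())))
}

validate_key <- function(key, enzyme = NULL) {
  bad <- which(!(key$barcode == "" | is_dna(key$barcode)))
  if (length(bad)) {
    abort(sprintf("barcode '%s' contains characters other than A/C/G/T",
                  key$barcode[bad[1]]))
  }
  for (f in unique(key$file)) {
    bc <- key$barcode[key$file == f]
    if (any(bc == "") && length(bc) > 1L) {
      abort(sprintf(
        "file '%s': a blank barcode must be the only row for its file", f))
    }
    if (anyDuplicated(bc)) {
      d <- bc[duplicated(bc)][1]
      abort(sprintf("file '%s': duplicate barcode '%s'", f, d))
    }
    if (!is.null(enzyme)) {
      check_barcode_ambiguity(bc, get_enzyme(enzyme), f)
    }
  }
  invisible(key)
}

# Error if any barcode+remnant concatenation is a proper prefix of
# another (reads starting with the longer one would be ambiguous only up
# to the longest-match rule; the key-file contract forbids the layout).
check_barcode_ambiguity <- function(barcodes, enzyme, file = "") {
  combos <- as.vector(outer(barcodes, enzyme$remnant_variants, paste0))
  owner <- rep(barcodes, times = length(enzyme$remnant_variants))
  o <- order(combos, method = "radix")
  combos <- combos[o]
  owner <- owner[o]
  if (length(combos) > 1L) {
    for (i in seq_len(length(combos) - 1L)) {
      if (startsWith(combos[i + 1L], combos[i]) &&
          owner[i] != owner[i + 1L]) {
        abort(sprintf(
          "%sbarcodes '%s' and '%s' are ambiguous: '%s' is a prefix of '%s'",
          if (nzchar(file)) sprintf("file '%s': ", file) else "",
          owner[i], owner[i + 1L], combos[i], combos[i + 1L]))
      }
    }
  }
  invisible(barcodes)
}

open_fastq <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, open = "rt")
  else file(path, open = "rt")
}

# Chunked FASTQ traversal: calls fn(headers, seqs, quals, first_record)
# per chunk.  Validates 4-line structure and '@' header lines.
stream_fastq <- function(path, fn, chunk_lines = FASTQ_CHUNK_LINES) {
  con <- open_fastq(path)
  on.exit(close(con), add = TRUE)
  rec0 <- 0L
  repeat {
    lines <- readLines(con, n = chunk_lines)
    if (length(lines) == 0L) break
    if (length(lines) %% 4L != 0L) {
      abort(sprintf("truncated FASTQ record in '%s' near record %d",
                    path, rec0 + length(lines) %/% 4L + 1L))
    }
    idx <- seq.int(1L, length(lines), by = 4L)
    headers <- lines[idx]
    bad <- which(!startsWith(headers, "@"))
    if (length(bad)) {
      abort(sprintf("malformed FASTQ record in '%s' at record %d",
                    path, rec0 + bad[1]))
    }
    fn(headers, lines[idx + 1L], lines[idx + 3L], rec0 + 1L)
    rec0 <- rec0 + length(idx)
    if (length(lines) < chunk_lines) break
  }
  rec0
}

# Build the per-file barcode+remnant indexing tree.  Each entry carries
# the key row it belongs to and the offset at which tag matching starts
# (after the remnant, or at the remnant for variable-site enzymes whose
# tags include it).
barcode_entries <- function(barcodes, enzyme) {
  nb <- length(barcodes)
  nv <- length(enzyme$remnant_variants)
  tibble(
    row = rep(seq_len(nb), times = nv),
    sequence = as.vector(outer(barcodes, enzyme$remnant_variants, paste0)),
    tag_start = rep(nchar(barcodes), times = nv) +
      if (enzyme$tags_include_remnant) 0L
      else rep(nchar(enzyme$remnant_variants), each = nb)
  )
}

#' Count tag occurrences per sample
#'
#' For each read: the barcode tree is walked from position 1; a read
#' beginning with an expected barcode followed by the expected cut-site
#' remnant proceeds to the tag tree, which is walked from the first base
#' after the remnant (or from the remnant itself for variable-site
#' enzymes).  A full two-stage match increments exactly one
#' (sample, tag) cell by 1; reads failing either stage are tallied as
#' discarded.  Counts for duplicate sample names are pooled.
#'
#' @param key A `key_file` (or a data frame with columns `file`,
#'   `barcode`, `sample` and optionally `path`).
#' @param tags A sanitized `tag_set` (no allele sequence may be shared
#'   between markers; see [sanitize_tag_set()]).
#' @param enzyme Enzyme name or `gbs_enzyme` object.
#' @param progress Print a progress line per FASTQ file.
#' @return A `tag_counts` tibble: column `sample`, then one integer
#'   column per tag (markers in tag-set order, alleles in allele order).
#'   Attributes: `discards` (per-file read tallies) and `tag_info`.
#' @export
count_tags <- function(key, tags, enzyme, progress = FALSE) {
  enzyme <- get_enzyme(enzyme)
  stopifnot(inherits(tags, "tag_set"))
  if (!is.data.frame(key)) abort("'key' must be a data frame")
  if (!"path" %in% names(key)) key$path <- key$file
  key$barcode <- toupper(ifelse(is.na(key$barcode), "", key$barcode))
  validate_key(key, enzyme)
  if (nrow(tags) == 0L) abort("the tag set is empty")
  if (anyDuplicated(tags$sequence)) {
    abort("tag set has duplicate sequences; run sanitize_tag_set() first")
  }
  samples <- unique(key$sample)
  sample_of_row <- match(key$sample, samples)
  n_tags <- nrow(tags)
  tagtrie <- seq_trie(tags$sequence, seq_len(n_tags))
  counts <- integer(length(samples) * n_tags)
  discards <- list()
  for (f in unique(key$file)) {
    rows <- which(key$file == f)
    ent <- barcode_entries(key$barcode[rows], enzyme)
    btrie <- seq_trie(ent$sequence, seq_len(nrow(ent)))
    fpath <- key$path[rows[1]]
    if (!file.exists(fpath)) {
      abort(sprintf("FASTQ file not found: '%s'", fpath))
    }
    total <- 0L
    matched <- 0L
    nrec <- stream_fastq(fpath, function(headers, seqs, quals, rec1) {
      bm <- trie_match(btrie, seqs)
      ok1 <- which(!is.na(bm$payload))
      if (length(ok1)) {
        e <- bm$payload[ok1]
        tails <- stringr::str_sub(seqs[ok1], ent$tag_start[e] + 1L)
        tm <- trie_match(tagtrie, tails)
        ok2 <- which(!is.na(tm$payload))
        if (length(ok2)) {
          s_i <- sample_of_row[rows[ent$row[e[ok2]]]]
          t_i <- tm$payload[ok2]
          counts <<- counts + tabulate((s_i - 1L) * n_tags + t_i,
                                       nbins = length(counts))
          matched <<- matched + length(ok2)
        }
      }
      total <<- total + length(seqs)
    })
    discards[[length(discards) + 1L]] <-
      tibble(file = f, reads = total, matched = matched,
             discarded = total - matched)
    if (progress) {
      message(sprintf("%s: %d reads, %d matched", f, total, matched))
    }
  }
  mat <- matrix(counts, nrow = length(samples), ncol = n_tags,
                byrow = TRUE)
  colnames(mat) <- tags$tag_name
  out <- bind_cols(tibble(sample = samples), as_tibble(mat))
  structure(out,
            discards = bind_rows(discards),
            tag_info = tibble(marker = tags$marker, allele = tags$allele,
                              tag_name = tags$tag_name),
            class = c("tag_counts", class(tibble())))
}

#' Per-file read tallies from a counting or splitting run
#'
#' @param x A `tag_counts` or split result.
#' @return A tibble of per-file totals, matched and discarded reads.
#' @export
read_tallies <- function(x) {
  attr(x, "discards")
}

#' Write / read the counts table
#'
#' The CSV has tag names in the first row and sample names in the first
#' column; cells are plain integers with no upper cap.
#'
#' @param counts A `tag_counts` tibble.
#' @param path Output CSV.
#' @return `path` (write) or a `tag_counts` tibble (read; `tag_info` is
#'   reconstructed by parsing the tag column names).
#' @export
write_counts_csv <- function(counts, path) {
  df <- as_tibble(counts)
  names(df)[1] <- "Sample"
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_counts_csv
#' @export
read_counts_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  names(df)[1] <- "sample"
  for (j in seq_along(df)[-1]) df[[j]] <- as.integer(df[[j]])
  parsed <- parse_tag_column(names(df)[-1])
  structure(df,
            tag_info = tibble(marker = parsed$marker,
                              allele = parsed$allele,
                              tag_name = names(df)[-1]),
            class = c("tag_counts", class(tibble())))
}

#' Call numeric diploid genotypes from read counts
#'
#' Defined when every marker is biallelic.  With per-sample allele
#' counts `(c0, c1)`: both positive is heterozygous `1`; only allele
#' `"0"` seen is `0`; only allele `"1"` seen is `2`; neither seen is
#' missing (`NA`, exported blank).  Optionally, homozygous calls whose
#' total depth is below `min_depth` are additionally blanked, since an
#' under-sampled heterozygote is indistinguishable from a homozygote at
#' low depth; the default (`0`) applies no depth filter.
#'
#' @param counts A `tag_counts` tibble.
#' @param tags Optional `tag_set`; defaults to the `tag_info` attribute.
#' @param min_depth Minimum total read depth for a homozygous call.
#' @return A `tag_genotypes` tibble: `sample` column plus one integer
#'   column per marker.
#' @export
call_genotypes <- function(counts, tags = NULL, min_depth = 0L) {
  info <- if (!is.null(tags)) {
    tibble(marker = tags$marker, allele = tags$allele,
           tag_name = tags$tag_name)
  } else {
    attr(counts, "tag_info")
  }
  if (is.null(info)) abort("no tag information available for 'counts'")
  n_per <- table(factor(info$marker, levels = unique(info$marker)))
  bad <- names(n_per)[n_per != 2L]
  if (length(bad)) {
    abort(sprintf("marker '%s' is not biallelic; genotypes are defined only for biallelic markers",
                  bad[1]))
  }
  markers <- unique(info$marker)
  out <- tibble(sample = counts$sample)
  for (mk in markers) {
    cols <- info$tag_name[info$marker == mk]
    c0 <- counts[[cols[1]]]
    c1 <- counts[[cols[2]]]
    g <- dplyr::case_when(
      c0 > 0 & c1 > 0 ~ 1L,
      c0 > 0 & c1 == 0 ~ 0L,
      c0 == 0 & c1 > 0 ~ 2L,
      TRUE ~ NA_integer_
    )
    if (min_depth > 0L) {
      g[!is.na(g) & g != 1L & (c0 + c1) < min_depth] <- NA_integer_
    }
    out[[mk]] <- g
  }
  structure(out, class = c("tag_genotypes", class(tibble())))
}

#' Write the genotype table
#'
#' Samples in rows, markers in columns, cells `0`/`1`/`2`; missing data
#' left blank.
#'
#' @param genotypes A `tag_genotypes` tibble.
#' @param path Output CSV.
#' @export
write_genotypes_csv <- function(genotypes, path) {
  df <- as_tibble(genotypes)
  names(df)[1] <- "Sample"
  readr::write_csv(df, path, na = "", progress = FALSE)
  invisible(path)
}

#' Export the SNP-name correspondence table
#'
#' Alignment-based pipelines may mine several SNPs from one aligned tag
#' locus; markers imported from their SAM output are renamed by
#' alignment coordinate, and this table records how the original SNP
#' names map onto the new marker names.
#'
#' @param tags A `tag_set` imported with `format = "tassel_sam"`.
#' @param path Output CSV with headers `"SNP name"`, `"Marker name"`.
#' @export
write_tassel_name_table <- function(tags, path) {
  nt <- name_table(tags)
  if (is.null(nt) || nrow(nt) == 0L) {
    abort("this tag set retains no original SNP names (import it from an alignment SAM)")
  }
  nt <- distinct(nt)
  if (anyDuplicated(nt$original_name)) {
    nt <- nt[!duplicated(nt$original_name), , drop = FALSE]
  }
  readr::write_csv(
    tibble(`SNP name` = nt$original_name, `Marker name` = nt$marker),
    path, progress = FALSE)
  invisible(path)
}
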