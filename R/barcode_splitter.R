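# Demultiplexing: split multiplexed FASTQ by barcode into per-sample
# uncompressed FASTQ with the barcode removed (cut-site remnant
# retained), potentially chimeric sequence truncated after the leftmost
# internal full cut site, adapter read-through trimmed from the 3' end,
# the barcode recorded at the end of the comment field, and an optional
# MD5 manifest for archive deposit.

#' Read a splitting key file
#'
#' Required headers are `"Input File"`, `"Barcode"` and `"Output File"`.
#' Barcodes must be unique within an input file (a blank barcode only as
#' the sole row for its file), and output paths must be unique.
#'
#' @param path Key CSV file.  Relative `Input File` entries are resolved
#'   against the key file's directory.
#' @return A `split_key` tibble with columns `input`, `barcode`,
#'   `output` and resolved `path`.
#' @export
read_split_key <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = "c"))
  for (h in c("Input File", "Barcode", "Output File")) {
    if (!h %in% names(df)) {
      abort(sprintf("missing required column header '%s' in '%s'", h, path))
    }
  }
  key <- tibble(
    input = df[["Input File"]],
    barcode = toupper(ifelse(is.na(df$Barcode), "", df$Barcode)),
    output = df[["Output File"]]
  )
  key$path <- ifelse(grepl("^(/|[A-Za-z]:)", key$input), key$input,
                     file.path(dirname(path), key$input))
  validate_split_key(key)
  structure(key, class = c("split_key", class(tibble())))
}

validate_split_key <- function(key) {
  if (anyDuplicated(key$output)) {
    abort(sprintf("duplicate output file '%s'",
                  key$output[duplicated(key$output)][1]))
  }
  for (f in unique(key$input)) {
    bc <- key$barcode[key$input == f]
    if (any(bc == "") && length(bc) > 1L) {
      abort(sprintf(
        "file '%s': a blank barcode must be the only row for its file", f))
    }
    if (anyDuplicated(bc)) {
      abort(sprintf("file '%s': duplicate barcode '%s'",
                    f, bc[duplicated(bc)][1]))
    }
  }
  invisible(key)
}

#' Split FASTQ files by barcode
#'
#' Each read matching a barcode + cut-site remnant is written to that
#' barcode's output file with, in order: (1) the barcode removed from
#' the sequence start (the remnant is retained, so downstream tools —
#' and blank-barcode counting — see the expected read start), (2) the
#' sequence truncated after the leftmost full restriction site found at
#' or after the first post-remnant position (the site itself is kept),
#' (3) the 3' end truncated at the adapter start if adapter content is
#' found from the end of the read, (4) the quality string cut to the
#' same length, and (5) the barcode appended to the end of the comment
#' (a `1:N:0:<barcode>` comment is created when the header has none; a
#' blank barcode adds nothing, which makes re-splitting idempotent).
#' Unmatched reads are dropped and tallied.  Outputs are uncompressed
#' FASTQ.
#'
#' @param key A `split_key` (or data frame with columns `input`,
#'   `barcode`, `output`, optionally `path`).
#' @param enzyme Enzyme name or `gbs_enzyme`.
#' @param adapters Adapter set (name, object or sequences).
#' @param min_overlap Minimum read/adapter overlap for 3' trimming.
#' @param outdir Directory where relative output paths are created.
#' @param progress Print a progress line per input file.
#' @return A tibble of per-output read tallies (`output`, `barcode`,
#'   `reads`), with attribute `unmatched` (per-input tallies of dropped
#'   reads) and `total` reads seen.
#' @export
split_fastq <- function(key, enzyme, adapters = "illumina_truseq",
                        min_overlap = 6L, outdir = ".",
                        progress = FALSE) {
  enzyme <- get_enzyme(enzyme)
  adapters <- get_adapters(adapters)
  if (!is.data.frame(key)) abort("'key' must be a data frame")
  if (!"path" %in% names(key)) key$path <- key$input
  key$barcode <- toupper(ifelse(is.na(key$barcode), "", key$barcode))
  validate_split_key(key)
  out_path <- ifelse(grepl("^(/|[A-Za-z]:)", key$output), key$output,
                     file.path(outdir, key$output))
  n_out <- integer(nrow(key))
  unmatched <- list()
  total_reads <- 0L
  for (op in out_path) {
    dir.create(dirname(op), showWarnings = FALSE, recursive = TRUE)
    file.create(op)  # truncate
  }
  for (f in unique(key$input)) {
    rows <- which(key$input == f)
    ent <- barcode_entries(key$barcode[rows], enzyme)
    bc_len <- nchar(key$barcode[rows])
    btrie <- seq_trie(ent$sequence, seq_len(nrow(ent)))
    fpath <- key$path[rows[1]]
    if (!file.exists(fpath)) {
      abort(sprintf("FASTQ file not found: '%s'", fpath))
    }
    total <- 0L
    kept <- 0L
    stream_fastq(fpath, function(headers, seqs, quals, rec1) {
      nbad <- which(nchar(seqs) != nchar(quals))
      if (length(nbad)) {
        abort(sprintf(
          "malformed FASTQ record in '%s' at record %d: sequence and quality lengths differ",
          fpath, rec1 + nbad[1] - 1L))
      }
      bm <- trie_match(btrie, seqs)
      hit <- which(!is.na(bm$payload))
      total <<- total + length(seqs)
      if (!length(hit)) return(invisible())
      e <- bm$payload[hit]
      row_i <- ent$row[e]                 # index into rows
      blen <- bc_len[row_i]
      rem_len <- bm$consumed[hit] - blen
      seq1 <- stringr::str_sub(seqs[hit], blen + 1L)
      # chimera: truncate after the leftmost full site past the remnant
      cs <- find_full_cut_site(seq1, enzyme$full_sites,
                               search_from = rem_len + 1L)
      keep1 <- ifelse(is.na(cs$position), nchar(seq1),
                      cs$position + nchar(cs$site) - 1L)
      seq2 <- stringr::str_sub(seq1, 1L, keep1)
      # adapter: trim from the 3' end
      ad <- find_adapter_trim(seq2, adapters, min_overlap)
      keep2 <- ifelse(is.na(ad), nchar(seq2), ad - 1L)
      seq_out <- stringr::str_sub(seq2, 1L, keep2)
      qual_out <- stringr::str_sub(quals[hit], blen + 1L, blen + keep2)
      hdr_out <- annotate_header(headers[hit], key$barcode[rows][row_i])
      grp <- split(seq_along(hit), row_i)
      for (g in names(grp)) {
        ri <- as.integer(g)
        sel <- grp[[g]]
        block <- as.vector(rbind(hdr_out[sel], seq_out[sel], "+",
                                 qual_out[sel]))
        con <- file(out_path[rows[ri]], open = "at")
        writeLines(block, con)
        close(con)
        n_out[rows[ri]] <<- n_out[rows[ri]] + length(sel)
      }
      kept <<- kept + length(hit)
    })
    unmatched[[length(unmatched) + 1L]] <-
      tibble(input = f, reads = total, unmatched = total - kept)
    total_reads <- total_reads + total
    if (progress) {
      message(sprintf("%s: %d reads, %d assigned", f, total, kept))
    }
  }
  structure(
    tibble(output = key$output, barcode = key$barcode, reads = n_out),
    unmatched = bind_rows(unmatched),
    total = total_reads,
    class = c("split_tally", class(tibble()))
  )
}

# Append ":"+barcode to an existing comment, or create an Illumina-style
# "1:N:0:"+barcode comment when the header has none.  A blank barcode
# leaves the header untouched.
annotate_header <- function(headers, barcodes) {
  has_comment <- grepl("[ \t]", headers)
  out <- headers
  nz <- barcodes != ""
  out[nz & has_comment] <- paste0(headers[nz & has_comment], ":",
                                  barcodes[nz & has_comment])
  out[nz & !has_comment] <- paste0(headers[nz & !has_comment],
                                   " 1:N:0:", barcodes[nz & !has_comment])
  out
}

#' MD5 manifest for output files
#'
#' One row per file with its 32-hexadecimal-digit MD5 digest of the file
#' bytes, as required when depositing reads in a public archive.
#'
#' @param paths Files to digest.
#' @param out Optional CSV path to write the manifest to.
#' @return A tibble with columns `file` (base name) and `md5`.
#' @export
md5_manifest <- function(paths, out = NULL) {
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    abort(sprintf("file not found: '%s'", missing[1]))
  }
  digests <- unname(tools::md5sum(paths))
  df <- tibble(file = basename(paths), md5 = digests)
  if (!is.null(out)) {
    readr::write_csv(df, out, progress = FALSE)
  }
  df
}
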