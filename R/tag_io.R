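# Readers for the seven tag-set dialects, the marker-subset filter, the
# shared-allele sanitizer, and the merged-CSV writer.
#
# Column headers in the CSV dialects are matched case-sensitively and
# exactly: "Marker name", "Tag sequence 0", "Tag sequence 1",
# "Allele name", "Tag sequence".

TAG_FORMATS <- c("csv_merged", "csv_two_tags", "csv_one_per_row",
                 "uneak_fasta", "tassel_sam", "stacks_catalog",
                 "pyrad_alleles")

#' Read a tag set
#'
#' Imports marker/tag definitions from any of seven dialects: three CSV
#' layouts (`csv_two_tags` with one biallelic marker per row,
#' `csv_one_per_row` allowing non-biallelic markers with verbatim allele
#' names, and `csv_merged` with bracket notation), paired-tag FASTA
#' (`uneak_fasta`), the alignment SAM used for reference-based marker
#' generation (`tassel_sam`), a catalog of consensus sequences plus SNP
#' and haplotype files (`stacks_catalog`), and locus allele blocks
#' (`pyrad_alleles`).
#'
#' Allele order: `csv_two_tags` fixes allele 0/1 by column, and
#' `csv_one_per_row` and `csv_merged` by row/bracket order; the other
#' formats order alleles alphabetically (first alphabetically = allele
#' `"0"`).  All sequences are uppercased on ingest.
#'
#' @param path Input file.  For `stacks_catalog` this is the catalog tags
#'   file; the companion SNP and allele files are found by substituting
#'   `"snps"` and `"alleles"` for `"tags"` in its name.
#' @param format One of `r paste0('"', TAG_FORMATS, '"', collapse = ", ")`.
#' @return A [tag_set()].  For `tassel_sam` the original SNP/query names
#'   are retained and available via [name_table()].
#' @export
read_tag_file <- function(path, format = TAG_FORMATS) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(sprintf("tag file not found: '%s'", path))
  }
  switch(format,
    csv_merged = read_tags_csv_merged(path),
    csv_two_tags = read_tags_csv_two(path),
    csv_one_per_row = read_tags_csv_one(path),
    uneak_fasta = read_tags_uneak(path),
    tassel_sam = read_tags_tassel_sam(path),
    stacks_catalog = read_tags_stacks(path),
    pyrad_alleles = read_tags_pyrad(path)
  )
}

read_csv_checked <- function(path, required) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        progress = FALSE,
                        col_types = readr::cols(.default = "c"))
  for (h in required) {
    if (!h %in% names(df)) {
      abort(sprintf("missing required column header '%s' in '%s'", h, path))
    }
  }
  if (nrow(df) == 0L) {
    abort(sprintf("tag file '%s' contains no rows", path))
  }
  df
}

check_seq_rows <- function(seqs, path, allow_merged = FALSE) {
  pat <- if (allow_merged) {
    "^[ACGTacgt]*(\\[[ACGTacgt]*(/[ACGTacgt]*)+\\])?[ACGTacgt]+$|^[ACGTacgt]*(\\[[ACGTacgt]*(/[ACGTacgt]*)+\\])[ACGTacgt]*$"
  } else {
    "^[ACGTacgt]+$"
  }
  bad <- which(is.na(seqs) | !grepl(pat, seqs))
  if (length(bad)) {
    abort(sprintf("illegal tag sequence in '%s' at line %d: '%s'",
                  path, bad[1] + 1L, seqs[bad[1]]))
  }
}

read_tags_csv_merged <- function(path) {
  df <- read_csv_checked(path, c("Marker name", "Tag sequence"))
  seqs <- df[["Tag sequence"]]
  check_seq_rows(seqs, path, allow_merged = TRUE)
  rows <- purrr::map2(df[["Marker name"]], seqs, function(mk, s) {
    if (grepl("[", s, fixed = TRUE)) {
      alleles <- expand_merged(s)
    } else {
      alleles <- toupper(s)  # monomorphic marker stored unbracketed
    }
    tibble(marker = mk, allele = as.character(seq_along(alleles) - 1L),
           sequence = alleles)
  })
  tag_set(bind_rows(rows))
}

read_tags_csv_two <- function(path) {
  df <- read_csv_checked(path, c("Marker name", "Tag sequence 0",
                                 "Tag sequence 1"))
  check_seq_rows(df[["Tag sequence 0"]], path)
  check_seq_rows(df[["Tag sequence 1"]], path)
  long <- tibble(
    marker = rep(df[["Marker name"]], each = 2L),
    allele = rep(c("0", "1"), nrow(df)),
    sequence = as.vector(rbind(df[["Tag sequence 0"]],
                               df[["Tag sequence 1"]]))
  )
  tag_set(long)
}

read_tags_csv_one <- function(path) {
  df <- read_csv_checked(path, c("Marker name", "Allele name",
                                 "Tag sequence"))
  check_seq_rows(df[["Tag sequence"]], path)
  tag_set(tibble(marker = df[["Marker name"]],
                 allele = df[["Allele name"]],
                 sequence = df[["Tag sequence"]]))
}

# Paired-tag FASTA: headers ">{marker}_{query|hit}_{length}"; sequences
# are padded with poly-A to a fixed width by the producing pipeline, so
# each is truncated to the stated length before storage.
read_tags_uneak <- function(path) {
  fa <- Biostrings::readDNAStringSet(path)
  if (length(fa) == 0L) {
    abort(sprintf("tag file '%s' contains no FASTA records", path))
  }
  hdr <- names(fa)
  m <- regmatches(hdr, regexec("^(.+)_(query|hit)_(\\d+)$", hdr))
  bad <- which(lengths(m) == 0L)
  if (length(bad)) {
    abort(sprintf("cannot parse FASTA header '%s' in '%s'",
                  hdr[bad[1]], path))
  }
  marker <- vapply(m, `[`, character(1), 2)
  len <- as.integer(vapply(m, `[`, character(1), 4))
  seqs <- toupper(substr(as.character(fa), 1L, len))
  rows <- lapply(split(seqs, factor(marker, levels = unique(marker))),
                 order_alleles)
  df <- bind_rows(rows, .id = "marker")
  tag_set(df[c("marker", "allele", "sequence")])
}

# Alignment SAM from reference-based marker generation.  Records are
# grouped into markers by (reference, leftmost position, strand);
# reverse-strand records are reverse-complemented back to read
# orientation.  Original query names are retained so the SNP-name
# correspondence table can be exported.
read_tags_tassel_sam <- function(path) {
  aln <- read_sam_records(path)
  aln <- aln[!bitwAnd(aln$flag, 4L), , drop = FALSE]
  if (nrow(aln) == 0L) {
    abort(sprintf("no aligned records in SAM file '%s'", path))
  }
  rev <- bitwAnd(aln$flag, 16L) > 0L
  seqs <- aln$seq
  seqs[rev] <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(seqs[rev])))
  marker <- paste0(aln$rname, "-", aln$pos)
  # avoid a name collision if both strands align at one coordinate
  marker[rev] <- ifelse(
    paste0(marker[rev], "") %in% marker[!rev],
    paste0(marker[rev], "-rev"), marker[rev])
  keep <- !duplicated(paste0(marker, "\r", seqs))
  nt <- tibble(original_name = aln$qname[keep], marker = marker[keep])
  grp <- split(seqs[keep], factor(marker[keep], levels = unique(marker[keep])))
  rows <- lapply(grp, function(s) {
    if (length(s) < 2L) {
      tibble(allele = "0", sequence = s)
    } else {
      order_alleles(s)
    }
  })
  df <- bind_rows(rows, .id = "marker")
  tag_set(df[c("marker", "allele", "sequence")],
          name_table = distinct(nt))
}

# Catalog dialect: consensus sequences (tags file) plus SNP columns and
# haplotype strings (snps/alleles files).  Full-length allele sequences
# are reconstructed by substituting each haplotype's nucleotides at the
# recorded SNP columns (0-based) of the consensus.
read_tags_stacks <- function(path) {
  snps_path <- file.path(dirname(path), sub("tags", "snps", basename(path)))
  alleles_path <- file.path(dirname(path),
                            sub("tags", "alleles", basename(path)))
  for (p in c(snps_path, alleles_path)) {
    if (!file.exists(p)) {
      abort(sprintf("companion catalog file not found: '%s'", p))
    }
  }
  tags <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                          show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(.default = "c"))
  if (nrow(tags) == 0L) {
    abort(sprintf("tag file '%s' contains no rows", path))
  }
  cons <- tags[tags$X7 == "consensus", , drop = FALSE]
  locus <- cons$X3
  consensus <- toupper(cons$X10)
  names(consensus) <- locus
  snps <- readr::read_tsv(snps_path, col_names = FALSE, comment = "#",
                          show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(.default = "c"))
  alle <- readr::read_tsv(alleles_path, col_names = FALSE, comment = "#",
                          show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(.default = "c"))
  snp_cols <- split(as.integer(snps$X4), snps$X3)
  haps <- split(toupper(alle$X4), alle$X3)
  rows <- lapply(seq_along(consensus), function(i) {
    loc <- names(consensus)[i]
    base <- consensus[[i]]
    cols <- sort(snp_cols[[loc]])
    hp <- unique(haps[[loc]])
    hp <- hp[is_dna(hp)]
    if (is.null(cols) || length(hp) == 0L) {
      return(tibble(marker = paste0("L", loc), allele = "0",
                    sequence = base))
    }
    ok <- nchar(hp) == length(cols)
    if (any(!ok)) {
      warn(sprintf(
        "locus %s: dropped %d haplotype(s) not matching its %d SNP column(s)",
        loc, sum(!ok), length(cols)))
      hp <- hp[ok]
    }
    if (length(hp) == 0L) {
      return(tibble(marker = paste0("L", loc), allele = "0",
                    sequence = base))
    }
    seqs <- vapply(hp, function(h) {
      v <- strsplit(base, "")[[1]]
      v[cols + 1L] <- strsplit(h, "")[[1]]
      paste(v, collapse = "")
    }, character(1), USE.NAMES = FALSE)
    seqs <- unique(seqs)
    if (length(seqs) < 2L) {
      return(tibble(marker = paste0("L", loc), allele = "0",
                    sequence = seqs))
    }
    oa <- order_alleles(seqs)
    oa$marker <- paste0("L", loc)
    oa[c("marker", "allele", "sequence")]
  })
  tag_set(bind_rows(rows))
}

# Locus allele blocks: lines ">name    SEQUENCE", loci separated by lines
# starting with "//".  "-" (indel) characters are deleted so sequences
# are literal and searchable; loci with more than `max_alleles` distinct
# alleles are dropped with a warning (likely collapsed paralogs).
read_tags_pyrad <- function(path, max_alleles = 8L) {
  lines <- readLines(path)
  if (!length(lines)) {
    abort(sprintf("tag file '%s' is empty", path))
  }
  locus_end <- grepl("^//", lines)
  locus_id <- cumsum(locus_end) - locus_end + 1L
  rows <- list()
  dropped <- 0L
  for (loc in unique(locus_id[!locus_end])) {
    block <- lines[locus_id == loc & !locus_end]
    block <- block[grepl("^>", block)]
    if (!length(block)) next
    seqs <- toupper(gsub("-", "", vapply(strsplit(block, "[ \t]+"),
                                         function(p) p[length(p)],
                                         character(1)), fixed = TRUE))
    seqs <- unique(seqs[nchar(seqs) > 0L])
    bad <- which(!is_dna(seqs))
    if (length(bad)) {
      abort(sprintf("illegal tag sequence in '%s' (locus %d): '%s'",
                    path, loc, seqs[bad[1]]))
    }
    if (length(seqs) > max_alleles) {
      dropped <- dropped + 1L
      warn(sprintf("locus %d has %d distinct alleles (> %d); dropped",
                   loc, length(seqs), max_alleles))
      next
    }
    rows[[length(rows) + 1L]] <-
      if (length(seqs) < 2L) {
        tibble(marker = paste0("L", loc), allele = "0", sequence = seqs)
      } else {
        oa <- order_alleles(seqs)
        oa$marker <- paste0("L", loc)
        oa[c("marker", "allele", "sequence")]
      }
  }
  if (!length(rows)) {
    abort(sprintf("no usable loci in '%s'", path))
  }
  tag_set(bind_rows(rows))
}

#' Keep only a named subset of markers
#'
#' Restricting the tag set to the markers of interest conserves
#' processing time and output size.  Subset names absent from the tag
#' set produce warnings, not errors.
#'
#' @param tags A `tag_set`.
#' @param names Character vector of marker names to retain (order of the
#'   tag set is preserved), or the result of [read_marker_subset()].
#' @return The filtered `tag_set`.
#' @export
filter_markers <- function(tags, names) {
  stopifnot(inherits(tags, "tag_set"))
  names <- unique(as.character(names))
  known <- unique(tags$marker)
  missing <- setdiff(names, known)
  for (m in missing) {
    warn(sprintf("marker '%s' in subset is not in the tag set", m))
  }
  if (length(names) == 0L) {
    warn("empty marker subset; returning an empty tag set")
  }
  out <- tags[tags$marker %in% names, , drop = FALSE]
  new_tag_set(as_tibble(out), name_table = attr(tags, "name_table"))
}

#' @rdname filter_markers
#' @param path CSV file whose first column lists marker names (a
#'   `"Marker name"` header row, if present, is skipped).
#' @export
read_marker_subset <- function(path) {
  df <- readr::read_csv(path, col_names = FALSE, show_col_types = FALSE,
                        progress = FALSE,
                        col_types = readr::cols(.default = "c"))
  v <- df[[1]]
  unique(v[!is.na(v) & v != "Marker name"])
}

#' Remove markers that share an allele sequence
#'
#' A tag sequence occurring in more than one marker makes read
#' attribution ambiguous, so every marker involved in such a collision is
#' removed entirely (all of its alleles).  After sanitization the
#' tag-to-marker lookup is injective.
#'
#' @param tags A `tag_set`.
#' @return A list with elements `tag_set` (the cleaned set) and
#'   `discards` (tibble of removed `marker` / shared `sequence` pairs).
#' @export
sanitize_tag_set <- function(tags) {
  stopifnot(inherits(tags, "tag_set"))
  by_seq <- split(tags$marker, tags$sequence)
  shared <- names(by_seq)[vapply(by_seq, function(m) {
    length(unique(m)) > 1L
  }, logical(1))]
  if (length(shared) == 0L) {
    return(list(tag_set = tags,
                discards = tibble(marker = character(),
                                  sequence = character())))
  }
  hit <- tags$sequence %in% shared
  bad_markers <- unique(tags$marker[hit])
  discards <- distinct(tibble(marker = tags$marker[hit],
                              sequence = tags$sequence[hit]))
  keep <- !(tags$marker %in% bad_markers)
  out <- new_tag_set(as_tibble(tags[keep, , drop = FALSE]),
                     name_table = attr(tags, "name_table"))
  list(tag_set = out, discards = arrange(discards, .data$marker))
}

#' Write a tag set in merged-CSV form
#'
#' Writes headers `"Marker name"` and `"Tag sequence"`; polymorphic
#' markers are rendered in bracket notation in their stored allele
#' order, monomorphic markers as the plain sequence.  The output is
#' re-importable with `read_tag_file(format = "csv_merged")`.
#'
#' @param tags A `tag_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tag_csv <- function(tags, path) {
  stopifnot(inherits(tags, "tag_set"))
  per <- split(tags$sequence, factor(tags$marker,
                                     levels = unique(tags$marker)))
  merged <- vapply(per, function(s) {
    if (length(s) < 2L) s else render_merged(merge_tags(s))
  }, character(1))
  df <- tibble(`Marker name` = names(per), `Tag sequence` = unname(merged))
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

# Minimal SAM record access via Rsamtools (SAM -> BAM -> scanBam); only
# the fields the tag dialects need.
read_sam_records <- function(path) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "seq"))
  r <- Rsamtools::scanBam(bam, param = p)[[1]]
  tibble(qname = r$qname, flag = as.integer(r$flag),
         rname = as.character(r$rname), pos = as.integer(r$pos),
         mapq = as.integer(r$mapq), seq = as.character(r$seq))
}
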