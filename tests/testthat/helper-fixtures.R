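# Shared test helpers: tiny in-code fixtures, independent naive oracles.

tiny_tagset <- function() {
  tag_set(tibble::tibble(
    marker = c("M1", "M1", "M2", "M2"),
    allele = c("0", "1", "0", "1"),
    sequence = c("ACAGACTTAGTACCCA", "ACAGACTTTGTACCCA",
                 "CCGATTAGCAGGGGTT", "CCGATTAGTAGGGGTT")
  ))
}

write_fastq <- function(path, seqs, headers = NULL, quals = NULL) {
  if (is.null(headers)) {
    headers <- sprintf("@read%d 1:N:0:0", seq_along(seqs))
  }
  if (is.null(quals)) quals <- strrep("I", nchar(seqs))
  writeLines(as.vector(rbind(headers, seqs, "+", quals)), path)
  path
}

write_key_csv <- function(path, file, barcode, sample) {
  readr::write_csv(tibble::tibble(File = file, Barcode = barcode,
                                  Sample = sample), path)
  path
}

# Minimal valid SAM writer (reference headers from the records).
write_sam <- function(path, qname, flag, rname, pos, mapq, seq,
                      ref_len = 100000L) {
  refs <- unique(rname[rname != "*"])
  if (!length(refs)) refs <- "chr1"
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", refs, "\tLN:", ref_len))
  rec <- vapply(seq_along(qname), function(i) {
    cig <- if (bitwAnd(flag[i], 4L)) "*" else paste0(nchar(seq[i]), "M")
    rn <- if (bitwAnd(flag[i], 4L)) "*" else rname[i]
    po <- if (bitwAnd(flag[i], 4L)) 0L else pos[i]
    paste(qname[i], flag[i], rn, po, mapq[i], cig, "*", 0, 0,
          seq[i], strrep("I", nchar(seq[i])), sep = "\t")
  }, character(1))
  writeLines(c(hdr, rec), path)
  path
}

# Independent naive longest-prefix-match oracle: string-compares every
# stored sequence against the read start and keeps the longest hit.
naive_match <- function(sequences, payloads, reads) {
  ord <- order(nchar(sequences), decreasing = TRUE)
  sequences <- sequences[ord]
  payloads <- payloads[ord]
  vapply(reads, function(r) {
    for (i in seq_along(sequences)) {
      if (startsWith(r, sequences[i])) return(payloads[i])
    }
    NA_integer_
  }, integer(1), USE.NAMES = FALSE)
}

rand_reads <- function(n, len = 60L) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = "")
  }, character(1))
}

counts_matrix <- function(x) {
  m <- as.matrix(as.data.frame(x)[-1])
  rownames(m) <- x$sample
  m
}
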