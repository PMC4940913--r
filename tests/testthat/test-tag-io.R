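test_that("the three CSV dialects read with their fixed headers and orders", {
  d <- withr::local_tempdir()
  merged <- file.path(d, "merged.csv")
  writeLines(c("Marker name,Tag sequence",
               "M1,CCGATTAG[C/T]AGGGGTT",
               "M2,ACGTACGTAA"), merged)
  ts <- read_tag_file(merged, "csv_merged")
  expect_equal(nrow(ts), 3L)
  expect_equal(ts$sequence[ts$marker == "M1"],
               c("CCGATTAGCAGGGGTT", "CCGATTAGTAGGGGTT"))
  expect_equal(ts$allele[ts$marker == "M2"], "0")  # monomorphic row

  two <- file.path(d, "two.csv")
  writeLines(c("Marker name,Tag sequence 0,Tag sequence 1",
               "M1,TTTTAAAA,AAAATTTT"), two)
  ts2 <- read_tag_file(two, "csv_two_tags")
  # column order fixes allele 0/1 even against alphabetical order
  expect_equal(ts2$sequence[ts2$allele == "0"], "TTTTAAAA")

  one <- file.path(d, "one.csv")
  writeLines(c("Marker name,Allele name,Tag sequence",
               "M1,refA,ACGTACGTAC",
               "M1,altB,ACGAACGTAC",
               "M1,altC,ACGCACGTAC"), one)
  ts3 <- read_tag_file(one, "csv_one_per_row")
  expect_equal(ts3$allele, c("refA", "altB", "altC"))  # verbatim names
  expect_equal(length(unique(ts3$marker)), 1L)

  bad <- file.path(d, "bad.csv")
  writeLines(c("Marker,Tag sequence", "M1,ACGT"), bad)
  expect_error(read_tag_file(bad, "csv_merged"), "'Marker name'")
  writeLines("Marker name,Tag sequence", bad)
  expect_error(read_tag_file(bad, "csv_merged"), "no rows")
  writeLines(c("Marker name,Tag sequence", "M1,ACXT"), bad)
  expect_error(read_tag_file(bad, "csv_merged"), "line 2")
})

test_that("paired-tag FASTA headers parse and poly-A padding is stripped", {
  d <- withr::local_tempdir()
  fa <- file.path(d, "tags.fa")
  writeLines(c(">TP1_query_10", paste0("GGGGGTTTTT", strrep("A", 54)),
               ">TP1_hit_10",   paste0("GGGGGTTTTC", strrep("A", 54)),
               ">TP2_query_8",  paste0("CCCCGGGG", strrep("A", 56)),
               ">TP2_hit_8",    paste0("CCCCGGGT", strrep("A", 56))), fa)
  ts <- read_tag_file(fa, "uneak_fasta")
  expect_equal(nrow(ts), 4L)
  expect_equal(max(nchar(ts$sequence[ts$marker == "TP1"])), 10L)
  # alphabetical allele order
  expect_equal(ts$sequence[ts$marker == "TP1" & ts$allele == "0"],
               "GGGGGTTTTC")
  writeLines(c(">oddheader", "ACGT"), fa)
  expect_error(read_tag_file(fa, "uneak_fasta"), "oddheader")
})

test_that("alignment SAM import groups by coordinate and keeps original names", {
  d <- withr::local_tempdir()
  sam <- file.path(d, "tags.sam")
  t0 <- "TGCAGAAACCCGGGTTTAAA"
  t1 <- "TGCAGAAACCCGGGTTTAAC"
  write_sam(sam,
            qname = c("S1_101", "S1_102", "S2_samename", "unmapped1"),
            flag = c(0L, 0L, 16L, 4L),
            rname = c("chr1", "chr1", "chr1", "*"),
            pos = c(500L, 500L, 900L, 0L),
            mapq = c(60L, 60L, 42L, 0L),
            seq = c(t0, t1,
                    as.character(Biostrings::reverseComplement(
                      Biostrings::DNAString("TGCAGCCCCAAAATTTTGGG"))),
                    "ACGTACGTACGTACGTACGT"))
  ts <- read_tag_file(sam, "tassel_sam")
  expect_setequal(unique(ts$marker), c("chr1-500", "chr1-900"))
  expect_setequal(ts$sequence[ts$marker == "chr1-500"], c(t0, t1))
  # reverse-strand record restored to read orientation
  expect_equal(ts$sequence[ts$marker == "chr1-900"],
               "TGCAGCCCCAAAATTTTGGG")
  nt <- name_table(ts)
  expect_setequal(nt$original_name[nt$marker == "chr1-500"],
                  c("S1_101", "S1_102"))
})

test_that("catalog consensus + SNP columns + haplotypes reconstruct alleles", {
  d <- withr::local_tempdir()
  tags <- file.path(d, "catalog.tags.tsv")
  cons <- "TGCAGAACCGGTTAACCGGT"
  writeLines(paste(c("1", "0", "7", "", "", "+", "consensus", "", "",
                     cons, "0", "0", "0"), collapse = "\t"), tags)
  writeLines(c(paste(c("1", "0", "7", "5", "E", "0", "A", "T"),
                     collapse = "\t"),
               paste(c("2", "0", "7", "12", "E", "0", "T", "G"),
                     collapse = "\t")),
             file.path(d, "catalog.snps.tsv"))
  writeLines(c(paste(c("1", "0", "7", "AT", "0", "10"), collapse = "\t"),
               paste(c("2", "0", "7", "TG", "0", "12"), collapse = "\t")),
             file.path(d, "catalog.alleles.tsv"))
  ts <- read_tag_file(tags, "stacks_catalog")
  expect_equal(unique(ts$marker), "L7")
  got <- sort(ts$sequence)
  # haplotype AT at 0-based columns 5 and 12; TG likewise
  e1 <- cons; substr(e1, 6, 6) <- "A"; substr(e1, 13, 13) <- "T"
  e2 <- cons; substr(e2, 6, 6) <- "T"; substr(e2, 13, 13) <- "G"
  expect_setequal(got, c(e1, e2))
})

test_that("allele-block loci parse, indels are stripped, paralogs dropped", {
  d <- withr::local_tempdir()
  al <- file.path(d, "out.alleles")
  writeLines(c(">ind1_0   TGCAGAAA-CCC",
               ">ind1_1   TGCAGAAATCCC",
               ">ind2_0   TGCAGAAA-CCC",
               "//            |1|",
               ">ind1_0   GGGGTTTTAAAA",
               ">ind1_1   GGGGTTTTAAAC",
               "//            |2|"), al)
  ts <- read_tag_file(al, "pyrad_alleles")
  expect_equal(length(unique(ts$marker)), 2L)
  # "-" deleted: the deletion allele is literal and searchable
  expect_setequal(ts$sequence[ts$marker == "L1"],
                  c("TGCAGAAACCC", "TGCAGAAATCCC"))
  # a locus with too many distinct alleles is dropped with a warning
  many <- c(vapply(1:9, function(i) {
    s <- "AAAAAAAAAA"
    substr(s, 1, 1) <- c("A", "C", "G", "T")[i %% 4 + 1]
    substr(s, 2, 2) <- c("A", "C", "G", "T")[i %% 3 + 1]
    substr(s, 10, 10) <- c("A", "C", "G", "T")[(i %/% 4) %% 4 + 1]
    paste0(">x_", i, "  ", s)
  }, character(1)), "//")
  writeLines(c(many, ">a_0  CCCCC", ">a_1  CCCCG", "//"), al)
  expect_warning(ts2 <- read_tag_file(al, "pyrad_alleles"), "dropped")
  expect_equal(unique(ts2$marker), "L2")
})

test_that("marker subsetting preserves order and warns on unknowns", {
  set.seed(2)
  seqs <- unique(rand_reads(200, len = 30L))[1:200]
  ts <- tag_set(tibble::tibble(
    marker = rep(sprintf("M%03d", 1:100), each = 2),
    allele = rep(c("0", "1"), 100),
    sequence = seqs))
  sub <- filter_markers(ts, sprintf("M%03d", c(5, 1, 50, 99, 100,
                                               42, 7, 13, 88, 21)))
  expect_equal(length(unique(sub$marker)), 10L)
  # tag-set order, not subset order
  expect_equal(unique(sub$marker)[1], "M001")
  w <- testthat::capture_warnings(
    filter_markers(ts, c("M001", "nope1", "nope2", "nope3")))
  expect_length(w, 3L)
  expect_warning(out <- filter_markers(ts, character()), "empty")
  expect_equal(nrow(out), 0L)
})

test_that("sanitization removes every marker sharing an allele", {
  ts <- tag_set(tibble::tibble(
    marker = c("M1", "M1", "M2", "M2", "M3", "M3"),
    allele = rep(c("0", "1"), 3),
    sequence = c("ACGT", "ACGG", "ACGT", "TTTT", "GGGG", "GGGA")))
  res <- sanitize_tag_set(ts)
  expect_setequal(unique(res$tag_set$marker), "M3")
  expect_setequal(res$discards$marker, c("M1", "M2"))
  expect_equal(unique(res$discards$sequence), "ACGT")
  # disjoint sets untouched
  clean <- sanitize_tag_set(res$tag_set)
  expect_identical(nrow(clean$discards), 0L)

  # planted collisions vs brute-force pairwise-overlap oracle
  set.seed(77)
  for (rep in 1:10) {
    n <- 40L
    seqs <- unique(rand_reads(2L * n + 10L, len = 16L))[1:(2L * n)]
    mk <- rep(sprintf("K%02d", 1:n), each = 2)
    k <- sample(0:5, 1)
    if (k > 0) {
      victims <- sample(seq(2, 2 * n, by = 2), k)
      donors <- sample(seq(1, 2 * n, by = 2), k)
      ok <- mk[victims] != mk[donors]
      seqs[victims[ok]] <- seqs[donors[ok]]
    }
    tt <- tibble::tibble(marker = mk, allele = rep(c("0", "1"), n),
                         sequence = seqs)
    tt <- tt[!duplicated(paste(tt$marker, tt$sequence)), ]
    ts2 <- tag_set(tt)
    res2 <- sanitize_tag_set(ts2)
    # oracle: all-against-all marker pairs sharing any sequence
    bad <- character()
    for (a in unique(tt$marker)) for (b in unique(tt$marker)) {
      if (a < b && length(intersect(tt$sequence[tt$marker == a],
                                    tt$sequence[tt$marker == b]))) {
        bad <- c(bad, a, b)
      }
    }
    expect_setequal(setdiff(unique(tt$marker),
                            unique(res2$tag_set$marker)),
                    unique(bad))
    expect_false(anyDuplicated(res2$tag_set$sequence) > 0)
  }
})

test_that("every reader round-trips through the merged-CSV writer", {
  d <- withr::local_tempdir()
  set.seed(19)
  sp <- fixture_spec(n_samples = 4, n_markers = 25, depth_mean = 2,
                     seed = 19)
  fx <- generate_fixture(sp, dir = d)
  ts <- read_tag_file(fx$tags_csv, "csv_merged")
  out <- file.path(d, "rt.csv")
  write_tag_csv(ts, out)
  ts2 <- read_tag_file(out, "csv_merged")
  expect_identical(as.data.frame(ts), as.data.frame(ts2))
  # content (marker -> allele-sequence set) survives for other dialects
  one <- file.path(d, "one.csv")
  writeLines(c("Marker name,Allele name,Tag sequence",
               "MM,ref,ACGTACGTAC",
               "MM,alt,ACGAACGTAC"), one)
  ts3 <- read_tag_file(one, "csv_one_per_row")
  write_tag_csv(ts3, out)
  ts4 <- read_tag_file(out, "csv_merged")
  expect_identical(ts4$sequence, ts3$sequence)
  expect_identical(unique(ts4$marker), unique(ts3$marker))
})
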