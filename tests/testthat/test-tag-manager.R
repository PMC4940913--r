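make_pair_set <- function(markers, tag0, tag1) {
  tag_set(tibble::tibble(marker = rep(markers, each = 2),
                         allele = rep(c("0", "1"), length(markers)),
                         sequence = as.vector(rbind(tag0, tag1))))
}

test_that("exact allele-set matches merge; truncations never do", {
  tsA <- make_pair_set(c("a1", "a2"),
                       c("TGCAGAAACCCGGTA", "TGCAGTTTTCCGGTA"),
                       c("TGCAGAAACCCGGTT", "TGCAGTTTTCCGGTT"))
  db <- consolidate(NULL, tsA, project = "projA", prefix = "MyLabsTags")
  expect_equal(db$universal_name,
               c("MyLabsTags000001", "MyLabsTags000002"))
  # same tag pair under another name in a second project -> one record
  tsB <- make_pair_set("b_somename",
                       "TGCAGAAACCCGGTA", "TGCAGAAACCCGGTT")
  db2 <- consolidate(db, tsB, project = "projB")
  expect_equal(nrow(db2), 2L)
  expect_equal(db2$projB[db2$universal_name == "MyLabsTags000001"],
               "b_somename")
  expect_equal(db2$projA[db2$universal_name == "MyLabsTags000001"], "a1")
  # truncated versions of both alleles are a different marker
  tsC <- make_pair_set("c_trunc", "TGCAGAAACCCGG", "TGCAGAAACCCGT")
  db3 <- consolidate(db2, tsC, project = "projC")
  expect_equal(nrow(db3), 3L)
  # prefix is pinned for the database's lifetime
  expect_error(consolidate(db3, tsB, project = "projD",
                           prefix = "Other"), "prefix")
  # single-allele markers violate the contract
  bad <- tag_set(tibble::tibble(marker = "solo", allele = "0",
                                sequence = "ACGTACGT"))
  expect_error(consolidate(db3, bad, project = "projE"), "solo")
})

test_that("partial allele overlap is reported as a conflict, not merged", {
  tsA <- make_pair_set("a", "TGCAGAAAACCCC", "TGCAGAAAACCCT")
  db <- consolidate(NULL, tsA, "p1", prefix = "U")
  tsB <- make_pair_set("b", "TGCAGAAAACCCC", "TGCAGAAAACCCG")
  db2 <- consolidate(db, tsB, "p2")
  expect_equal(nrow(db2), 2L)  # new record, no merge
  cf <- db_conflicts(db2)
  expect_equal(cf$marker, "b")
  expect_equal(cf$universal_name, "U000001")
  expect_equal(cf$shared_sequence, "TGCAGAAAACCCC")
})

test_that("binary-search merging agrees with a quadratic oracle on planted overlaps", {
  set.seed(123)
  n_a <- 400L; n_b <- 300L; n_shared <- 60L
  pool <- unique(rand_reads(2L * (n_a + n_b) + 200L, len = 30L))
  t0a <- pool[1:n_a]; t1a <- pool[(n_a + 1):(2 * n_a)]
  t0b <- c(t0a[1:n_shared], pool[(2 * n_a + 1):(2 * n_a + n_b - n_shared)])
  t1b <- c(t1a[1:n_shared],
           pool[(2 * n_a + n_b - n_shared + 1):(2 * n_a + 2 * n_b - 2 * n_shared)])
  tsA <- make_pair_set(sprintf("A%03d", 1:n_a), t0a, t1a)
  tsB <- make_pair_set(sprintf("B%03d", 1:n_b), t0b, t1b)
  db <- consolidate(NULL, tsA, "A", prefix = "U")
  db2 <- consolidate(db, tsB, "B")
  expect_equal(nrow(db2), n_a + n_b - n_shared)
  # quadratic all-pairs set-equality oracle
  keyA <- vapply(seq_len(n_a), function(i) {
    paste(sort(c(t0a[i], t1a[i])), collapse = ";")
  }, character(1))
  keyB <- vapply(seq_len(n_b), function(i) {
    paste(sort(c(t0b[i], t1b[i])), collapse = ";")
  }, character(1))
  merged_oracle <- vapply(keyB, function(k) any(keyA == k), logical(1))
  expect_equal(sum(merged_oracle), n_shared)
  got_merged <- !is.na(db2$A) & !is.na(db2$B)
  expect_equal(sum(got_merged), n_shared)
  # alias pairs match the oracle exactly
  oracle_pairs <- sort(paste(sprintf("A%03d", which(keyA %in% keyB)),
                             sprintf("B%03d", match(keyA[keyA %in% keyB],
                                                    keyB))))
  got_pairs <- sort(paste(db2$A[got_merged], db2$B[got_merged]))
  expect_equal(got_pairs, oracle_pairs)
})

test_that("consolidation is stable across project order and idempotent", {
  set.seed(7)
  pool <- unique(rand_reads(60, len = 25L))
  tsA <- make_pair_set(sprintf("A%d", 1:10), pool[1:10], pool[11:20])
  tsB <- make_pair_set(sprintf("B%d", 1:10),
                       c(pool[1:5], pool[21:25]),
                       c(pool[11:15], pool[26:30]))
  ab <- consolidate(consolidate(NULL, tsA, "A", prefix = "U"), tsB, "B")
  ba <- consolidate(consolidate(NULL, tsB, "B", prefix = "U"), tsA, "A")
  key <- function(db) {
    k <- vapply(db$tag_sequence,
                function(m) paste(sort(expand_merged(m)), collapse = ";"),
                character(1), USE.NAMES = FALSE)
    df <- tibble::tibble(k = k, A = db$A, B = db$B)
    df[order(df$k), ]
  }
  expect_equal(key(ab), key(ba))
  # idempotent re-consolidation of a seen project
  again <- consolidate(ab, tsB, "B")
  expect_equal(as.data.frame(again), as.data.frame(ab))
})

test_that("merged CSV export round-trips and uses padded universal names", {
  d <- withr::local_tempdir()
  ts <- make_pair_set("orig", "CCGATTAGCAGGGGTT", "CCGATTAGTAGGGGTT")
  db <- consolidate(NULL, ts, "p1", prefix = "MyLabsTags")
  p <- file.path(d, "db.csv")
  export_merged_csv(db, p)
  lines <- readLines(p)
  expect_equal(lines[1], "Marker name,Tag sequence,p1")
  expect_equal(lines[2], "MyLabsTags000001,CCGATTAG[C/T]AGGGGTT,orig")
  back <- read_tag_file(p, "csv_merged")
  expect_setequal(back$sequence, ts$sequence)
  # empty database -> header-only file
  export_merged_csv(marker_db("X"), p)
  expect_equal(readLines(p), "Marker name,Tag sequence")
})

test_that("an exported database re-imports and accepts further projects", {
  d <- withr::local_tempdir()
  tsA <- make_pair_set(c("a1", "a2"),
                       c("TGCAGAAACCCGGTA", "TGCAGTTTTCCGGTA"),
                       c("TGCAGAAACCCGGTT", "TGCAGTTTTCCGGTT"))
  db <- consolidate(NULL, tsA, "projA", prefix = "MyLabsTags")
  p <- file.path(d, "db.csv")
  export_merged_csv(db, p)
  back <- read_marker_db(p)
  expect_equal(db_prefix(back), "MyLabsTags")
  expect_equal(back$universal_name, db$universal_name)
  expect_equal(back$tag_sequence, db$tag_sequence)
  tsB <- make_pair_set("b1", "TGCAGAAACCCGGTA", "TGCAGAAACCCGGTT")
  db2 <- consolidate(back, tsB, "projB")
  expect_equal(nrow(db2), 2L)
  expect_equal(db2$projB[1], "b1")
  expect_equal(db2$projA[1], "a1")  # alias column restored
})

test_that("FASTA export writes IUPAC codes at variable sites", {
  d <- withr::local_tempdir()
  ts <- make_pair_set(c("m1", "m2"),
                      c("CCGATTAGCAGGGGTT", "TGCAGGGACCCTTTAA"),
                      c("CCGATTAGTAGGGGTT", "TGCAGGGTCCCTTTAA"))
  db <- consolidate(NULL, ts, "p", prefix = "U")
  p <- file.path(d, "db.fa")
  export_fasta(db, p)
  fa <- Biostrings::readBStringSet(p)
  expect_equal(length(fa), 2L)
  seqs <- as.character(fa)
  names(seqs) <- names(fa)
  expect_equal(unname(seqs["U000001"]), "CCGATTAGYAGGGGTT")  # C/T -> Y
  expect_equal(unname(seqs["U000002"]), "TGCAGGGWCCCTTTAA")  # A/T -> W
  # unequal allele lengths fall back to allele 0's full sequence
  ts2 <- make_pair_set("indel", "ACGTT", "ACTT")
  db2 <- consolidate(NULL, ts2, "p", prefix = "V")
  export_fasta(db2, p)
  expect_equal(as.character(Biostrings::readBStringSet(p))[[1]], "ACGTT")
})

test_that("SAM annotation copies coordinates and skips unknown or unmapped", {
  d <- withr::local_tempdir()
  ts <- make_pair_set(c("m1", "m2"),
                      c("TGCAGAAACCCGGTAT", "TGCAGCCCCAAAGGGT"),
                      c("TGCAGAAACCCGGTAA", "TGCAGCCCCAAAGGGA"))
  db <- consolidate(NULL, ts, "p", prefix = "U")
  sam <- file.path(d, "aln.sam")
  write_sam(sam,
            qname = c("U000001", "U000002", "Unknown9"),
            flag = c(0L, 4L, 0L),
            rname = c("chr3", "*", "chr1"),
            pos = c(1234L, 0L, 1L),
            mapq = c(37L, 0L, 60L),
            seq = c("TGCAGAAACCCGGTAT", "TGCAGCCCCAAAGGGT",
                    "ACGTACGTACGTACGT"))
  expect_warning(db2 <- annotate_from_sam(db, sam), "Unknown9")
  expect_equal(db2$chromosome[db2$universal_name == "U000001"], "chr3")
  expect_equal(db2$position[db2$universal_name == "U000001"], 1234L)
  expect_equal(db2$alignment_quality[db2$universal_name == "U000001"],
               37L)
  expect_true(is.na(db2$chromosome[db2$universal_name == "U000002"]))
})
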