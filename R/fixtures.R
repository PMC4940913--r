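# Seeded synthetic-data generator: multiplexed FASTQ with known per-read
# ground truth, plus the matching key files and tag file, so every
# pipeline stage is testable without external downloads.
#
# The generator emulates a typical single-enzyme-pair GBS library: reads
# are barcode + cut-site remnant + allele tag + filler, with optional 3'
# adapter read-through and internal-full-cut-site chimeras, and
# per-(sample, tag) depths drawn from a negative-binomial-shaped
# distribution to mimic the strong depth heterogeneity of real GBS data.
# Tags and fillers are generated free of full restriction sites (a real
# fragment would have been cut there) and of incidental adapter content,
# so planted truth is exact.

#' Describe a synthetic GBS fixture
#'
#' Defaults emulate one multiplexed HiSeq-style lane fragment: 96
#' barcodes of mixed length (4-8 nt), 1000 biallelic markers with tags
#' of 40-80 nt, and a mean depth of 1 read per sample x tag cell
#' (~192,000 reads in expectation).
#'
#' @param n_samples Number of barcoded samples.
#' @param n_markers Number of biallelic markers.
#' @param barcode_lengths Pool of barcode lengths, cycled over samples.
#' @param tag_length Two-element range of tag lengths (nt, excluding the
#'   remnant for fixed-remnant enzymes).
#' @param enzyme Enzyme name or `gbs_enzyme`.
#' @param depth_mean,depth_dispersion Negative-binomial mean and size
#'   for reads per (sample, tag) cell.
#' @param error_rate Per-base substitution probability.
#' @param adapter_readthrough Fraction of reads carrying 3' adapter
#'   read-through.
#' @param chimera_fraction Fraction of reads carrying an internal full
#'   cut site followed by decoy sequence.
#' @param read_length Read length (nt).
#' @param adapters Adapter set used for read-through simulation.
#' @param seed Integer seed; fixtures are byte-identical under a fixed
#'   seed.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_samples = 96L, n_markers = 1000L,
                         barcode_lengths = 4:8,
                         tag_length = c(40L, 80L),
                         enzyme = "PstI-MspI",
                         depth_mean = 1, depth_dispersion = 0.5,
                         error_rate = 0, adapter_readthrough = 0.05,
                         chimera_fraction = 0.02,
                         read_length = 100L,
                         adapters = "illumina_truseq",
                         seed = 1L) {
  probs <- c(error_rate, adapter_readthrough, chimera_fraction)
  if (any(probs < 0 | probs > 1)) {
    abort("error_rate, adapter_readthrough and chimera_fraction must be in [0, 1]")
  }
  enz <- get_enzyme(enzyme)
  max_rem <- max(nchar(enz$remnant_variants))
  if (max(barcode_lengths) + max_rem + max(tag_length) + 4L > read_length) {
    abort("read_length is too short for the longest barcode + remnant + tag")
  }
  if (n_markers * 2L > 4^min(tag_length) / 4) {
    abort("tag count is infeasible for the requested tag length")
  }
  structure(list(
    n_samples = as.integer(n_samples), n_markers = as.integer(n_markers),
    barcode_lengths = as.integer(barcode_lengths),
    tag_length = as.integer(tag_length), enzyme = enz,
    depth_mean = depth_mean, depth_dispersion = depth_dispersion,
    error_rate = error_rate, adapter_readthrough = adapter_readthrough,
    chimera_fraction = chimera_fraction,
    read_length = as.integer(read_length),
    adapters = get_adapters(adapters), seed = as.integer(seed)
  ), class = "fixture_spec")
}

# Random sequences free of any of the given motifs (regenerated until
# clean; motifs are short so a handful of attempts suffice).
rand_dna_clean <- function(lengths, motifs) {
  out <- rand_dna(lengths)
  if (!length(motifs) || !length(out)) return(out)
  pat <- paste(motifs, collapse = "|")
  for (it in 1:50) {
    bad <- grepl(pat, out)
    if (!any(bad)) return(out)
    out[bad] <- rand_dna(lengths[bad])
  }
  # deterministic fallback: an AC repeat contains none of the motifs used
  out[grepl(pat, out)] <- vapply(lengths[grepl(pat, out)], function(L) {
    paste(rep_len(c("A", "C"), L), collapse = "")
  }, character(1))
  out
}

#' Generate a synthetic multiplexed GBS fixture
#'
#' Writes a FASTQ file, the counting and splitting key files and a
#' merged-CSV tag file into `dir`, and returns them together with the
#' ground truth: the expected counts table and a per-read label table.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @param gzip Compress the FASTQ with GZIP (exercises `.gz` handling).
#' @return A list: `fastq`, `key`, `split_key`, `tags_csv` (paths),
#'   `tags` (the `tag_set`), `truth_counts` (tibble shaped like
#'   [count_tags()] output), `read_labels` (tibble with one row per read:
#'   `sample`, `tag_name`, `expect_match`), `barcodes`, `samples`.
#' @export
generate_fixture <- function(spec, dir = tempfile("fixture"),
                             gzip = FALSE) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(spec$seed)

  enz <- spec$enzyme
  sites <- enz$full_sites
  adapter_starts <- substr(spec$adapters$sequences, 1L, 8L)
  forbidden <- c(sites, adapter_starts)

  ## samples and barcodes: mixed lengths, unambiguous after remnant
  samples <- sprintf("S%03d", seq_len(spec$n_samples))
  bc_len <- rep_len(spec$barcode_lengths, spec$n_samples)
  barcodes <- rand_dna_clean(bc_len, forbidden)
  for (it in 1:100) {
    combos <- as.vector(outer(barcodes, enz$remnant_variants, paste0))
    ok <- !anyDuplicated(barcodes)
    if (ok) {
      s <- sort(combos, method = "radix")
      pref <- any(startsWith(s[-1], s[-length(s)]))
      ok <- !pref
    }
    if (ok) break
    barcodes <- rand_dna_clean(bc_len, forbidden)
  }

  ## markers: biallelic tags, unique, site-free, prefix-free
  tag_len <- sample(seq(spec$tag_length[1], spec$tag_length[2]),
                    spec$n_markers, replace = TRUE)
  markers <- sprintf("M%04d", seq_len(spec$n_markers))
  site_pat <- paste(sites, collapse = "|")
  tag0 <- character(spec$n_markers)
  tag1 <- character(spec$n_markers)
  bad <- seq_len(spec$n_markers)
  for (it in 1:200) {
    if (!length(bad)) break
    # (re)draw offending markers only: a clean base tag plus a single
    # substitution somewhere after the first position
    tag0[bad] <- rand_dna_clean(tag_len[bad], forbidden)
    pos <- sample.int(spec$tag_length[1] - 1L, length(bad),
                      replace = TRUE) + 1L
    t1 <- tag0[bad]
    for (j in seq_along(bad)) {
      old <- substr(t1[j], pos[j], pos[j])
      substr(t1[j], pos[j], pos[j]) <-
        sample(setdiff(DNA_BASES, old), 1L)
    }
    tag1[bad] <- t1
    f0 <- tag0
    f1 <- tag1
    if (enz$tags_include_remnant) {
      rem_tag <- sample(enz$remnant_variants, spec$n_markers,
                        replace = TRUE)
      f0 <- paste0(rem_tag, tag0)
      f1 <- paste0(rem_tag, tag1)
    }
    all_tags <- c(f0, f1)
    bad <- which(grepl(site_pat, f1) | grepl(site_pat, f0))
    dup <- duplicated(all_tags) | duplicated(all_tags, fromLast = TRUE)
    bad <- union(bad, (which(dup) - 1L) %% spec$n_markers + 1L)
    o <- order(all_tags, method = "radix")
    s <- all_tags[o]
    pref <- which(startsWith(s[-1], s[-length(s)]))
    if (length(pref)) {
      off <- unique(c(o[pref], o[pref + 1L]))
      bad <- union(bad, (off - 1L) %% spec$n_markers + 1L)
    }
    if (!length(bad)) {
      tag0 <- f0
      tag1 <- f1
      break
    }
  }
  if (length(bad)) {
    abort("could not generate a clean tag set; relax the fixture spec")
  }
  # allele "0" is the alphabetically smaller tag
  resort <- tag0 > tag1
  tmp <- tag0[resort]; tag0[resort] <- tag1[resort]; tag1[resort] <- tmp
  tags <- tag_set(tibble(
    marker = rep(markers, each = 2L),
    allele = rep(c("0", "1"), spec$n_markers),
    sequence = as.vector(rbind(tag0, tag1))
  ))

  ## depths per (sample, tag) cell
  n_tags <- 2L * spec$n_markers
  depth <- rnbinom(spec$n_samples * n_tags, mu = spec$depth_mean,
                   size = spec$depth_dispersion)
  cell_sample <- rep(seq_len(spec$n_samples), each = n_tags)
  cell_tag <- rep(seq_len(n_tags), times = spec$n_samples)
  read_sample <- rep(cell_sample, depth)
  read_tag <- rep(cell_tag, depth)
  n_reads <- length(read_sample)

  ## assemble reads
  tag_seq_all <- tags$sequence
  remnant <- if (enz$tags_include_remnant) "" else {
    sample(enz$remnant_variants, n_reads, replace = TRUE)
  }
  core <- paste0(barcodes[read_sample], remnant, tag_seq_all[read_tag])
  core_len <- nchar(core)
  fill_len <- spec$read_length - core_len
  kind <- sample(c("plain", "adapter", "chimera"), n_reads,
                 replace = TRUE,
                 prob = c(1 - spec$adapter_readthrough -
                            spec$chimera_fraction,
                          spec$adapter_readthrough,
                          spec$chimera_fraction))
  filler <- rand_dna_clean(fill_len, forbidden)
  ad_main <- spec$adapters$sequences[1]
  is_ad <- kind == "adapter"
  if (any(is_ad)) {
    filler[is_ad] <- substr(
      paste0(ad_main, filler[is_ad]), 1L, fill_len[is_ad])
  }
  is_ch <- kind == "chimera"
  if (any(is_ch)) {
    site <- sample(sites, sum(is_ch), replace = TRUE)
    filler[is_ch] <- substr(
      paste0(site, filler[is_ch]), 1L, fill_len[is_ch])
  }
  reads <- paste0(core, filler)

  ## junction cleanup: regenerate filler where an unplanted full site or
  ## adapter overlap appears at or before the end of the core
  bc_of_read <- nchar(barcodes[read_sample])
  rem_len_read <- if (enz$tags_include_remnant) {
    rep.int(nchar(enz$remnant_variants[1]), n_reads)
  } else {
    nchar(remnant)
  }
  active <- seq_len(n_reads)  # reads still needing the check
  for (it in 1:20) {
    if (!length(active)) break
    stripped <- substring(reads[active], bc_of_read[active] + 1L)
    core_in_stripped <- core_len[active] - bc_of_read[active]
    cs <- find_full_cut_site(stripped, sites,
                             search_from = rem_len_read[active] + 1L)
    planted_at <- ifelse(is_ch[active], core_in_stripped + 1L,
                         NA_integer_)
    bad_site <- !is.na(cs$position) &
      (is.na(planted_at) | cs$position < planted_at)
    ad <- find_adapter_trim(reads[active], spec$adapters,
                            min_overlap = 6L)
    bad_ad <- !is.na(ad) & (ad <= core_len[active])
    bad <- active[bad_site | bad_ad]
    if (!length(bad)) break
    plain <- bad[!is_ad[bad] & !is_ch[bad]]
    filler[plain] <- rand_dna_clean(fill_len[plain], forbidden)
    redo_ad <- bad[is_ad[bad]]
    if (length(redo_ad)) {
      filler[redo_ad] <- substr(
        paste0(ad_main, rand_dna_clean(fill_len[redo_ad], forbidden)),
        1L, fill_len[redo_ad])
    }
    redo_ch <- bad[is_ch[bad]]
    if (length(redo_ch)) {
      site <- sample(sites, length(redo_ch), replace = TRUE)
      filler[redo_ch] <- substr(
        paste0(site, rand_dna_clean(fill_len[redo_ch], forbidden)),
        1L, fill_len[redo_ch])
    }
    reads[bad] <- paste0(core[bad], filler[bad])
    active <- bad
  }

  ## substitution errors; an erroneous core never matches a registered
  ## combination (checked and re-drawn), so errors only cause losses
  expect_match <- rep(TRUE, n_reads)
  if (spec$error_rate > 0 && n_reads > 0L) {
    n_err <- stats::rbinom(n_reads, spec$read_length, spec$error_rate)
    err_reads <- which(n_err > 0L)
    # every registered barcode+remnant+tag combination, not only those
    # present among the planted reads
    reg <- if (enz$tags_include_remnant) {
      as.vector(outer(barcodes, tags$sequence, paste0))
    } else {
      unlist(lapply(enz$remnant_variants, function(rv) {
        as.vector(outer(paste0(barcodes, rv), tags$sequence, paste0))
      }))
    }
    reg_sorted <- sort(unique(reg), method = "radix")
    for (i in err_reads) {
      for (attempt in 1:20) {
        r <- reads[i]
        pp <- sample.int(spec$read_length, n_err[i])
        for (p in pp) {
          old <- substr(r, p, p)
          substr(r, p, p) <- sample(setdiff(DNA_BASES, old), 1L)
        }
        core_err <- any(pp <= core_len[i])
        if (!core_err) {
          # error only in filler: the read still matches its own tag
          reads[i] <- r
          break
        }
        # would the mutated core prefix still match some registered
        # barcode+remnant+tag exactly?  (binary search on sorted cores)
        hit <- FALSE
        for (cl in unique(nchar(reg_sorted))) {
          if (bisect_find(reg_sorted,
                          substr(r, 1L, cl)) > 0L) { hit <- TRUE; break }
        }
        if (!hit) {
          reads[i] <- r
          expect_match[i] <- FALSE
          break
        }
        # the error recreated a registered combination; re-draw
      }
    }
  }

  ## shuffle read order and write files
  ord <- sample.int(n_reads)
  reads <- reads[ord]
  read_sample <- read_sample[ord]
  read_tag <- read_tag[ord]
  expect_match <- expect_match[ord]
  headers <- sprintf("@SIM:1:FC1:1:1:%d:%d 1:N:0:0",
                     seq_len(n_reads), seq_len(n_reads))
  quals <- strrep("I", nchar(reads))
  fq_name <- if (gzip) "reads.fastq.gz" else "reads.fastq"
  fastq <- file.path(dir, fq_name)
  con <- if (gzip) gzfile(fastq, open = "wb") else file(fastq, open = "wb")
  writeLines(as.vector(rbind(headers, reads, "+", quals)), con)
  close(con)

  key_path <- file.path(dir, "key.csv")
  readr::write_csv(tibble(File = fq_name, Barcode = barcodes,
                          Sample = samples), key_path, progress = FALSE)
  split_key_path <- file.path(dir, "split_key.csv")
  readr::write_csv(tibble(`Input File` = fq_name, Barcode = barcodes,
                          `Output File` = paste0(samples, ".fastq")),
                   split_key_path, progress = FALSE)
  tags_csv <- file.path(dir, "tags.csv")
  write_tag_csv(tags, tags_csv)

  ## ground truth
  truth <- integer(spec$n_samples * n_tags)
  ok <- expect_match
  if (any(ok)) {
    truth <- tabulate((read_sample[ok] - 1L) * n_tags + read_tag[ok],
                      nbins = length(truth))
  }
  mat <- matrix(truth, nrow = spec$n_samples, ncol = n_tags, byrow = TRUE)
  colnames(mat) <- tags$tag_name
  truth_counts <- bind_cols(tibble(sample = samples), as_tibble(mat))
  read_labels <- tibble(sample = samples[read_sample],
                        tag_name = tags$tag_name[read_tag],
                        expect_match = expect_match)
  list(fastq = fastq, key = key_path, split_key = split_key_path,
       tags_csv = tags_csv, tags = tags, truth_counts = truth_counts,
       read_labels = read_labels, barcodes = barcodes, samples = samples)
}
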