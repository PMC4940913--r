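# Registry of restriction enzymes and sequencing adapters.  The tables
# below are plain data at the top of this file so that new enzymes and
# adapter chemistries can be added with a single entry (or at run time
# with register_enzyme()/register_adapter_set()).
#
# remnant_variants: sequence expected immediately after the barcode in a
#   read (the portion of the recognition site left at the fragment end
#   after digestion and adapter ligation); more than one entry for
#   enzymes with a variable base in the site.
# full_sites: reconstituted recognition sites scanned for anywhere inside
#   a read; an internal full site suggests a re-ligation chimera of two
#   genomic fragments.
# tags_include_remnant: TRUE for variable-site enzymes, where tag
#   sequences start at the remnant itself so the variable base stays part
#   of the tag.
#
# Remnants/sites follow the published recognition sequences:
#   PstI  CTGCA^G  -> reads begin barcode + TGCAG; full site CTGCAG
#   NsiI  ATGCA^T  -> reads begin barcode + TGCAT; full site ATGCAT
#   MspI  C^CGG    -> common-cutter partner; full site CCGG
#   ApeKI G^CWGC   -> reads begin barcode + CAGC or CTGC; full sites
#                     GCAGC/GCTGC
# PstI/NsiI 3'-overhangs are incompatible with the MspI 5'-overhang, so
# no hybrid junction site exists for those double digests; the chimera
# site list is the two reconstituted sites.

.tagtally_registry <- new.env(parent = emptyenv())

.tagtally_registry$enzymes <- list(
  "PstI-MspI" = list(name = "PstI-MspI",
                     remnant_variants = "TGCAG",
                     full_sites = c("CTGCAG", "CCGG"),
                     tags_include_remnant = FALSE),
  "NsiI-MspI" = list(name = "NsiI-MspI",
                     remnant_variants = "TGCAT",
                     full_sites = c("ATGCAT", "CCGG"),
                     tags_include_remnant = FALSE),
  "ApeKI"     = list(name = "ApeKI",
                     remnant_variants = c("CAGC", "CTGC"),
                     full_sites = c("GCAGC", "GCTGC"),
                     tags_include_remnant = TRUE)
)

# Illumina TruSeq-style common adapter, as read through from the 3' end
# of a short insert (read-1 and read-2 forms share the 13 nt start).
.tagtally_registry$adapters <- list(
  "illumina_truseq" = list(
    name = "illumina_truseq",
    sequences = c("AGATCGGAAGAGCACACGTCTGAACTCCAGTCA",
                  "AGATCGGAAGAGCGTCGTGTAGGGAAAGAGTGT")
  )
)

#' Look up a restriction enzyme
#'
#' @param name Registered enzyme name (see [list_enzymes()]).
#' @return A `gbs_enzyme` list with fields `name`, `remnant_variants`,
#'   `full_sites` and `tags_include_remnant`.
#' @examples
#' get_enzyme("PstI-MspI")$remnant_variants
#' @export
get_enzyme <- function(name) {
  if (inherits(name, "gbs_enzyme")) return(name)
  stopifnot(is.character(name), length(name) == 1L)
  e <- .tagtally_registry$enzymes[[name]]
  if (is.null(e)) {
    abort(sprintf(
      "unknown enzyme '%s'; registered enzymes are: %s",
      name, paste(list_enzymes(), collapse = ", ")
    ))
  }
  structure(e, class = "gbs_enzyme")
}

#' @rdname get_enzyme
#' @export
list_enzymes <- function() {
  names(.tagtally_registry$enzymes)
}

#' Register a restriction enzyme
#'
#' Adds (or replaces) an enzyme entry so the full counting and splitting
#' pipeline can run with it.
#'
#' @inheritParams get_enzyme
#' @param remnant_variants Post-barcode remnant sequence(s); more than
#'   one entry for variable-site enzymes.
#' @param full_sites Reconstituted recognition sites scanned for chimeras.
#' @param tags_include_remnant Must be `TRUE` exactly when there is more
#'   than one remnant variant.
#' @return The registered `gbs_enzyme`, invisibly.
#' @export
register_enzyme <- function(name, remnant_variants, full_sites,
                            tags_include_remnant =
                              length(remnant_variants) > 1L) {
  remnant_variants <- toupper(remnant_variants)
  full_sites <- toupper(full_sites)
  assert_dna(remnant_variants, "remnant")
  assert_dna(full_sites, "cut site")
  if (tags_include_remnant != (length(remnant_variants) > 1L)) {
    abort("tags_include_remnant must be TRUE exactly for variable-site enzymes (more than one remnant variant)")
  }
  e <- list(name = name, remnant_variants = remnant_variants,
            full_sites = full_sites,
            tags_include_remnant = tags_include_remnant)
  .tagtally_registry$enzymes[[name]] <- e
  invisible(structure(e, class = "gbs_enzyme"))
}

#' Look up an adapter set
#'
#' @param name Registered adapter chemistry name (see [list_adapters()]),
#'   or a character vector of adapter sequences used directly.
#' @return An `adapter_set` list with fields `name` and `sequences`.
#' @export
get_adapters <- function(name) {
  if (inherits(name, "adapter_set")) return(name)
  if (is.character(name) && length(name) == 1L &&
      !is.null(.tagtally_registry$adapters[[name]])) {
    return(structure(.tagtally_registry$adapters[[name]],
                     class = "adapter_set"))
  }
  if (is.character(name) && all(is_dna(toupper(name)))) {
    return(structure(list(name = "custom", sequences = toupper(name)),
                     class = "adapter_set"))
  }
  abort(sprintf(
    "unknown adapter set '%s'; registered sets are: %s",
    paste(name, collapse = ","), paste(list_adapters(), collapse = ", ")
  ))
}

#' @rdname get_adapters
#' @export
list_adapters <- function() {
  names(.tagtally_registry$adapters)
}

#' @rdname get_adapters
#' @param sequences Adapter sequences searched from the 3' end of reads.
#' @export
register_adapter_set <- function(name, sequences) {
  sequences <- toupper(sequences)
  assert_dna(sequences, "adapter")
  a <- list(name = name, sequences = sequences)
  .tagtally_registry$adapters[[name]] <- a
  invisible(structure(a, class = "adapter_set"))
}
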