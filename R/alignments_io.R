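# Reading, writing and column access for gapped barcode alignments.

#' Construct a barcode alignment object
#'
#' Usually created via [read_alignment()]; exposed so that tests and
#' simulations can build alignments programmatically.
#'
#' @param locus Locus name, e.g. `"ITS"` or `"matK"`.
#' @param sequence_id Character vector of unique record identifiers.
#' @param species Character vector of species labels, one per record.
#' @param sequences Character vector of aligned sequences (equal lengths,
#'   characters drawn from `A,C,G,T`, IUPAC ambiguity codes and `-`).
#' @param headers Optional original FASTA headers (defaults to
#'   `"<sequence_id> <species>"`).
#'
#' @return An object of class `barcode_alignment` with fields `locus`,
#'   `sequence_id`, `species`, `sequences`, `headers` and `length` (number of
#'   alignment columns).
#' @export
barcode_alignment <- function(locus, sequence_id, species, sequences,
                              headers = NULL) {
  if (!is_string(locus)) herbq_error("locus must be a single name", "herbq_input_error")
  n <- length(sequences)
  if (n < 1L) herbq_error("alignment has no records", "herbq_input_error")
  if (length(sequence_id) != n || length(species) != n) {
    herbq_error("sequence_id, species and sequences lengths differ",
                "herbq_input_error")
  }
  if (anyDuplicated(sequence_id)) {
    herbq_error(sprintf("duplicated sequence_id: %s",
                        sequence_id[duplicated(sequence_id)][1L]),
                "herbq_input_error")
  }
  if (any(!nzchar(species) | is.na(species))) {
    herbq_error(sprintf("record '%s' has an empty species label",
                        sequence_id[(!nzchar(species) | is.na(species))][1L]),
                "herbq_input_error")
  }
  sequences <- toupper(sequences)
  widths <- nchar(sequences)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1L])[1L]
    herbq_error(sprintf(
      "ragged alignment: record '%s' has length %d, expected %d",
      sequence_id[bad], widths[bad], widths[1L]), "herbq_alignment_error")
  }
  chars <- unique(unlist(strsplit(sequences, "", fixed = TRUE), use.names = FALSE))
  bad_chars <- setdiff(chars, .ALN_ALPHABET)
  if (length(bad_chars)) {
    offender <- sequence_id[grepl(bad_chars[1L], sequences, fixed = TRUE)][1L]
    herbq_error(sprintf(
      "record '%s' contains non-nucleotide character '%s'",
      offender, bad_chars[1L]), "herbq_input_error")
  }
  structure(list(
    locus = locus,
    sequence_id = unname(as.character(sequence_id)),
    species = unname(as.character(species)),
    sequences = unname(sequences),
    headers = unname(headers %||% paste(sequence_id, species)),
    length = unname(widths[1L])
  ), class = "barcode_alignment")
}

#' Read an aligned multi-FASTA barcode file
#'
#' Headers are split on `delim`; the first field becomes the record's
#' `sequence_id` and the remaining fields (joined by a space) the species
#' label, so standard headers such as `">FCIR1 Fritillaria cirrhosa"` work
#' out of the box. Sequences are uppercased on read; gaps (`-`) and IUPAC
#' ambiguity codes are retained (their treatment is a screening-time policy,
#' see [find_group_diagnostic_sites()]).
#'
#' @param path Path to an aligned FASTA file with at least 2 records.
#' @param locus Locus name attached to the alignment.
#' @param delim Regular expression splitting the header into id and species
#'   fields (default: whitespace).
#'
#' @return A [barcode_alignment()] object.
#' @export
read_alignment <- function(path, locus, delim = "\\s+") {
  if (!file.exists(path)) {
    herbq_error(sprintf("alignment file not found: %s", path), "herbq_input_error")
  }
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) {
                    herbq_error(sprintf("cannot parse FASTA '%s': %s",
                                        path, conditionMessage(e)),
                                "herbq_input_error")
                  })
  if (length(set) == 0L) {
    herbq_error(sprintf("empty FASTA file: %s", path), "herbq_input_error")
  }
  if (length(set) < 2L) {
    herbq_error(sprintf("alignment '%s' has fewer than 2 records", path),
                "herbq_input_error")
  }
  headers <- names(set)
  parts <- strsplit(headers, delim)
  ids <- vapply(parts, `[[`, character(1L), 1L)
  species <- vapply(parts, function(p) {
    paste(p[-1L], collapse = " ")
  }, character(1L))
  if (any(!nzchar(species))) {
    herbq_error(sprintf(
      "header '%s' carries no species label after the id field",
      headers[!nzchar(species)][1L]), "herbq_input_error")
  }
  barcode_alignment(locus, ids, species, as.character(set), headers = headers)
}

#' Write an alignment back to FASTA
#'
#' Canonical output: original headers, uppercase residues, 60-column line
#' wrapping. Reading a file written by this function round-trips
#' byte-identically for canonical input.
#'
#' @param alignment A [barcode_alignment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(alignment, path) {
  stopifnot(inherits(alignment, "barcode_alignment"))
  set <- Biostrings::BStringSet(setNames(alignment$sequences, alignment$headers))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Extract one alignment column
#'
#' @param alignment A [barcode_alignment()].
#' @param pos 1-based column index.
#' @return A data.frame with columns `sequence_id`, `species`, `residue`
#'   (gaps and ambiguity codes preserved).
#' @export
alignment_column <- function(alignment, pos) {
  stopifnot(inherits(alignment, "barcode_alignment"))
  if (!is_scalar_number(pos) || pos != as.integer(pos) ||
      pos < 1L || pos > alignment$length) {
    herbq_error(sprintf("column %s out of range [1, %d]",
                        format(pos), alignment$length), "herbq_bounds_error")
  }
  data.frame(
    sequence_id = alignment$sequence_id,
    species = alignment$species,
    residue = substr(alignment$sequences, pos, pos),
    stringsAsFactors = FALSE
  )
}

# Character matrix view (records x columns); screening workhorse.
.aln_matrix <- function(alignment) {
  m <- do.call(rbind, strsplit(alignment$sequences, "", fixed = TRUE))
  rownames(m) <- alignment$sequence_id
  m
}

#' @export
print.barcode_alignment <- function(x, ...) {
  cat(sprintf("<barcode_alignment> locus %s: %d records x %d columns, %d species\n",
              x$locus, length(x$sequence_id), x$length,
              length(unique(x$species))))
  invisible(x)
}

#' Construct a taxon grouping (target group vs adulterants)
#'
#' @param target_group Character vector of species forming the genuine drug's
#'   permitted origin group.
#' @param adulterants Character vector of adulterant species.
#' @param joint_taxa Named list of character vectors: unions of adulterant
#'   species that share a single diagnostic site (e.g. a pair of sister
#'   species with no private fixed difference).
#' @param name Label used for the target group in reports (e.g. `"FCB"`).
#'
#' @return An object of class `taxon_grouping`.
#' @export
taxon_grouping <- function(target_group, adulterants, joint_taxa = list(),
                           name = "target") {
  target_group <- unique(as.character(target_group))
  adulterants <- unique(as.character(adulterants))
  if (length(target_group) == 0L || length(adulterants) == 0L) {
    herbq_error("target_group and adulterants must both be nonempty",
                "herbq_config_error")
  }
  overlap <- intersect(target_group, adulterants)
  if (length(overlap)) {
    herbq_error(sprintf("species listed in both roles: %s",
                        paste(overlap, collapse = ", ")),
                "herbq_config_error")
  }
  if (length(joint_taxa)) {
    if (is.null(names(joint_taxa)) || any(!nzchar(names(joint_taxa)))) {
      herbq_error("joint_taxa must be a named list", "herbq_config_error")
    }
    for (nm in names(joint_taxa)) {
      extra <- setdiff(joint_taxa[[nm]], adulterants)
      if (length(extra)) {
        herbq_error(sprintf(
          "joint taxon '%s' contains non-adulterant species: %s",
          nm, paste(extra, collapse = ", ")), "herbq_config_error")
      }
    }
  }
  structure(list(
    name = name,
    target_group = target_group,
    adulterants = adulterants,
    joint_taxa = joint_taxa,
    universe = c(target_group, adulterants)
  ), class = "taxon_grouping")
}

#' Load a taxon grouping from JSON or two-column TSV
#'
#' JSON files carry fields `target_group`, `adulterants`, optional
#' `joint_taxa` (named lists of species) and optional `name`. TSV files carry
#' two columns `species` and `role`, with role `"target"` or `"adulterant"`
#' (joint taxa are only expressible in JSON).
#'
#' @param path Path to the configuration file.
#' @return A [taxon_grouping()].
#' @export
load_grouping <- function(path) {
  if (!file.exists(path)) {
    herbq_error(sprintf("grouping file not found: %s", path), "herbq_input_error")
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    jt <- cfg$joint_taxa %||% list()
    jt <- lapply(as.list(jt), as.character)
    return(taxon_grouping(cfg$target_group, cfg$adulterants,
                          joint_taxa = jt,
                          name = cfg$name %||% "target"))
  }
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("species", "role") %in% names(tab))) {
    herbq_error("grouping TSV must have columns 'species' and 'role'",
                "herbq_config_error")
  }
  bad <- setdiff(unique(tab$role), c("target", "adulterant"))
  if (length(bad)) {
    herbq_error(sprintf("unknown role '%s' in grouping file", bad[1L]),
                "herbq_config_error")
  }
  taxon_grouping(tab$species[tab$role == "target"],
                 tab$species[tab$role == "adulterant"])
}

#' @export
print.taxon_grouping <- function(x, ...) {
  cat(sprintf("<taxon_grouping> %s: %d target species vs %d adulterants",
              x$name, length(x$target_group), length(x$adulterants)))
  if (length(x$joint_taxa)) {
    cat(sprintf(" (joint: %s)", paste(names(x$joint_taxa), collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}
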