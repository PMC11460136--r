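# Shared fixtures: the packaged synthetic reference panel, random toy
# alignments with optional planted diagnostic columns, and a naive
# per-column screening oracle kept deliberately independent of the
# implementation (set logic over alignment_column(), no shared code path).

fcb_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    grouping <- load_grouping(system.file("extdata", "fcb_grouping.json",
                                          package = "herbq"))
    its <- read_alignment(system.file("extdata", "synthetic_its_aln.fasta",
                                      package = "herbq"), "ITS")
    matk <- read_alignment(system.file("extdata", "synthetic_matk_aln.fasta",
                                       package = "herbq"), "matK")
    group_sites <- c(find_group_diagnostic_sites(its, grouping),
                     find_group_diagnostic_sites(matk, grouping))
    species_sites <- setNames(
      lapply(species_scan_taxa(grouping), function(taxon) {
        c(find_species_diagnostic_sites(its, grouping, taxon),
          find_species_diagnostic_sites(matk, grouping, taxon))
      }), species_scan_taxa(grouping))
    panel <- build_panel(group_sites, species_sites, grouping,
                         alignments = list(ITS = its, matK = matk))
    cache <<- list(grouping = grouping, its = its, matk = matk,
                   group_sites = group_sites, species_sites = species_sites,
                   panel = panel)
    cache
  }
})

# Random toy alignment over a target/adulterant split. Per-species column
# bases are drawn i.i.d.; accessions within a species are identical except
# for planted blemishes. `plant` is a list of
# list(pos, target_allele, background_allele [, taxon]) columns forced to be
# diagnostic (group-wise, or species-wise when `taxon` is given).
random_alignment <- function(n_target = 3, n_adult = 2, n_cols = 80,
                             n_per_species = 2, plant = list(),
                             p_gap = 0, p_ambig = 0, locus = "toy") {
  species <- c(sprintf("Target species%02d", seq_len(n_target)),
               sprintf("Adulterant species%02d", seq_len(n_adult)))
  is_target <- rep(c(TRUE, FALSE), c(n_target, n_adult))
  base <- matrix(sample(c("A", "C", "G", "T"),
                        (n_target + n_adult) * n_cols, replace = TRUE),
                 nrow = n_target + n_adult)
  for (p in plant) {
    if (is.null(p$taxon)) {
      base[, p$pos] <- ifelse(is_target, p$target_allele, p$background_allele)
    } else {
      base[, p$pos] <- ifelse(species == p$taxon,
                              p$target_allele, p$background_allele)
    }
  }
  rows <- base[rep(seq_len(nrow(base)), each = n_per_species), , drop = FALSE]
  if (p_gap > 0) {
    k <- rbinom(1, length(rows), p_gap)
    rows[sample(length(rows), k)] <- "-"
  }
  if (p_ambig > 0) {
    k <- rbinom(1, length(rows), p_ambig)
    rows[sample(length(rows), k)] <- sample(c("N", "R", "Y"), k,
                                            replace = TRUE)
  }
  sp_rep <- rep(species, each = n_per_species)
  aln <- barcode_alignment(
    locus,
    sequence_id = sprintf("seq%03d", seq_len(nrow(rows))),
    species = sp_rep,
    sequences = apply(rows, 1L, paste, collapse = ""))
  grouping <- taxon_grouping(species[is_target], species[!is_target],
                             name = "TGT")
  list(alignment = aln, grouping = grouping, species = species)
}

# Naive oracle: for every column, collect residues per side via
# alignment_column() and apply the fixed-difference predicate directly.
oracle_sites <- function(alignment, target_species, background_species) {
  acgt <- c("A", "C", "G", "T")
  found <- list()
  for (pos in seq_len(alignment$length)) {
    col <- alignment_column(alignment, pos)
    rt <- col$residue[col$species %in% target_species]
    rb <- col$residue[col$species %in% background_species]
    if (any(!rt %in% acgt) || any(!rb %in% acgt)) next
    if (length(unique(rt)) == 1L && length(unique(rb)) == 1L &&
        rt[1L] != rb[1L]) {
      found[[length(found) + 1L]] <-
        list(position = pos, target_allele = rt[1L],
             background_allele = rb[1L])
    }
  }
  found
}

# Character-matrix view used by tests only (kept separate from package
# internals so oracle-side checks do not share the implementation's code).
.aln_matrix_test <- function(alignment) {
  do.call(rbind, strsplit(alignment$sequences, "", fixed = TRUE))
}

site_key <- function(sites) {
  vapply(sites, function(s) {
    sprintf("%d:%s>%s", s$position, s$target_allele, s$background_allele)
  }, character(1L))
}

# Write a small FASTA from a named character vector of sequences.
write_tmp_fasta <- function(seqs, headers = names(seqs)) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(rbind(paste0(">", headers), unname(seqs)), path)
  path
}

# Measurement rows for one site at fixed replicate frequencies.
meas_rows <- function(locus, position, allele, freqs,
                      sample_id = "s1") {
  data.frame(sample_id = sample_id, locus = locus, position = position,
             allele = allele, replicate = seq_along(freqs),
             frequency = freqs, stringsAsFactors = FALSE)
}
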