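# Two-step diagnostic-SNP screening over barcode alignments.
#
# A column is diagnostic when every considered sequence on one side of the
# contrast carries one fixed unambiguous base and every sequence on the other
# side carries a different fixed unambiguous base. Any gap or IUPAC ambiguity
# code in a considered sequence disqualifies the column (conservative policy;
# proofread alignments are assumed).

#' Construct a diagnostic site
#'
#' @param locus Locus name.
#' @param position 1-based alignment column.
#' @param mode `"group_diagnostic"` (target group vs all adulterants) or
#'   `"species_diagnostic"` (one adulterant or joint taxon vs all other taxa).
#' @param target_taxa Species carrying the target allele.
#' @param target_allele,background_allele Single bases in `A,C,G,T`;
#'   `background_allele` may be `NA` only for exploratory lenient screening.
#' @param n_supporting Number of sequences consistent with the call.
#' @param taxon_label Display label for the target taxa (species name, joint
#'   taxon name, or group name).
#' @param flank Optional flanking sequence (see [extract_flank()]).
#'
#' @return An object of class `diagnostic_site`. Its `id` is `"locus:position"`.
#' @export
diagnostic_site <- function(locus, position, mode, target_taxa,
                            target_allele, background_allele,
                            n_supporting, taxon_label = NULL,
                            flank = NA_character_) {
  mode <- match.arg(mode, c("group_diagnostic", "species_diagnostic"))
  if (!target_allele %in% .ACGT) {
    herbq_error("target_allele must be one of A, C, G, T", "herbq_input_error")
  }
  if (!is.na(background_allele)) {
    if (!background_allele %in% .ACGT) {
      herbq_error("background_allele must be one of A, C, G, T",
                  "herbq_input_error")
    }
    if (identical(target_allele, background_allele)) {
      herbq_error("target and background alleles must differ",
                  "herbq_input_error")
    }
  }
  structure(list(
    id = sprintf("%s:%d", locus, as.integer(position)),
    locus = locus,
    position = as.integer(position),
    mode = mode,
    target_taxa = as.character(target_taxa),
    taxon_label = taxon_label %||% paste(target_taxa, collapse = "+"),
    target_allele = target_allele,
    background_allele = background_allele,
    n_supporting = as.integer(n_supporting),
    flank = flank
  ), class = "diagnostic_site")
}

#' @export
print.diagnostic_site <- function(x, ...) {
  cat(sprintf("<diagnostic_site> %s [%s] %s: %s vs %s (n=%d)\n",
              x$id, x$mode, x$taxon_label, x$target_allele,
              ifelse(is.na(x$background_allele), "*", x$background_allele),
              x$n_supporting))
  invisible(x)
}

.check_species_present <- function(alignment, species) {
  missing <- setdiff(species, alignment$species)
  if (length(missing)) {
    herbq_error(sprintf("species absent from %s alignment: %s",
                        alignment$locus, paste(missing, collapse = ", ")),
                "herbq_coverage_error")
  }
}

.warn_screen_inputs <- function(alignment, grouping, min_support) {
  extra <- setdiff(unique(alignment$species), grouping$universe)
  if (length(extra)) {
    herbq_warning(sprintf(
      "ignoring %d species not listed in the grouping: %s",
      length(extra), paste(extra, collapse = ", ")), "herbq_coverage_warning")
  }
  counts <- table(alignment$species[alignment$species %in% grouping$universe])
  low <- names(counts)[counts < min_support]
  if (length(low)) {
    herbq_warning(sprintf(
      "species with fewer than %d accessions (singleton calls are weakly supported): %s",
      min_support, paste(low, collapse = ", ")), "herbq_support_warning")
  }
}

# Shared fixed-difference scan. Returns diagnostic_site list for all columns
# where target rows are fixed for one unambiguous base and background rows
# are fixed for (strict) or free of (lenient) a different one.
.scan_fixed_columns <- function(alignment, target_rows, background_rows,
                                mode, target_taxa, taxon_label,
                                background = "fixed") {
  m <- .aln_matrix(alignment)
  n_sup <- sum(target_rows) + sum(background_rows)
  sites <- list()
  for (j in seq_len(alignment$length)) {
    ct <- m[target_rows, j]
    cb <- m[background_rows, j]
    if (!all(ct %in% .ACGT) || !all(cb %in% .ACGT)) next
    ut <- unique(ct)
    if (length(ut) != 1L) next
    ub <- unique(cb)
    if (background == "fixed") {
      if (length(ub) != 1L || ub == ut) next
      bg_allele <- ub
    } else {
      if (ut %in% ub) next
      bg_allele <- if (length(ub) == 1L) ub else NA_character_
    }
    sites[[length(sites) + 1L]] <- diagnostic_site(
      locus = alignment$locus, position = j, mode = mode,
      target_taxa = target_taxa, taxon_label = taxon_label,
      target_allele = ut, background_allele = bg_allele,
      n_supporting = n_sup)
  }
  sites
}

#' Find group-diagnostic sites (target group vs all adulterants)
#'
#' Scans every alignment column for a fixed difference separating the whole
#' target group from all adulterants. Columns containing a gap or an IUPAC
#' ambiguity code in any considered sequence are excluded; species present in
#' the alignment but absent from the grouping are ignored with a warning.
#'
#' @param alignment A [barcode_alignment()].
#' @param grouping A [taxon_grouping()]; every species in it must appear in
#'   the alignment.
#' @param min_support Minimum number of accessions per species below which a
#'   weak-support warning is emitted (default 2; the call itself is still
#'   made).
#'
#' @return A list of `diagnostic_site` objects (possibly empty).
#' @export
find_group_diagnostic_sites <- function(alignment, grouping, min_support = 2L) {
  stopifnot(inherits(alignment, "barcode_alignment"),
            inherits(grouping, "taxon_grouping"))
  .check_species_present(alignment, grouping$universe)
  .warn_screen_inputs(alignment, grouping, min_support)
  .scan_fixed_columns(
    alignment,
    target_rows = alignment$species %in% grouping$target_group,
    background_rows = alignment$species %in% grouping$adulterants,
    mode = "group_diagnostic",
    target_taxa = grouping$target_group,
    taxon_label = grouping$name)
}

#' Find species-diagnostic sites (one adulterant vs all other taxa)
#'
#' Contrasts one adulterant species (or a named joint taxon from the
#' grouping) against every other species in the grouping universe. By default
#' the background must itself be fixed for a single alternative base
#' (`background = "fixed"`); `background = "any"` relaxes this to "background
#' merely lacks the target allele", for exploratory use.
#'
#' @inheritParams find_group_diagnostic_sites
#' @param taxon A species label or the name of a joint taxon defined in the
#'   grouping.
#' @param background `"fixed"` (default) or `"any"`.
#'
#' @return A list of `diagnostic_site` objects (possibly empty).
#' @export
find_species_diagnostic_sites <- function(alignment, grouping, taxon,
                                          min_support = 2L,
                                          background = c("fixed", "any")) {
  stopifnot(inherits(alignment, "barcode_alignment"),
            inherits(grouping, "taxon_grouping"))
  background <- match.arg(background)
  if (taxon %in% names(grouping$joint_taxa)) {
    members <- grouping$joint_taxa[[taxon]]
  } else if (taxon %in% grouping$universe) {
    members <- taxon
  } else {
    herbq_error(sprintf("taxon '%s' is not in the grouping", taxon),
                "herbq_coverage_error")
  }
  .check_species_present(alignment, grouping$universe)
  .warn_screen_inputs(alignment, grouping, min_support)
  others <- setdiff(grouping$universe, members)
  .scan_fixed_columns(
    alignment,
    target_rows = alignment$species %in% members,
    background_rows = alignment$species %in% others,
    mode = "species_diagnostic",
    target_taxa = members,
    taxon_label = taxon,
    background = background)
}

#' Rank candidate sites for quantitative use
#'
#' Pyrosequencing dispensations of base A consume extra substrate during the
#' reaction, which distorts quantitative peak heights; group-diagnostic sites
#' whose target or background allele is A are therefore ranked below A-free
#' sites. The rule applies only to group-diagnostic sites: unique species
#' sites have no alternative, so base economy is not considered for them.
#' Ties break by `n_supporting` (descending) then position (ascending).
#'
#' @param sites Nonempty list of `diagnostic_site` objects.
#' @return The same sites, reordered.
#' @export
rank_sites_for_quantification <- function(sites) {
  if (length(sites) == 0L) {
    herbq_error("no sites to rank", "herbq_input_error")
  }
  uses_a <- vapply(sites, function(s) {
    s$mode == "group_diagnostic" &&
      "A" %in% c(s$target_allele, s$background_allele)
  }, logical(1L))
  n_sup <- vapply(sites, function(s) s$n_supporting, numeric(1L))
  pos <- vapply(sites, function(s) s$position, numeric(1L))
  sites[order(uses_a, -n_sup, pos)]
}

#' Extract the flanking sequence around a diagnostic site
#'
#' Returns the gap-stripped subsequence of a designated representative
#' accession (a real sequence, not a consensus, so the flank can be submitted
#' to BLAST), centred on the SNP. Default width 55 nt mirrors common
#' specificity-check practice. When the site sits too close to a sequence
#' end, the flank is truncated and flagged.
#'
#' @param alignment The [barcode_alignment()] the site was found in.
#' @param site A `diagnostic_site`.
#' @param width Total flank length in nucleotides (>= 1).
#' @param representative `sequence_id` of the accession to excerpt; default:
#'   the first accession belonging to the site's target taxa.
#'
#' @return A character scalar of class `herbq_flank` with attributes
#'   `snp_index` (position of the SNP base within the flank), `truncated`
#'   (logical) and `representative`.
#' @export
extract_flank <- function(alignment, site, width = 55L, representative = NULL) {
  stopifnot(inherits(alignment, "barcode_alignment"),
            inherits(site, "diagnostic_site"))
  if (!is_scalar_number(width) || width < 1L) {
    herbq_error("width must be a positive integer", "herbq_input_error")
  }
  width <- as.integer(width)
  if (is.null(representative)) {
    idx <- which(alignment$species %in% site$target_taxa)[1L]
    if (is.na(idx)) {
      herbq_error("no representative record for the site's target taxa",
                  "herbq_config_error")
    }
  } else {
    idx <- match(representative, alignment$sequence_id)
    if (is.na(idx)) {
      herbq_error(sprintf("representative record '%s' not in alignment",
                          representative), "herbq_config_error")
    }
  }
  chars <- strsplit(alignment$sequences[idx], "", fixed = TRUE)[[1L]]
  keep <- chars != "-"
  if (!keep[site$position]) {
    herbq_error(sprintf(
      "representative '%s' has a gap at column %d",
      alignment$sequence_id[idx], site$position), "herbq_config_error")
  }
  ungapped <- chars[keep]
  centre <- sum(keep[seq_len(site$position)])
  left <- (width - 1L) %/% 2L
  right <- width - 1L - left
  start <- max(1L, centre - left)
  end <- min(length(ungapped), centre + right)
  truncated <- (centre - left < 1L) || (centre + right > length(ungapped))
  structure(paste(ungapped[start:end], collapse = ""),
            snp_index = centre - start + 1L,
            truncated = truncated,
            representative = alignment$sequence_id[idx],
            class = c("herbq_flank", "character"))
}

#' @export
print.herbq_flank <- function(x, ...) {
  i <- attr(x, "snp_index")
  s <- unclass(x)
  marked <- paste0(substr(s, 1L, i - 1L), "[", substr(s, i, i), "]",
                   substr(s, i + 1L, nchar(s)))
  cat(sprintf("<flank %d nt%s, from %s> %s\n", nchar(s),
              if (attr(x, "truncated")) ", truncated" else "",
              attr(x, "representative"), marked))
  invisible(x)
}

#' Assemble a site panel from screening results
#'
#' Selects the top-ranked group-diagnostic site as the primary
#' identification site (A-free sites preferred, see
#' [rank_sites_for_quantification()]) plus one site per adulterant taxon when
#' available, and records which adulterant species remain uncovered.
#'
#' @param group_sites Nonempty list of group-diagnostic sites.
#' @param species_sites_by_taxon Named list (by species or joint-taxon label)
#'   of lists of species-diagnostic sites; empty entries are allowed.
#' @param grouping The [taxon_grouping()] the sites were screened against.
#' @param alignments Optional named list of alignments (by locus) used to
#'   attach flanks to the selected sites.
#' @param flank_width Flank width when `alignments` is given.
#'
#' @return An object of class `site_panel` with fields `sites` (named list by
#'   site id, primary first), `primary` (site id), `coverage` (named character
#'   vector: adulterant species -> site id or `"uncovered"`) and `grouping`.
#' @export
build_panel <- function(group_sites, species_sites_by_taxon, grouping,
                        alignments = NULL, flank_width = 55L) {
  stopifnot(inherits(grouping, "taxon_grouping"))
  if (length(group_sites) == 0L) {
    herbq_error("no group-diagnostic site: panel cannot be built",
                "herbq_panel_error")
  }
  primary <- rank_sites_for_quantification(group_sites)[[1L]]
  selected <- list(primary)
  for (taxon in names(species_sites_by_taxon)) {
    cand <- species_sites_by_taxon[[taxon]]
    if (length(cand) == 0L) next
    n_sup <- vapply(cand, function(s) s$n_supporting, numeric(1L))
    pos <- vapply(cand, function(s) s$position, numeric(1L))
    selected[[length(selected) + 1L]] <- cand[[order(-n_sup, pos)[1L]]]
  }
  ids <- vapply(selected, function(s) s$id, character(1L))
  if (anyDuplicated(ids)) {
    herbq_error(sprintf("duplicate site in panel: %s",
                        ids[duplicated(ids)][1L]), "herbq_panel_error")
  }
  names(selected) <- ids
  if (!is.null(alignments)) {
    for (id in ids) {
      locus <- selected[[id]]$locus
      if (!is.null(alignments[[locus]])) {
        selected[[id]]$flank <- as.character(
          extract_flank(alignments[[locus]], selected[[id]], flank_width))
      }
    }
  }
  coverage <- setNames(rep("uncovered", length(grouping$adulterants)),
                       grouping$adulterants)
  for (id in ids[-1L]) {
    covered <- intersect(selected[[id]]$target_taxa, grouping$adulterants)
    coverage[covered] <- id
  }
  structure(list(
    sites = selected,
    primary = primary$id,
    coverage = coverage,
    grouping = grouping
  ), class = "site_panel")
}

#' @export
print.site_panel <- function(x, ...) {
  cat(sprintf("<site_panel> %d sites (primary: %s)\n",
              length(x$sites), x$primary))
  for (s in x$sites) {
    cat(sprintf("  %-10s %-18s %-22s %s/%s\n", s$id, s$mode, s$taxon_label,
                s$target_allele,
                ifelse(is.na(s$background_allele), "*", s$background_allele)))
  }
  unc <- names(x$coverage)[x$coverage == "uncovered"]
  if (length(unc)) cat("  uncovered:", paste(unc, collapse = ", "), "\n")
  invisible(x)
}

#' Adulterant taxa to screen for species-diagnostic sites
#'
#' Joint taxa replace their member species in the scan list.
#'
#' @param grouping A [taxon_grouping()].
#' @return Character vector of taxon labels.
#' @export
species_scan_taxa <- function(grouping) {
  c(names(grouping$joint_taxa),
    setdiff(grouping$adulterants, unlist(grouping$joint_taxa)))
}
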