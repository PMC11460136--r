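# Serialisation of site panels and measurement tables.

.sites_as_df <- function(panel) {
  do.call(rbind, lapply(panel$sites, function(s) {
    data.frame(
      id = s$id, locus = s$locus, position = s$position, mode = s$mode,
      taxon_label = s$taxon_label,
      target_taxa = paste(s$target_taxa, collapse = ";"),
      target_allele = s$target_allele,
      background_allele = ifelse(is.na(s$background_allele), "",
                                 s$background_allele),
      n_supporting = s$n_supporting,
      flank = ifelse(is.na(s$flank), "", s$flank),
      stringsAsFactors = FALSE)
  }))
}

#' Write a site panel report as TSV
#'
#' One row per site: locus, position, mode, taxa, target/background alleles,
#' support and flank.
#'
#' @param panel A [build_panel()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel_tsv <- function(panel, path) {
  stopifnot(inherits(panel, "site_panel"))
  write.table(.sites_as_df(panel), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a site panel (with its grouping) as JSON
#'
#' The JSON form is complete: [read_panel_json()] reconstructs the panel,
#' including the taxon grouping, so downstream commands need no other input.
#'
#' @inheritParams write_panel_tsv
#' @return `path`, invisibly.
#' @export
write_panel_json <- function(panel, path) {
  stopifnot(inherits(panel, "site_panel"))
  g <- panel$grouping
  obj <- list(
    primary = panel$primary,
    coverage = as.list(panel$coverage),
    grouping = list(
      name = g$name,
      target_group = g$target_group,
      adulterants = g$adulterants,
      joint_taxa = g$joint_taxa
    ),
    sites = lapply(unname(panel$sites), function(s) {
      list(locus = s$locus, position = s$position, mode = s$mode,
           taxon_label = s$taxon_label, target_taxa = s$target_taxa,
           target_allele = s$target_allele,
           background_allele = s$background_allele,
           n_supporting = s$n_supporting, flank = s$flank)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null",
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a site panel from JSON
#'
#' @param path Path written by [write_panel_json()].
#' @return A `site_panel`.
#' @export
read_panel_json <- function(path) {
  if (!file.exists(path)) {
    herbq_error(sprintf("panel file not found: %s", path), "herbq_input_error")
  }
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  g <- obj$grouping
  grouping <- taxon_grouping(
    unlist(g$target_group), unlist(g$adulterants),
    joint_taxa = lapply(g$joint_taxa %||% list(), unlist),
    name = g$name %||% "target")
  sites <- lapply(obj$sites, function(s) {
    diagnostic_site(
      locus = s$locus, position = s$position, mode = s$mode,
      target_taxa = unlist(s$target_taxa), taxon_label = s$taxon_label,
      target_allele = s$target_allele,
      background_allele = s$background_allele %||% NA_character_,
      n_supporting = s$n_supporting,
      flank = s$flank %||% NA_character_)
  })
  names(sites) <- vapply(sites, function(s) s$id, character(1L))
  structure(list(
    sites = sites,
    primary = obj$primary,
    coverage = unlist(obj$coverage),
    grouping = grouping
  ), class = "site_panel")
}

#' Export site flanks as FASTA for external specificity checks
#'
#' @param panel A `site_panel` whose sites carry flanks (see
#'   [build_panel()]'s `alignments` argument).
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_flanks_fasta <- function(panel, path) {
  stopifnot(inherits(panel, "site_panel"))
  with_flank <- Filter(function(s) !is.na(s$flank) && nzchar(s$flank),
                       panel$sites)
  if (length(with_flank) == 0L) {
    herbq_error("no flanks attached to panel sites", "herbq_input_error")
  }
  lines <- unlist(lapply(with_flank, function(s) {
    c(sprintf(">%s %s %s %s/%s", s$id, s$mode, gsub(" ", "_", s$taxon_label),
              s$target_allele,
              ifelse(is.na(s$background_allele), "*", s$background_allele)),
      s$flank)
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}

.MEAS_COLS <- c("sample_id", "locus", "position", "allele", "replicate",
                "frequency")

#' Write an allele-frequency measurement table as TSV
#'
#' Standard columns: `sample_id`, `locus`, `position`, `allele`, `replicate`,
#' `frequency` (plus any extras such as `level`). A `# seed:` header comment
#' records the simulation seed when one is supplied.
#'
#' @param measurements Measurement data.frame.
#' @param path Output path.
#' @param seed Optional seed to record in the header.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(measurements, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", as.integer(seed)), con)
  write.table(measurements, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an allele-frequency measurement table
#'
#' @param path TSV path; `#`-prefixed header comments are skipped. Must carry
#'   at least `locus`, `position`, `allele`, `replicate` and `frequency`.
#' @return A data.frame.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) {
    herbq_error(sprintf("measurement file not found: %s", path),
                "herbq_input_error")
  }
  tab <- tryCatch(
    read.delim(path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) {
      herbq_error(sprintf("cannot parse measurement TSV '%s': %s",
                          path, conditionMessage(e)), "herbq_input_error")
    })
  needed <- setdiff(c("locus", "position", "allele", "replicate", "frequency"),
                    names(tab))
  if (length(needed)) {
    herbq_error(sprintf("measurement table lacks columns: %s",
                        paste(needed, collapse = ", ")), "herbq_input_error")
  }
  if (!is.numeric(tab$frequency) ||
      any(tab$frequency < 0 | tab$frequency > 1, na.rm = TRUE)) {
    herbq_error("frequencies must be numeric in [0, 1]", "herbq_input_error")
  }
  tab
}
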