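# External-standard quantification: standard curves, the two-step weight
# calculation, presence calls and sample-level deconvolution.
#
# Two-step mass math (the heart of the method): with a spiked external
# standard of known mass w_ext measured at allele frequency r_ext,
#   w_total = w_ext / r_ext                (total amplifying-material weight)
#   w_species = w_total * r_species        (per-species weight)
# Frequencies enter these equations directly, as replicate means; an optional
# fitted standard curve can invert the instrument response first.

#' Fit a quantitative standard curve
#'
#' Ordinary least squares of mean allele frequency on mixing proportion.
#' Replicate frequencies at the same proportion are averaged before fitting.
#' The curve passes the linearity gate when the coefficient of determination
#' R^2 is at least `r2_min` (default 0.99).
#'
#' @param points Data.frame with columns `proportion` and `frequency`
#'   (replicate rows allowed), or a 2-column numeric data.frame in that
#'   order. At least 3 distinct proportions with nonzero variance.
#' @param r2_min Linearity gate on R^2.
#'
#' @return An object of class `standard_curve` with fields `slope`,
#'   `intercept`, `r_squared`, `points` (the averaged points) and
#'   `passes_linearity`.
#' @export
fit_standard_curve <- function(points, r2_min = 0.99) {
  if (!is.data.frame(points)) {
    herbq_error("points must be a data.frame", "herbq_input_error")
  }
  if (!all(c("proportion", "frequency") %in% names(points))) {
    if (ncol(points) == 2L && all(vapply(points, is.numeric, logical(1L)))) {
      names(points) <- c("proportion", "frequency")
    } else {
      herbq_error("points must have columns 'proportion' and 'frequency'",
                  "herbq_input_error")
    }
  }
  mean_f <- tapply(points$frequency, points$proportion, mean)
  agg <- data.frame(proportion = as.numeric(names(mean_f)),
                    frequency = as.numeric(mean_f))
  if (nrow(agg) < 3L) {
    herbq_error("at least 3 distinct proportions are required",
                "herbq_input_error")
  }
  if (stats::var(agg$proportion) == 0) {
    herbq_error("proportions have zero variance: cannot fit a line",
                "herbq_degenerate_error")
  }
  fit <- lm(frequency ~ proportion, data = agg)
  # coefficient of determination computed directly: summary.lm warns on
  # numerically perfect fits, which are routine for noise-free series
  sst <- sum((agg$frequency - mean(agg$frequency))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  structure(list(
    slope = unname(coef(fit)[2L]),
    intercept = unname(coef(fit)[1L]),
    r_squared = r2,
    points = agg,
    r2_min = r2_min,
    passes_linearity = r2 >= r2_min
  ), class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve> y = %.4f x + %.4f, R^2 = %.4f (%s, gate %.2f)\n",
              x$slope, x$intercept, x$r_squared,
              if (x$passes_linearity) "passes" else "FAILS", x$r2_min))
  invisible(x)
}

#' Invert a standard curve
#'
#' Maps a measured frequency back to a mixing proportion,
#' `x = (y - intercept) / slope`.
#'
#' @param curve A [fit_standard_curve()] result.
#' @param frequency Measured frequency (vectorised).
#' @return Estimated proportion(s).
#' @export
invert_curve <- function(curve, frequency) {
  stopifnot(inherits(curve, "standard_curve"))
  (frequency - curve$intercept) / curve$slope
}

#' Total amplifying-material weight from the external standard
#'
#' `w_ext / r_ext`: the known spiked mass divided by the standard's measured
#' allele frequency at its species-diagnostic site.
#'
#' @param w_ext Spiked mass of the external standard in grams (> 0).
#' @param r_ext Measured mean allele frequency of the standard, in `(0, 1]`.
#'
#' @return Total weight in grams.
#' @export
total_weight <- function(w_ext, r_ext) {
  if (!is_scalar_number(w_ext) || w_ext <= 0) {
    herbq_error("external-standard weight must be > 0 g", "herbq_input_error")
  }
  if (!is_scalar_number(r_ext)) {
    herbq_error("r_ext must be a single number", "herbq_input_error")
  }
  if (r_ext > 1) {
    herbq_error("r_ext is a frequency and cannot exceed 1", "herbq_input_error")
  }
  if (r_ext <= 0) {
    herbq_error(
      "standard allele frequency is 0: sample cannot be quantified",
      "herbq_unquantifiable_error")
  }
  w_ext / r_ext
}

#' Component weight from the total weight
#'
#' `w_total * r_tar`: the total amplifying weight multiplied by the
#' component's measured mean allele frequency at the appropriate site.
#'
#' @param w_total Total weight in grams (> 0).
#' @param r_tar Component allele frequency in `[0, 1]` (vectorised).
#'
#' @return Component weight(s) in grams.
#' @export
component_weight <- function(w_total, r_tar) {
  if (!is_scalar_number(w_total) || w_total <= 0) {
    herbq_error("total weight must be > 0 g", "herbq_input_error")
  }
  if (!is.numeric(r_tar) || any(!is.finite(r_tar)) ||
      any(r_tar < 0 | r_tar > 1)) {
    herbq_error("component frequencies must lie in [0, 1]",
                "herbq_input_error")
  }
  w_total * r_tar
}

#' Percent bias between calculated and actual weights
#'
#' `|calculated - actual| / actual * 100`, with a pass flag at the
#' acceptance bound (default 25%).
#'
#' @param calculated Calculated weight(s), grams.
#' @param actual Actual weight(s), grams (> 0); recycled against
#'   `calculated`.
#' @param bound Acceptance bound in percent.
#'
#' @return Numeric vector of percent biases with a logical attribute `pass`
#'   (`bias < bound`).
#' @export
compute_bias <- function(calculated, actual, bound = 25) {
  if (!is.numeric(calculated) || !is.numeric(actual)) {
    herbq_error("weights must be numeric", "herbq_input_error")
  }
  if (any(actual <= 0)) {
    herbq_error("actual weights must be > 0", "herbq_input_error")
  }
  bias <- abs(calculated - actual) / actual * 100
  structure(bias, pass = unname(bias < bound))
}

#' Presence call at one diagnostic site
#'
#' An allele is "present" when its mean frequency across replicates reaches
#' `threshold` (default 0.02, the assay's validated quantification floor).
#' The site call is `"pure_target"`, `"pure_background"` or `"mixed"`. When
#' only one of the two alleles appears in the table, the other's frequency
#' is taken as its complement.
#'
#' @param measurements Measurement data.frame (see [read_measurements()]).
#' @param site A `diagnostic_site`.
#' @param threshold Presence threshold in `(0, 0.5]`.
#'
#' @return An object of class `presence_call`: list with `site_id`, `call`,
#'   `frequencies` (named `target`/`background` means) and `threshold`.
#' @export
call_presence <- function(measurements, site, threshold = 0.02) {
  stopifnot(inherits(site, "diagnostic_site"))
  if (!is_scalar_number(threshold) || threshold <= 0 || threshold > 0.5) {
    herbq_error("threshold must lie in (0, 0.5]", "herbq_input_error")
  }
  rows <- measurements$locus == site$locus &
    measurements$position == site$position
  if (!any(rows)) {
    herbq_error(sprintf("no measurements for site %s", site$id),
                "herbq_missing_data_error")
  }
  sub <- measurements[rows, , drop = FALSE]
  mean_by_allele <- tapply(sub$frequency, sub$allele, mean)
  f_target <- mean_by_allele[site$target_allele]
  bg <- site$background_allele
  f_background <- if (!is.na(bg)) mean_by_allele[bg] else NA_real_
  if (is.na(f_target) && is.na(f_background)) {
    herbq_error(sprintf(
      "measurements at %s carry neither the target nor the background allele",
      site$id), "herbq_missing_data_error")
  }
  if (is.na(f_target)) f_target <- 1 - f_background
  if (is.na(f_background)) f_background <- 1 - f_target
  target_present <- f_target >= threshold
  background_present <- f_background >= threshold
  call <- if (target_present && background_present) {
    "mixed"
  } else if (target_present) {
    "pure_target"
  } else {
    "pure_background"
  }
  structure(list(
    site_id = site$id,
    call = call,
    frequencies = c(target = unname(f_target),
                    background = unname(f_background)),
    threshold = threshold
  ), class = "presence_call")
}

#' Identify the species composition of a sample from panel calls
#'
#' A pure-target call at the primary group site means the sample contains
#' only the target group. A mixed group call adds every adulterant taxon
#' whose species-diagnostic site is positive (target allele present); a
#' mixed group call with no positive species site yields an unresolved flag
#' — an adulterant is present but cannot be typed, and missing species-site
#' data never silently degrades to "pure".
#'
#' @param calls Named list of [call_presence()] results keyed by site id;
#'   must include the panel's primary site. Sites without data may be
#'   omitted or `NULL`.
#' @param panel The `site_panel` the calls were made against.
#'
#' @return An object of class `composition`: list with `species` (character
#'   vector of identified taxa, the target group appearing under its group
#'   name), `unresolved` (logical) and `group_call`.
#' @export
identify_composition <- function(calls, panel) {
  stopifnot(inherits(panel, "site_panel"))
  group_call <- calls[[panel$primary]]
  if (is.null(group_call)) {
    herbq_error("no presence call for the primary group site",
                "herbq_missing_data_error")
  }
  g <- panel$grouping
  species_sites <- Filter(function(s) s$mode == "species_diagnostic",
                          panel$sites)
  positives <- character(0)
  for (s in species_sites) {
    cl <- calls[[s$id]]
    if (!is.null(cl) && cl$call %in% c("mixed", "pure_target")) {
      positives <- c(positives, s$taxon_label)
    }
  }
  if (group_call$call == "pure_target") {
    return(structure(list(species = g$name, unresolved = FALSE,
                          group_call = group_call$call),
                     class = "composition"))
  }
  species <- if (group_call$call == "mixed") c(g$name, positives) else positives
  unresolved <- length(positives) == 0L
  structure(list(species = species, unresolved = unresolved,
                 group_call = group_call$call),
            class = "composition")
}

#' @export
print.composition <- function(x, ...) {
  cat(sprintf("<composition> group site: %s; taxa: %s%s\n", x$group_call,
              if (length(x$species)) paste(x$species, collapse = ", ") else "(none)",
              if (x$unresolved) " [UNRESOLVED adulterant present]" else ""))
  invisible(x)
}

#' Choose an external standard absent from the sample
#'
#' The standard must be a species the sample does not contain, so that its
#' diagnostic-site signal is attributable solely to the spiked mass.
#' Returns the first such candidate.
#'
#' @param composition A [identify_composition()] result or character vector
#'   of taxa present in the sample.
#' @param candidates Ordered character vector of candidate species, each of
#'   which must have a species-diagnostic site in the panel in use.
#'
#' @return A species label.
#' @export
select_external_standard <- function(composition, candidates) {
  if (inherits(composition, "composition")) {
    composition <- composition$species
  }
  if (length(candidates) == 0L) {
    herbq_error("no candidate standards supplied", "herbq_input_error")
  }
  free <- setdiff(candidates, composition)
  if (length(free) == 0L) {
    herbq_error("every candidate standard is already present in the sample",
                "herbq_no_standard_error")
  }
  free[1L]
}

#' Bundle a quantification request
#'
#' @param sample_id Sample label.
#' @param external_standard Species label of the spiked standard.
#' @param w_ext Spiked mass in grams (> 0).
#' @param measurements Measurement data.frame covering at least the primary
#'   group site and the standard's species site.
#' @param actual_weights Optional named numeric vector of known true
#'   component weights (grams) for bias assessment.
#'
#' @return An object of class `quant_sample`.
#' @export
quant_sample <- function(sample_id, external_standard, w_ext, measurements,
                         actual_weights = NULL) {
  if (!is_string(sample_id) || !is_string(external_standard)) {
    herbq_error("sample_id and external_standard must be single names",
                "herbq_input_error")
  }
  if (!is_scalar_number(w_ext) || w_ext <= 0) {
    herbq_error("external-standard weight must be > 0 g", "herbq_input_error")
  }
  if (!is.data.frame(measurements)) {
    herbq_error("measurements must be a data.frame", "herbq_input_error")
  }
  structure(list(
    sample_id = sample_id,
    external_standard = external_standard,
    w_ext = w_ext,
    measurements = measurements,
    actual_weights = actual_weights
  ), class = "quant_sample")
}

.standard_site <- function(panel, standard) {
  for (s in panel$sites) {
    if (s$mode == "species_diagnostic" &&
        (identical(s$taxon_label, standard) || standard %in% s$target_taxa)) {
      return(s)
    }
  }
  herbq_error(sprintf(
    "external standard '%s' has no species-diagnostic site in the panel",
    standard), "herbq_config_error")
}

#' Quantify a sample against a site panel
#'
#' Full sample-level workflow: presence calls at every measured panel site,
#' composition identification, total weight from the external standard
#' (`w_ext / r_ext`), and per-component weights (`w_total * r`). Replicate
#' frequencies are averaged per site before any weight math. A consistency
#' warning is emitted when the frequencies of all identified components
#' (standard included) sum outside `1 ± freq_tol`. Quantification is refused
#' (classed error) when the composition is unresolved — mass is present that
#' cannot be attributed to a typed species.
#'
#' @param sample A [quant_sample()].
#' @param panel A `site_panel` (carries its grouping).
#' @param threshold Presence threshold for composition calls.
#' @param freq_tol Tolerance on the frequency-sum consistency check.
#' @param curve Optional [fit_standard_curve()] result; when supplied,
#'   measured frequencies are mapped through [invert_curve()] before the
#'   weight equations (off by default: raw frequencies are the standard
#'   usage).
#'
#' @return An object of class `quant_result`: `w_total`,
#'   `component_weights`, `frequencies_used`, `biases` (where actual weights
#'   were given), `composition`, plus the request fields. Weights are stored
#'   at full precision; printing rounds to 4 decimals.
#' @export
quantify_sample <- function(sample, panel, threshold = 0.02,
                            freq_tol = 0.05, curve = NULL) {
  stopifnot(inherits(sample, "quant_sample"), inherits(panel, "site_panel"))
  calls <- list()
  for (id in names(panel$sites)) {
    calls[[id]] <- tryCatch(
      call_presence(sample$measurements, panel$sites[[id]], threshold),
      herbq_missing_data_error = function(e) NULL)
  }
  calls <- Filter(Negate(is.null), calls)
  composition <- identify_composition(calls, panel)
  if (composition$unresolved) {
    herbq_error(paste(
      "adulterant present but not typed by any species site:",
      "quantification refused for untyped mass"), "herbq_unresolved_error")
  }
  std_site <- .standard_site(panel, sample$external_standard)
  if (is.null(calls[[std_site$id]])) {
    herbq_error(sprintf("no measurements at the standard's site %s",
                        std_site$id), "herbq_missing_data_error")
  }
  as_proportion <- function(f) {
    if (is.null(curve)) f else invert_curve(curve, f)
  }
  r_ext <- as_proportion(calls[[std_site$id]]$frequencies[["target"]])
  w_total <- total_weight(sample$w_ext, r_ext)

  freqs <- c()
  std_label <- std_site$taxon_label
  g <- panel$grouping
  if (g$name %in% composition$species) {
    freqs[g$name] <- as_proportion(calls[[panel$primary]]$frequencies[["target"]])
  }
  for (s in panel$sites) {
    if (s$mode != "species_diagnostic") next
    if (s$taxon_label %in% composition$species ||
        identical(s$taxon_label, std_label)) {
      if (!is.null(calls[[s$id]])) {
        freqs[s$taxon_label] <- as_proportion(calls[[s$id]]$frequencies[["target"]])
      }
    }
  }
  freqs[std_label] <- r_ext
  weights <- component_weight(w_total, pmax(pmin(freqs, 1), 0))

  fsum <- sum(freqs)
  if (abs(fsum - 1) > freq_tol) {
    herbq_warning(sprintf(
      "component frequencies sum to %.3f, outside 1 +/- %.2f: possible untyped or co-measured material",
      fsum, freq_tol), "herbq_consistency_warning")
  }
  biases <- NULL
  if (!is.null(sample$actual_weights)) {
    common <- intersect(names(sample$actual_weights), names(weights))
    if (length(common)) {
      biases <- compute_bias(weights[common], sample$actual_weights[common])
      names(biases) <- common
    }
  }
  structure(list(
    sample_id = sample$sample_id,
    external_standard = sample$external_standard,
    w_ext = sample$w_ext,
    w_total = w_total,
    component_weights = weights,
    frequencies_used = freqs,
    biases = biases,
    composition = composition,
    threshold = threshold
  ), class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf("<quant_result> %s (standard %s, %.4f g spiked)\n",
              x$sample_id, x$external_standard, x$w_ext))
  cat(sprintf("  total amplifying weight: %.4f g\n", x$w_total))
  for (nm in names(x$component_weights)) {
    b <- if (!is.null(x$biases) && nm %in% names(x$biases)) {
      sprintf("  bias %.3f%% [%s]", x$biases[[nm]],
              if (abs(x$biases[[nm]]) < 25) "pass" else "FAIL")
    } else ""
    cat(sprintf("  %-28s %3.0f%%  %.4f g%s\n", nm,
                100 * x$frequencies_used[[nm]],
                x$component_weights[[nm]], b))
  }
  invisible(x)
}

#' Write a quantification result as JSON and/or TSV
#'
#' The report layer rounds weights to 4 decimals (grams) and frequencies to
#' whole percent; the in-memory object keeps full precision.
#'
#' @param result A [quantify_sample()] result.
#' @param json_path,tsv_path Output paths (either may be `NULL`).
#' @return Invisibly, the report data.frame.
#' @export
write_quant_result <- function(result, json_path = NULL, tsv_path = NULL) {
  stopifnot(inherits(result, "quant_result"))
  comps <- names(result$component_weights)
  report <- data.frame(
    component = comps,
    frequency_pct = round(100 * as.numeric(result$frequencies_used[comps])),
    weight_g = round(as.numeric(result$component_weights[comps]), 4L),
    bias_pct = vapply(comps, function(nm) {
      if (!is.null(result$biases) && nm %in% names(result$biases)) {
        round(result$biases[[nm]], 3L)
      } else NA_real_
    }, numeric(1L)),
    stringsAsFactors = FALSE)
  report$bias_pass <- ifelse(is.na(report$bias_pct), NA,
                             report$bias_pct < 25)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      sample_id = result$sample_id,
      external_standard = result$external_standard,
      w_ext_g = result$w_ext,
      w_total_g = round(result$w_total, 4L),
      composition = result$composition$species,
      components = report
    ), json_path, auto_unbox = TRUE, na = "null", pretty = TRUE, digits = NA)
  }
  if (!is.null(tsv_path)) {
    write.table(report, tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(report)
}
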