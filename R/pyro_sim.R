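# Synthetic pyrosequencing measurements.
#
# Observation model per site and replicate:
#   observed = clamp(slope * expected + intercept + eps, 0, 1),
#   eps ~ Normal(0, noise_sd),
# where `expected` is the mass-share frequency under the equal-yield
# assumption, and the complementary allele is mirrored as 1 - observed so a
# biallelic site always sums to exactly 1 within a replicate. The instrument
# reports allele frequencies, which is the level the quantification math
# consumes; pyrogram peak traces are not modelled.

#' Specify a ground-truth mixture for simulation
#'
#' @param components Named numeric vector: species label -> mass in grams.
#'   All masses >= 0, at least one positive.
#' @param impurity_mass Grams of non-amplifying material (soil, flour); it
#'   contributes to total powder mass but never to allele frequencies.
#' @param yield_factor Optional named numeric vector of relative DNA yield
#'   per unit mass. Default 1 for every component — the equal-yield
#'   assumption under which allele frequency equals mass share. Non-unit
#'   values exist solely for sensitivity analysis and deviate from the
#'   quantification model.
#' @param noise_sd Standard deviation of replicate frequency noise, absolute
#'   on the `[0, 1]` scale. Default 0.005, which places the assay's
#'   quantification floor near a 2% mass fraction (population RSD 25% at
#'   a measured frequency of 0.02).
#' @param distortion Length-2 numeric `(slope, intercept)` of the affine
#'   frequency response; identity by default. Fitted assay responses such as
#'   `c(0.994, 0.002)` can be plugged in to emulate a calibrated instrument.
#' @param seed Optional RNG seed making simulations reproducible.
#'
#' @return An object of class `mixture_spec`.
#' @export
mixture_spec <- function(components, impurity_mass = 0, yield_factor = NULL,
                         noise_sd = 0.005, distortion = c(1, 0), seed = NULL) {
  if (!is.numeric(components) || is.null(names(components)) ||
      any(!nzchar(names(components)))) {
    herbq_error("components must be a named numeric vector of masses",
                "herbq_input_error")
  }
  if (anyDuplicated(names(components))) {
    herbq_error("duplicated component species", "herbq_input_error")
  }
  if (any(components < 0) || any(!is.finite(components))) {
    herbq_error("component masses must be finite and >= 0", "herbq_input_error")
  }
  if (!any(components > 0)) {
    herbq_error("at least one component mass must be positive",
                "herbq_input_error")
  }
  if (!is_scalar_number(impurity_mass) || impurity_mass < 0) {
    herbq_error("impurity_mass must be a single number >= 0",
                "herbq_input_error")
  }
  if (is.null(yield_factor)) {
    yield_factor <- setNames(rep(1, length(components)), names(components))
  }
  missing_y <- setdiff(names(components), names(yield_factor))
  if (length(missing_y)) {
    herbq_error(sprintf("yield_factor missing for: %s",
                        paste(missing_y, collapse = ", ")),
                "herbq_input_error")
  }
  if (any(yield_factor <= 0)) {
    herbq_error("yield factors must be > 0", "herbq_input_error")
  }
  if (!is_scalar_number(noise_sd) || noise_sd < 0) {
    herbq_error("noise_sd must be a single number >= 0", "herbq_input_error")
  }
  if (!is.numeric(distortion) || length(distortion) != 2L) {
    herbq_error("distortion must be c(slope, intercept)", "herbq_input_error")
  }
  structure(list(
    components = components,
    impurity_mass = impurity_mass,
    yield_factor = yield_factor[names(components)],
    noise_sd = noise_sd,
    distortion = unname(distortion),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "mixture_spec")
}

#' @export
print.mixture_spec <- function(x, ...) {
  cat(sprintf(
    "<mixture_spec> %d components, %.4f g amplifying + %.4f g impurity; noise_sd=%g, response=%gx+%g\n",
    length(x$components), sum(x$components), x$impurity_mass, x$noise_sd,
    x$distortion[1L], x$distortion[2L]))
  invisible(x)
}

#' Genotype map implied by a diagnostic site
#'
#' Species among the site's target taxa carry the target allele; all other
#' species carry the background allele.
#'
#' @param site A `diagnostic_site`.
#' @param species Character vector of species labels.
#' @return Named character vector: species -> allele.
#' @export
site_genotypes <- function(site, species) {
  stopifnot(inherits(site, "diagnostic_site"))
  if (is.na(site$background_allele)) {
    herbq_error("site has no fixed background allele; supply genotypes explicitly",
                "herbq_input_error")
  }
  setNames(ifelse(species %in% site$target_taxa,
                  site$target_allele, site$background_allele), species)
}

#' Expected target-allele frequency of a mixture at a site
#'
#' Under the equal-yield model the frequency is the DNA-weighted mass share:
#' `sum(mass * yield over species carrying the target allele) /
#' sum(mass * yield over all amplifying components)`. Non-amplifying impurity
#' mass is excluded from both sums, so adding soil or flour leaves every
#' frequency unchanged.
#'
#' @param mixture A [mixture_spec()].
#' @param site A `diagnostic_site`.
#' @param genotypes Optional named character vector (species -> allele) at
#'   the site; defaults to [site_genotypes()] over the mixture's components.
#'
#' @return Frequency in `[0, 1]`.
#' @export
expected_frequency <- function(mixture, site, genotypes = NULL) {
  stopifnot(inherits(mixture, "mixture_spec"),
            inherits(site, "diagnostic_site"))
  sp <- names(mixture$components)
  if (is.null(genotypes)) genotypes <- site_genotypes(site, sp)
  missing_g <- setdiff(sp, names(genotypes))
  if (length(missing_g)) {
    herbq_error(sprintf("no genotype at %s for: %s", site$id,
                        paste(missing_g, collapse = ", ")),
                "herbq_input_error")
  }
  dna <- mixture$components * mixture$yield_factor
  total <- sum(dna)
  if (total <= 0) {
    herbq_error("mixture has zero amplifying mass", "herbq_degenerate_error")
  }
  sum(dna[genotypes[sp] == site$target_allele]) / total
}

.panel_sites <- function(panel) {
  if (inherits(panel, "diagnostic_site")) {
    return(setNames(list(panel), panel$id))
  }
  stopifnot(inherits(panel, "site_panel"))
  panel$sites
}

#' Simulate replicate allele-frequency measurements
#'
#' For each site and replicate the observed target-allele frequency is
#' `clamp(slope * expected + intercept + eps, 0, 1)` with
#' `eps ~ Normal(0, noise_sd)`; the complementary allele is emitted as
#' `1 - observed`. Runs are deterministic for a fixed `seed` in the mixture
#' spec.
#'
#' @param mixture A [mixture_spec()].
#' @param panel A `site_panel` or a single `diagnostic_site`.
#' @param n_replicates Number of technical replicates (>= 1).
#' @param genotypes Optional list keyed by site id of named genotype vectors;
#'   defaults to [site_genotypes()] per site.
#' @param sample_id Sample label written into the table.
#'
#' @return A data.frame with columns `sample_id`, `locus`, `position`,
#'   `allele`, `replicate`, `frequency` (two rows per site and replicate).
#' @export
simulate_measurements <- function(mixture, panel, n_replicates,
                                  genotypes = NULL, sample_id = "sample") {
  stopifnot(inherits(mixture, "mixture_spec"))
  if (!is_scalar_number(n_replicates) || n_replicates < 1L) {
    herbq_error("n_replicates must be >= 1", "herbq_input_error")
  }
  n_replicates <- as.integer(n_replicates)
  if (!is.null(mixture$seed)) set.seed(mixture$seed)
  sites <- .panel_sites(panel)
  slope <- mixture$distortion[1L]
  intercept <- mixture$distortion[2L]
  blocks <- lapply(sites, function(site) {
    e <- expected_frequency(mixture, site, genotypes[[site$id]])
    eps <- if (mixture$noise_sd > 0) {
      rnorm(n_replicates, 0, mixture$noise_sd)
    } else {
      numeric(n_replicates)
    }
    obs <- pmin(1, pmax(0, slope * e + intercept + eps))
    bg <- ifelse(is.na(site$background_allele), "other",
                 site$background_allele)
    data.frame(
      sample_id = sample_id,
      locus = site$locus,
      position = site$position,
      allele = rep(c(site$target_allele, bg), each = n_replicates),
      replicate = rep(seq_len(n_replicates), 2L),
      frequency = c(obs, 1 - obs),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, unname(blocks))
  rownames(out) <- NULL
  out
}

#' Simulate a dilution (adulteration) series
#'
#' Emulates spiking a genuine powder with increasing mass fractions of one
#' adulterant: at level `f` the base components are scaled to `(1 - f)` of
#' the total amplifying mass and the adulterant supplies the remaining `f`.
#' Noise, response and seed come from the base mixture spec; one measurement
#' block per level is emitted with its ground-truth level label, directly
#' consumable by [validate_assay()].
#'
#' @param base A [mixture_spec()] describing the genuine powder (the
#'   adulterant must not be among its components).
#' @param adulterant Species label of the spiked adulterant.
#' @param levels Numeric vector of adulteration mass fractions in `(0, 1]`.
#' @param n_replicates Replicates per level (20 is typical for detection
#'   studies).
#' @param site The assay `diagnostic_site` (or a `site_panel` to measure all
#'   sites).
#' @param genotypes Optional genotype list as in [simulate_measurements()].
#'
#' @return A data.frame: `level` plus the [simulate_measurements()] columns.
#' @export
simulate_dilution_series <- function(base, adulterant, levels, n_replicates,
                                     site, genotypes = NULL) {
  stopifnot(inherits(base, "mixture_spec"))
  if (!is_string(adulterant)) {
    herbq_error("adulterant must be a species label", "herbq_input_error")
  }
  if (adulterant %in% names(base$components)) {
    herbq_error("adulterant already present in the base mixture",
                "herbq_input_error")
  }
  if (length(levels) == 0L) {
    return(data.frame(level = numeric(0), sample_id = character(0),
                      locus = character(0), position = integer(0),
                      allele = character(0), replicate = integer(0),
                      frequency = numeric(0), stringsAsFactors = FALSE))
  }
  if (!is.numeric(levels) || any(levels <= 0 | levels > 1)) {
    herbq_error("adulteration levels must lie in (0, 1]", "herbq_input_error")
  }
  if (!is.null(base$seed)) set.seed(base$seed)
  total <- sum(base$components)
  blocks <- lapply(seq_along(levels), function(i) {
    f <- levels[i]
    comps <- c(base$components * (1 - f), setNames(f * total, adulterant))
    mix <- mixture_spec(comps, impurity_mass = base$impurity_mass,
                        noise_sd = base$noise_sd,
                        distortion = base$distortion, seed = NULL)
    m <- simulate_measurements(mix, site, n_replicates,
                               genotypes = genotypes,
                               sample_id = sprintf("level_%g", f))
    cbind(level = f, m)
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}
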