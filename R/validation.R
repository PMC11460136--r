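# Assay validation calculus: repeatability, LOD by stable-detection rate,
# LOQ by relative standard deviation, and a one-shot report assembler.

#' Repeatability summary of replicate measurements
#'
#' Mean and relative standard deviation (RSD) of replicate measured
#' proportions. The RSD uses the sample (n-1) standard deviation divided by
#' the mean, in percent — the convention that reproduces published
#' replicate tables for this assay class.
#'
#' @param values Numeric vector of replicate measured proportions
#'   (length >= 2, nonzero mean).
#' @return List with `n`, `mean`, `sd` and `rsd` (percent).
#' @export
repeatability_stats <- function(values) {
  if (!is.numeric(values) || length(values) < 2L) {
    herbq_error("at least 2 replicate values are required",
                "herbq_input_error")
  }
  m <- mean(values)
  if (m == 0) {
    herbq_error("mean is zero: RSD undefined", "herbq_degenerate_error")
  }
  s <- sd(values)
  list(n = length(values), mean = m, sd = s, rsd = s / m * 100)
}

# Normalise per-level inputs. Accepts a named numeric vector (names =
# levels, values = the per-level statistic) or a data.frame carrying `level`
# plus a value column; returns a numeric vector named by level, sorted.
.per_level <- function(series, value_col, agg) {
  if (is.numeric(series) && !is.null(names(series))) {
    v <- series
  } else if (is.data.frame(series) && all(c("level", value_col) %in% names(series))) {
    v <- tapply(series[[value_col]], series$level, agg)
    v <- setNames(as.numeric(v), names(v))
  } else {
    herbq_error(sprintf(
      "series must be a named numeric vector or a data.frame with columns 'level' and '%s'",
      value_col), "herbq_input_error")
  }
  if (length(v) == 0L) {
    herbq_error("empty level series", "herbq_input_error")
  }
  v[order(as.numeric(names(v)))]
}

# Lowest level passing its criterion with every higher tested level also
# passing (the stability clause); NA when none qualifies.
.lowest_stable <- function(levels, pass) {
  ok <- rev(cumprod(rev(pass))) == 1
  if (!any(ok)) return(NA_real_)
  levels[which(ok)[1L]]
}

#' Limit of detection by stable-detection rate
#'
#' The LOD is the lowest adulteration level whose per-replicate detection
#' rate reaches `detection_min` (default 0.95) with every higher tested
#' level also passing. Returns `NA` (flagged) when no level qualifies.
#'
#' @param series Either a data.frame with columns `level` and `detected`
#'   (logical per replicate; a warning is emitted for levels with fewer than
#'   20 replicates), or a named numeric vector of per-level detection rates.
#' @param detection_min Required detection rate.
#'
#' @return The LOD level (same units as `level`), or `NA_real_`.
#' @export
determine_lod <- function(series, detection_min = 0.95) {
  if (is.data.frame(series) && "detected" %in% names(series)) {
    counts <- table(series$level)
    if (any(counts < 20L)) {
      herbq_warning(sprintf(
        "fewer than 20 replicates at level(s) %s: detection rates are unstable",
        paste(names(counts)[counts < 20L], collapse = ", ")),
        "herbq_support_warning")
    }
  }
  rates <- .per_level(series, "detected", function(x) mean(as.logical(x)))
  if (any(rates < 0 | rates > 1)) {
    herbq_error("detection rates must lie in [0, 1]", "herbq_input_error")
  }
  .lowest_stable(as.numeric(names(rates)), rates >= detection_min)
}

#' Limit of quantification by relative standard deviation
#'
#' The LOQ is the lowest adulteration level whose replicate RSD is at most
#' `rsd_max` percent (default 25) with every higher tested level also
#' passing. Returns `NA` (flagged) when no level qualifies.
#'
#' @param series Either a data.frame with columns `level` and `value`
#'   (replicate measured proportions; per-level RSDs are computed with
#'   [repeatability_stats()]), or a named numeric vector of per-level RSDs
#'   in percent.
#' @param rsd_max Maximum acceptable RSD, percent.
#'
#' @return The LOQ level, or `NA_real_`.
#' @export
determine_loq <- function(series, rsd_max = 25) {
  rsds <- .per_level(series, "value",
                     function(x) repeatability_stats(x)$rsd)
  .lowest_stable(as.numeric(names(rsds)), rsds <= rsd_max)
}

#' Assemble a full assay-validation report
#'
#' Per-level summaries (mean measured proportion, RSD, detection rate), LOD,
#' LOQ and a linearity fit, from one labelled dilution table such as
#' [simulate_dilution_series()] output filtered to the adulterant allele.
#'
#' "Detected" means the adulterant allele's measured frequency reaches
#' `detection_threshold` in that replicate (default 0.01 for detection
#' studies, deliberately below the 0.02 quantification threshold); a
#' pre-existing logical `detected` column takes precedence.
#'
#' @param measurements Data.frame with columns `level` and `frequency`
#'   (replicate rows), optionally `detected`.
#' @param detection_threshold Per-replicate detection rule.
#' @param detection_min LOD criterion (rate).
#' @param rsd_max LOQ criterion (percent).
#' @param r2_min Linearity gate for the level-vs-frequency fit.
#'
#' @return An object of class `validation_report`: `per_level` data.frame,
#'   `lod`, `loq`, `linearity` (a `standard_curve`, or `NULL` with fewer
#'   than 3 levels) and `parameters`.
#' @export
validate_assay <- function(measurements, detection_threshold = 0.01,
                           detection_min = 0.95, rsd_max = 25,
                           r2_min = 0.99) {
  if (!is.data.frame(measurements) ||
      !all(c("level", "frequency") %in% names(measurements))) {
    herbq_error("measurements must carry columns 'level' and 'frequency'",
                "herbq_input_error")
  }
  if (nrow(measurements) == 0L) {
    herbq_error("empty measurement table", "herbq_input_error")
  }
  detected <- if ("detected" %in% names(measurements)) {
    as.logical(measurements$detected)
  } else {
    measurements$frequency >= detection_threshold
  }
  levels_sorted <- sort(unique(measurements$level))
  per_level <- do.call(rbind, lapply(levels_sorted, function(lv) {
    idx <- measurements$level == lv
    f <- measurements$frequency[idx]
    rsd <- if (sum(idx) >= 2L && mean(f) != 0) {
      repeatability_stats(f)$rsd
    } else NA_real_
    data.frame(level = lv, n = sum(idx), mean_frequency = mean(f),
               rsd = rsd, detection_rate = mean(detected[idx]))
  }))
  # A single tested level cannot establish the stability clause.
  lod <- loq <- NA_real_
  if (length(levels_sorted) >= 2L) {
    lod <- determine_lod(setNames(per_level$detection_rate, per_level$level),
                         detection_min)
    rsd_known <- !is.na(per_level$rsd)
    if (sum(rsd_known) >= 2L) {
      loq <- determine_loq(setNames(per_level$rsd[rsd_known],
                                    per_level$level[rsd_known]), rsd_max)
    }
  }
  linearity <- NULL
  if (length(levels_sorted) >= 3L) {
    linearity <- fit_standard_curve(
      data.frame(proportion = per_level$level,
                 frequency = per_level$mean_frequency), r2_min)
  }
  structure(list(
    per_level = per_level,
    lod = lod,
    loq = loq,
    linearity = linearity,
    parameters = list(detection_threshold = detection_threshold,
                      detection_min = detection_min,
                      rsd_max = rsd_max, r2_min = r2_min)
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  pl <- x$per_level
  for (i in seq_len(nrow(pl))) {
    cat(sprintf("  level %-6g n=%-3d mean=%.4f RSD=%s%% detect=%.0f%%\n",
                pl$level[i], pl$n[i], pl$mean_frequency[i],
                ifelse(is.na(pl$rsd[i]), "NA", sprintf("%.1f", pl$rsd[i])),
                100 * pl$detection_rate[i]))
  }
  cat(sprintf("  LOD = %s (detection >= %.0f%%), LOQ = %s (RSD <= %g%%)\n",
              ifelse(is.na(x$lod), "undefined", format(x$lod)),
              100 * x$parameters$detection_min,
              ifelse(is.na(x$loq), "undefined", format(x$loq)),
              x$parameters$rsd_max))
  if (!is.null(x$linearity)) print(x$linearity)
  invisible(x)
}

#' Write a validation report as JSON and/or TSV
#'
#' @param report A [validate_assay()] result.
#' @param json_path,tsv_path Output paths (either may be `NULL`).
#' @return `report`, invisibly.
#' @export
write_validation_report <- function(report, json_path = NULL,
                                    tsv_path = NULL) {
  stopifnot(inherits(report, "validation_report"))
  if (!is.null(json_path)) {
    lin <- report$linearity
    jsonlite::write_json(list(
      per_level = report$per_level,
      lod = report$lod,
      loq = report$loq,
      linearity = if (is.null(lin)) NULL else list(
        slope = lin$slope, intercept = lin$intercept,
        r_squared = lin$r_squared,
        passes_linearity = lin$passes_linearity),
      parameters = report$parameters
    ), json_path, auto_unbox = TRUE, na = "null", pretty = TRUE, digits = NA)
  }
  if (!is.null(tsv_path)) {
    write.table(report$per_level, tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(report)
}
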