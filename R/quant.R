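#' Fit an internal-standard calibration curve
#'
#' Ordinary least squares of response ratio (analyte area / internal
#' standard area) on concentration. LOD and LOQ follow the ICH-style
#' convention 3.3 and 10 times the residual standard error divided by
#' the slope. Optional `1/x` weighting down-weights the top of the
#' range.
#'
#' @param points A data frame with a `concentration` column (ng/uL) and
#'   either a `response` column or `area` + `is_area` columns (the
#'   response ratio is then `area / is_area`).
#' @param weighting `"none"` (default) or `"1/x"`.
#' @return An object of class `calibration_fit` with elements `slope`,
#'   `intercept`, `r_squared`, `sy` (residual standard error), `lod`,
#'   `loq`, `points` and the underlying `lm` fit. [generics::tidy()] and
#'   [generics::glance()] methods are provided.
#' @export
#' @examples
#' pts <- tibble::tibble(concentration = c(30, 100, 300, 500, 700, 1000),
#'                       response = 0.002 * concentration)
#' fit_calibration(pts)
fit_calibration <- function(points, weighting = c("none", "1/x")) {
  weighting <- match.arg(weighting)
  points <- as_tibble(points)
  if (!"concentration" %in% names(points)) {
    abort("`points` must have a `concentration` column")
  }
  if (!"response" %in% names(points)) {
    if (!all(c("area", "is_area") %in% names(points))) {
      abort("`points` needs a `response` column or `area` and `is_area`")
    }
    points$response <- points$area / points$is_area
  }
  if (length(unique(points$concentration)) < 3) {
    abort("calibration needs at least 3 distinct concentrations")
  }
  w <- if (weighting == "1/x") 1 / points$concentration else NULL
  fit <- stats::lm(response ~ concentration, data = points, weights = w)
  sm <- suppressWarnings(summary(fit))  # zero-residual fits are legitimate here
  slope <- unname(stats::coef(fit)[2])
  sy <- sm$sigma
  structure(
    list(
      slope = slope,
      intercept = unname(stats::coef(fit)[1]),
      r_squared = sm$r.squared,
      sy = sy,
      lod = 3.3 * sy / slope,
      loq = 10 * sy / slope,
      weighting = weighting,
      points = points,
      fit = fit
    ),
    class = "calibration_fit"
  )
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat("<calibration_fit> response = ",
      sprintf("%.6g", x$slope), " * conc + ", sprintf("%.6g", x$intercept),
      "\n  R^2 = ", sprintf("%.6f", x$r_squared),
      ", LOD = ", sprintf("%.4g", x$lod),
      ", LOQ = ", sprintf("%.4g", x$loq), " ng/uL\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.calibration_fit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std_error = sm[, "Std. Error"],
    p_value = sm[, "Pr(>|t|)"]
  )
}

#' @export
glance.calibration_fit <- function(x, ...) {
  tibble(r_squared = x$r_squared, sigma = x$sy, lod = x$lod, loq = x$loq,
         n = nrow(x$points), weighting = x$weighting)
}

#' Invert a calibration curve
#'
#' @param fit A `calibration_fit`.
#' @param response Observed response ratio(s).
#' @return Estimated concentration(s) in ng/uL.
#' @export
quantify_concentration <- function(fit, response) {
  (response - fit$intercept) / fit$slope
}

#' Percent recovery of a spiked internal standard
#'
#' @param measured Measured amount(s).
#' @param spiked Spiked (known) amount; must be positive.
#' @return `100 * measured / spiked` (vectorized).
#' @export
#' @examples
#' percent_recovery(96.4, 100)
percent_recovery <- function(measured, spiked) {
  if (any(spiked <= 0)) abort("`spiked` amount must be positive")
  100 * measured / spiked
}

#' Summarize replicate recoveries
#'
#' @param data A data frame with a recovery-percentage column and a
#'   grouping column (e.g. extraction method).
#' @param recovery,group Column names (defaults `"recovery"`, `"method"`).
#' @return A tibble with per-group `mean`, `sd` and `n`.
#' @export
recovery_summary <- function(data, recovery = "recovery", group = "method") {
  data |>
    group_by(.data[[group]]) |>
    summarise(
      mean = mean(.data[[recovery]]),
      sd = stats::sd(.data[[recovery]]),
      n = dplyr::n(),
      .groups = "drop"
    )
}

#' Percent relative abundance across replicates
#'
#' Within each replicate, each species' integrated area is expressed as a
#' percentage of the summed area (so per-replicate percentages total
#' 100); the summary reports the mean and standard deviation across
#' replicates, ranked by mean descending, together with each replicate's
#' total abundance.
#'
#' @param areas A data frame with `species`, `replicate` and `area`
#'   columns (non-negative areas).
#' @return A list with `profile` (species, pct_mean, pct_sd, n) and
#'   `totals` (replicate, total_area).
#' @export
#' @examples
#' relative_abundance(tibble::tibble(
#'   species = rep(c("GM3", "GM1"), 2), replicate = rep(1:2, each = 2),
#'   area = c(3, 1, 3.2, 0.9)))
relative_abundance <- function(areas) {
  needed <- c("species", "replicate", "area")
  missing <- setdiff(needed, names(areas))
  if (length(missing) > 0) {
    abort(paste0("`areas` is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (any(areas$area < 0)) abort("areas must be non-negative")
  totals <- areas |>
    group_by(.data$replicate) |>
    summarise(total_area = sum(.data$area), .groups = "drop")
  dead <- totals$replicate[totals$total_area == 0]
  if (length(dead) > 0) {
    abort(paste0("replicate(s) with all-zero areas: ",
                 paste(dead, collapse = ", ")))
  }
  pct <- areas |>
    group_by(.data$replicate) |>
    mutate(pct = 100 * .data$area / sum(.data$area)) |>
    ungroup()
  profile <- pct |>
    group_by(.data$species) |>
    summarise(
      pct_mean = mean(.data$pct),
      pct_sd = if (dplyr::n() > 1) stats::sd(.data$pct) else NA_real_,
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    arrange(desc(.data$pct_mean))
  list(profile = profile, totals = totals, per_replicate = pct)
}
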