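#' Extract an ion chromatogram at ppm tolerance
#'
#' For each MS1 spectrum, sums the intensities of centroids whose m/z
#' lies within `tolerance_ppm` of the query; scans with no centroid in
#' the window contribute a zero point, so the chromatogram has exactly
#' one point per spectrum.
#'
#' @param run A [spectrum_run()].
#' @param mz Query m/z.
#' @param tolerance_ppm Extraction tolerance in ppm (default 10).
#' @return A tibble with columns `rt` (minutes) and `intensity`.
#' @export
extract_xic <- function(run, mz, tolerance_ppm = 10) {
  stopifnot(inherits(run, "spectrum_run"))
  if (length(run$rt) == 0) abort("run contains no spectra")
  if (!is.numeric(tolerance_ppm) || tolerance_ppm <= 0) {
    abort("`tolerance_ppm` must be positive")
  }
  half <- mz * tolerance_ppm * 1e-6
  lo <- mz - half
  hi <- mz + half
  intensity <- vapply(run$peaks, function(p) {
    if (nrow(p) == 0) return(0)
    sum(p[p[, 1] >= lo & p[, 1] <= hi, 2])
  }, 0)
  tibble(rt = run$rt, intensity = intensity)
}

#' Detect chromatographic peaks
#'
#' Finds local maxima above `min_height` in an extracted chromatogram and
#' walks outward from each apex (most intense first) until the signal
#' falls to `max(baseline, 1%% of apex)` or rises again at a local
#' minimum; regions already claimed by a stronger peak are not re-used,
#' so reported peaks never overlap. Peaks spanning fewer than
#' `min_points` scans are dropped.
#'
#' @param xic A tibble with `rt` and `intensity` columns.
#' @param min_height Minimum apex intensity (default 0).
#' @param min_points Minimum number of scans under a peak (default 4).
#' @param baseline Intensity floor used for peak bounds (default 0).
#' @return A tibble with `apex_rt`, `left_rt`, `right_rt`, `height`,
#'   `area` (trapezoidal), ordered by `apex_rt`.
#' @export
detect_peaks <- function(xic, min_height = 0, min_points = 4, baseline = 0) {
  y <- xic$intensity
  rt <- xic$rt
  n <- length(y)
  empty <- tibble(apex_rt = numeric(0), left_rt = numeric(0),
                  right_rt = numeric(0), height = numeric(0),
                  area = numeric(0))
  if (n < min_points) return(empty)
  is_max <- which(vapply(seq_len(n), function(i) {
    y[i] > 0 && y[i] > min_height &&
      (i == 1 || y[i] >= y[i - 1]) && (i == n || y[i] > y[i + 1])
  }, logical(1)))
  if (length(is_max) == 0) return(empty)
  claimed <- logical(n)
  # Walk outward from the apex until the signal drops to the floor or
  # starts climbing into a neighbouring peak; small noise upticks on a
  # flank do not terminate the walk. The bound is the valley point.
  walk_bound <- function(i, dir, floor_i) {
    j <- i
    min_j <- i
    repeat {
      k <- j + dir
      if (k < 1 || k > n || claimed[k]) break
      if (y[k] <= floor_i) {
        min_j <- k
        break
      }
      if (y[k] < y[min_j]) {
        min_j <- k
      } else if (y[k] > 2 * y[min_j]) {
        break
      }
      j <- k
    }
    min_j
  }
  rows <- list()
  for (i in is_max[order(y[is_max], decreasing = TRUE)]) {
    if (claimed[i]) next
    floor_i <- max(baseline, 0.01 * y[i])
    l <- walk_bound(i, -1L, floor_i)
    r <- walk_bound(i, 1L, floor_i)
    if (r - l + 1 < min_points) next
    claimed[l:r] <- TRUE
    rows[[length(rows) + 1]] <- tibble(
      apex_rt = rt[i], left_rt = rt[l], right_rt = rt[r],
      height = y[i],
      area = trapezoid_area(rt[l:r], y[l:r])
    )
  }
  if (length(rows) == 0) return(empty)
  bind_rows(rows) |> arrange(.data$apex_rt)
}

trapezoid_area <- function(x, y) {
  if (length(x) < 2) return(0)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Integrate a chromatogram between bounds
#'
#' Trapezoidal area of the trace over `[left_rt, right_rt]`.
#'
#' @param xic A tibble with `rt` and `intensity`.
#' @param left_rt,right_rt Integration bounds in minutes.
#' @return Area in intensity * min.
#' @export
integrate_peak <- function(xic, left_rt, right_rt) {
  if (left_rt >= right_rt) abort("`left_rt` must be less than `right_rt`")
  sel <- xic$rt >= left_rt & xic$rt <= right_rt
  trapezoid_area(xic$rt[sel], xic$intensity[sel])
}

#' Isotope-pattern score at a peak apex
#'
#' Cosine similarity between a target's theoretical isotope abundances
#' and the observed intensities at the corresponding m/z positions in the
#' spectrum nearest the peak apex, each extracted at the same ppm
#' tolerance. 1 means the observed envelope is proportional to theory; a
#' missing or distorted envelope scores lower; no signal at all scores 0.
#'
#' @param run A [spectrum_run()].
#' @param target One row of a target tibble (with `iso_mz_*`, `iso_ab_*`).
#' @param apex_rt Peak apex retention time (minutes).
#' @param tolerance_ppm Tolerance for locating isotope centroids.
#' @return A score in `[0, 1]`.
#' @export
isotope_score <- function(run, target, apex_rt, tolerance_ppm = 10) {
  iso_mz <- c(target$iso_mz_1, target$iso_mz_2, target$iso_mz_3)
  iso_ab <- c(target$iso_ab_1, target$iso_ab_2, target$iso_ab_3)
  keep <- !is.na(iso_mz)
  iso_mz <- iso_mz[keep]
  iso_ab <- iso_ab[keep]
  if (length(iso_mz) < 2) abort("target needs at least two isotope peaks")
  scan <- which.min(abs(run$rt - apex_rt))
  p <- run$peaks[[scan]]
  obs <- vapply(iso_mz, function(m) {
    if (nrow(p) == 0) return(0)
    half <- m * tolerance_ppm * 1e-6
    sum(p[p[, 1] >= m - half & p[, 1] <= m + half, 2])
  }, 0)
  if (sum(obs) == 0) return(0)
  sum(iso_ab * obs) / (sqrt(sum(iso_ab^2)) * sqrt(sum(obs^2)))
}

#' Quantify a target list against a run
#'
#' For each target: extract its chromatogram at `tolerance_ppm`, detect
#' peaks, restrict candidates to the target's RT window when annotated,
#' select the most intense (largest-area) candidate for quantitation,
#' and attach an isotope score at its apex. All candidate counts are
#' reported so ambiguous windows are visible.
#'
#' @param run A [spectrum_run()].
#' @param targets A target tibble (see [enumerate_targets()]).
#' @param tolerance_ppm Extraction tolerance in ppm (default 10).
#' @param min_height,min_points,baseline Passed to [detect_peaks()].
#' @return A tibble with one row per target: `species_name`, `adduct`,
#'   `theoretical_mz`, `apex_rt`, `left_rt`, `right_rt`, `height`,
#'   `area`, `isotope_score`, `score` (1 - isotope score, so smaller is
#'   better, matching keep-if-below filter semantics), `n_candidates`.
#'   Targets with no detected peak get zero area and `NA` retention time.
#' @export
quantify_targets <- function(run, targets, tolerance_ppm = 10,
                             min_height = 0, min_points = 4, baseline = 0) {
  purrr::map(seq_len(nrow(targets)), function(i) {
    tg <- targets[i, ]
    xic <- extract_xic(run, tg$theoretical_mz, tolerance_ppm)
    pk <- detect_peaks(xic, min_height = min_height,
                       min_points = min_points, baseline = baseline)
    if (!is.na(tg$rt_center) && nrow(pk) > 0) {
      pk <- pk |>
        filter(abs(.data$apex_rt - tg$rt_center) <= tg$rt_halfwidth)
    }
    base_row <- tibble(
      species_name = tg$species_name, adduct = tg$adduct,
      theoretical_mz = tg$theoretical_mz
    )
    if (nrow(pk) == 0) {
      return(bind_cols(base_row, tibble(
        apex_rt = NA_real_, left_rt = NA_real_, right_rt = NA_real_,
        height = 0, area = 0, isotope_score = NA_real_, score = NA_real_,
        n_candidates = 0L
      )))
    }
    best <- pk |> slice_max(.data$area, n = 1, with_ties = FALSE)
    iso <- isotope_score(run, tg, best$apex_rt, tolerance_ppm)
    bind_cols(base_row, tibble(
      apex_rt = best$apex_rt, left_rt = best$left_rt,
      right_rt = best$right_rt, height = best$height, area = best$area,
      isotope_score = iso, score = 1 - iso, n_candidates = nrow(pk)
    ))
  }) |> bind_rows()
}
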