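#' Default synthetic species panel
#'
#' The panel mirrors the concordant species of a typical negative-mode
#' ganglioside run: hexosylceramides and the GM/GD/GT series, with GD1a
#' and GD1b as two retention-time-separated peaks at the same m/z (GD1a
#' earlier, as on ZIC-HILIC) and GM3 eluting first among the
#' gangliosides. Retention times are minutes on a 25-min gradient; peak
#' widths (sigma = 0.05 min) and apex intensities are typical Orbitrap
#' MS1 scales.
#'
#' @return A tibble with columns `name`, `adduct`, `true_rt`, `rt_sigma`,
#'   `apex_intensity`.
#' @export
default_sim_panel <- function() {
  tibble(
    name = c("Hex1Cer(d17:0_18:2+2O)", "Hex2Cer(m17:1_12:0)",
             "GM3(d18:1_18:0)", "GM2(d18:1_16:0)", "GM1(d18:1_16:0)",
             "GD3(d18:1_16:0)", "GD2(d18:1_18:0)",
             "GD1a(d18:1_20:0)", "GD1b(d18:1_20:0)", "GT1(d18:1_18:0)"),
    adduct = c("-H", "-H", "-H", "-H", "-H", "-2H", "-2H", "-2H", "-2H",
               "-2H"),
    true_rt = c(3.0, 4.2, 6.0, 7.0, 8.0, 8.6, 9.3, 10.0, 10.6, 12.0),
    rt_sigma = 0.05,
    apex_intensity = c(2.0e6, 1.2e6, 1.6e6, 9e5, 1.1e6, 7e5, 8e5, 6e5,
                       4.5e5, 5e5)
  )
}

#' Synthetic-run configuration
#'
#' @param species A tibble like [default_sim_panel()] (columns `name`,
#'   `adduct`, `true_rt`, `rt_sigma`, `apex_intensity`).
#' @param run_length Run length in minutes (default 25).
#' @param scan_interval MS1 scan interval in minutes (default 0.005,
#'   i.e. 3.3 Hz).
#' @param baseline_mean Mean intensity of additive noise centroids
#'   scattered uniformly over the scan range (0 = none).
#' @param n_noise_peaks Number of noise centroids per scan.
#' @param mult_sd Multiplicative (relative) intensity noise sd.
#' @param mz_noise_ppm Mass-error jitter sd in ppm.
#' @param mz_window Scan range, default `c(500, 2000)`.
#' @param seed Random seed; the same config and seed give an identical
#'   run.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(species = default_sim_panel(), run_length = 25,
                       scan_interval = 0.005, baseline_mean = 0,
                       n_noise_peaks = 0, mult_sd = 0, mz_noise_ppm = 0,
                       mz_window = c(500, 2000), seed = 1L) {
  if (scan_interval <= 0) abort("`scan_interval` must be positive")
  if (run_length <= 0) abort("`run_length` must be positive")
  if (mult_sd < 0 || mz_noise_ppm < 0 || baseline_mean < 0) {
    abort("noise parameters must be non-negative")
  }
  structure(list(species = as_tibble(species), run_length = run_length,
                 scan_interval = scan_interval,
                 baseline_mean = baseline_mean,
                 n_noise_peaks = n_noise_peaks, mult_sd = mult_sd,
                 mz_noise_ppm = mz_noise_ppm, mz_window = mz_window,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a centroided negative-mode run
#'
#' Each species elutes as a Gaussian in retention time (apex
#' `apex_intensity`, width `rt_sigma`) and contributes its first three
#' isotope peaks at charge-scaled spacing to every scan, with optional
#' multiplicative intensity noise, ppm mass jitter and additive noise
#' centroids. The returned truth table records, per species, the exact
#' m/z, apex and the analytic Gaussian area
#' `apex * sigma * sqrt(2*pi)` used as the integration oracle.
#'
#' @param cfg A [sim_config()].
#' @param registry A [class_registry()] tibble.
#' @return A list with `run` (a [spectrum_run()]) and `truth` (a tibble
#'   with `name`, `adduct`, `mz`, `true_rt`, `rt_sigma`,
#'   `apex_intensity`, `true_area`).
#' @export
#' @examples
#' sim <- simulate_run(sim_config(run_length = 2, seed = 7,
#'   species = default_sim_panel()[3, ] |>
#'     transform(true_rt = 1)))
simulate_run <- function(cfg, registry = class_registry()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  rt <- seq(0, cfg$run_length, by = cfg$scan_interval)
  sp <- cfg$species
  n_sp <- nrow(sp)
  iso <- purrr::map(seq_len(n_sp), function(i) {
    parsed <- suppressWarnings(parse_species(sp$name[i], registry))
    pat <- isotope_pattern_mz(parsed$composition, sp$adduct[i],
                              threshold = 1e-3)
    pat <- pat[seq_len(min(3, nrow(pat))), ]
    # scale so the monoisotopic centroid carries apex_intensity: the truth
    # area apex * sigma * sqrt(2*pi) then holds exactly for the XIC at the
    # monoisotopic m/z (for large compositions A+1 can exceed A0)
    pat$abundance <- pat$abundance / pat$abundance[1]
    if (any(pat$mz < cfg$mz_window[1] | pat$mz > cfg$mz_window[2])) {
      abort(paste0("species ", sp$name[i], " falls outside the scan range"))
    }
    pat
  })
  truth <- sp |>
    mutate(
      mz = vapply(iso, function(p) p$mz[1], 0),
      true_area = .data$apex_intensity * .data$rt_sigma * sqrt(2 * pi)
    )
  peaks <- purrr::map(rt, function(t) {
    mzs <- numeric(0)
    ints <- numeric(0)
    for (i in seq_len(n_sp)) {
      g <- sp$apex_intensity[i] *
        exp(-(t - sp$true_rt[i])^2 / (2 * sp$rt_sigma[i]^2))
      if (g < 1) next
      pat <- iso[[i]]
      val <- g * pat$abundance
      if (cfg$mult_sd > 0) {
        val <- val * (1 + stats::rnorm(length(val), 0, cfg$mult_sd))
        val <- pmax(val, 0)
      }
      m <- pat$mz
      if (cfg$mz_noise_ppm > 0) {
        m <- m * (1 + stats::rnorm(length(m), 0, cfg$mz_noise_ppm * 1e-6))
      }
      mzs <- c(mzs, m)
      ints <- c(ints, val)
    }
    if (cfg$n_noise_peaks > 0 && cfg$baseline_mean > 0) {
      mzs <- c(mzs, stats::runif(cfg$n_noise_peaks, cfg$mz_window[1],
                                 cfg$mz_window[2]))
      ints <- c(ints, stats::rexp(cfg$n_noise_peaks,
                                  1 / cfg$baseline_mean))
    }
    keep <- ints > 0
    cbind(mz = mzs[keep], intensity = ints[keep])
  })
  run <- spectrum_run(rt, peaks, polarity = "negative",
                      metadata = list(seed = cfg$seed,
                                      scan_range = cfg$mz_window,
                                      simulated = TRUE))
  list(run = run, truth = truth)
}

#' Simulate a calibration series
#'
#' Response ratios `slope * c + intercept + N(0, sigma)` at the given
#' concentration design (default the six-level 30-1000 ng/uL series used
#' for ganglioside standards).
#'
#' @param slope True slope (> 0).
#' @param intercept True intercept.
#' @param sigma Gaussian noise sd on the response (>= 0).
#' @param concentrations Concentration design in ng/uL.
#' @param n_replicates Replicates per level.
#' @param seed Random seed.
#' @return A tibble with `concentration` and `response`.
#' @export
simulate_calibration <- function(slope, intercept = 0, sigma = 0,
                                 concentrations = c(30, 100, 300, 500,
                                                    700, 1000),
                                 n_replicates = 1, seed = 1L) {
  if (slope <= 0) abort("`slope` must be positive")
  if (sigma < 0) abort("`sigma` must be non-negative")
  if (length(concentrations) == 0) {
    abort("`concentrations` must be non-empty")
  }
  set.seed(seed)
  conc <- rep(concentrations, each = n_replicates)
  tibble(
    concentration = conc,
    response = slope * conc + intercept + stats::rnorm(length(conc), 0, sigma)
  )
}

#' Simulate a LipidSearch-style results table with known labels
#'
#' True rows satisfy all three inclusion criteria (RT > 2 min,
#' area > 1000, score < 0.5) with margin; each false row violates
#' exactly one criterion, chosen uniformly, and some violations sit
#' exactly on the threshold (rt = 2, area = 1000, score = 0.5) to pin
#' down the strict-inequality boundary semantics.
#'
#' @param n_true,n_false Numbers of true and false rows (>= 0).
#' @param seed Random seed.
#' @return A tibble with `lipid_ion`, `class`, `adduct`, `rt`, `area`,
#'   `score`, `sample`, `replicate` and the truth label `true_row`.
#' @export
simulate_results_table <- function(n_true, n_false, seed = 1L) {
  if (n_true < 0 || n_false < 0) abort("row counts must be non-negative")
  set.seed(seed)
  classes <- c("GM3", "GM2", "GM1", "GD3", "GD2", "GD1", "GT1", "Hex1Cer")
  make_rows <- function(n, true) {
    if (n == 0) {
      return(tibble(lipid_ion = character(0), class = character(0),
                    adduct = character(0), rt = numeric(0),
                    area = numeric(0), score = numeric(0),
                    sample = character(0), replicate = integer(0),
                    true_row = logical(0)))
    }
    cls <- sample(classes, n, replace = TRUE)
    rt <- stats::runif(n, 3, 14)
    area <- stats::runif(n, 5e3, 1e6)
    score <- stats::runif(n, 0.05, 0.4)
    if (!true) {
      which_bad <- sample(1:3, n, replace = TRUE)
      on_boundary <- stats::runif(n) < 0.25
      rt[which_bad == 1] <- ifelse(on_boundary[which_bad == 1], 2,
                                   stats::runif(sum(which_bad == 1), 0.2, 1.9))
      area[which_bad == 2] <- ifelse(on_boundary[which_bad == 2], 1000,
                                     stats::runif(sum(which_bad == 2), 10, 900))
      score[which_bad == 3] <- ifelse(on_boundary[which_bad == 3], 0.5,
                                      stats::runif(sum(which_bad == 3), 0.55, 0.95))
    }
    tibble(
      lipid_ion = paste0(cls, "(d18:1_", sample(c(16, 18, 20), n, TRUE),
                         ":0)"),
      class = cls,
      adduct = sample(c("-H", "-2H"), n, TRUE),
      rt = rt, area = area, score = score,
      sample = "synthetic", replicate = 1L, true_row = true
    )
  }
  out <- bind_rows(make_rows(n_true, TRUE), make_rows(n_false, FALSE))
  out[sample(nrow(out)), ]
}
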