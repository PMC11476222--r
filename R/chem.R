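# Charge-carrier masses (Da). The proton mass is electron-corrected; the
# hydrogen-atom mass is the legacy convention some vendor tables use.
PROTON_MASS <- 1.00727646
HYDROGEN_MASS <- 1.00782503207

#' Deprotonated adduct ions
#'
#' Negative-mode electrospray of gangliosides yields singly and doubly
#' deprotonated ions, written `-H` ([M-H]-) and `-2H` ([M-2H]2-).
#'
#' @param label Adduct label, `"-H"` or `"-2H"` (or `"-3H"`, ...).
#' @return A list with `n_protons_removed`, `charge` and `label`.
#' @export
#' @examples
#' adduct("-2H")
adduct <- function(label) {
  if (!is.character(label) || length(label) != 1) {
    abort("`label` must be a single string such as '-H' or '-2H'")
  }
  m <- regmatches(label, regexec("^-([0-9]*)H$", label))[[1]]
  if (length(m) == 0) {
    abort(paste0("unrecognized adduct label '", label,
                 "'; expected '-H' or '-2H'"))
  }
  n <- if (m[2] == "") 1L else as.integer(m[2])
  if (n < 1) abort("number of protons removed must be >= 1")
  list(n_protons_removed = n, charge = -n, label = label)
}

#' m/z of a deprotonated ion
#'
#' Computes `(M - n * m_carrier) / n` for the [M-nH]n- ion. The default
#' carrier is the proton (electron-corrected, 1.00727646 Da); the
#' `"hydrogen"` convention subtracts the neutral H-atom mass instead,
#' matching legacy software output. The two differ by under 0.8 ppm for
#' ions above 700 m/z.
#'
#' @param neutral_mass Neutral monoisotopic mass in Da.
#' @param adduct An [adduct()] or adduct label string.
#' @param convention `"proton"` (default) or `"hydrogen"`.
#' @return m/z of the deprotonated ion.
#' @export
#' @examples
#' adduct_mz(1000, "-H")
adduct_mz <- function(neutral_mass, adduct = "-H",
                      convention = c("proton", "hydrogen")) {
  if (is.character(adduct)) adduct <- gangliotk::adduct(adduct)
  convention <- match.arg(convention)
  carrier <- if (convention == "proton") PROTON_MASS else HYDROGEN_MASS
  n <- adduct$n_protons_removed
  if (!is.numeric(neutral_mass) || any(neutral_mass <= n * carrier)) {
    abort("`neutral_mass` must exceed the mass of the protons removed")
  }
  (neutral_mass - n * carrier) / n
}

#' Mass accuracy in parts per million
#'
#' `1e6 * |observed - theoretical| / theoretical`. The absolute value is
#' returned; the sign of the deviation is not preserved.
#'
#' @param theoretical,observed m/z values; `theoretical` must be positive.
#' @return ppm error (vectorized).
#' @export
#' @examples
#' ppm_error(1516.8375, 1516.8451) # 5.0 ppm
ppm_error <- function(theoretical, observed) {
  if (any(theoretical <= 0)) abort("`theoretical` m/z must be positive")
  1e6 * abs(observed - theoretical) / theoretical
}

# Single-element isotopologue distribution over nominal mass shifts:
# list(prob = p_k, mw = sum of prob*mass per bin), k = 0, 1, ...
element_shift_dist <- function(element) {
  tab <- isotope_table()
  iso <- tab[tab$element == element, ]
  iso <- iso[order(iso$nominal), ]
  shifts <- iso$nominal - iso$nominal[which.max(iso$abundance)]
  if (any(shifts < 0)) abort(paste0("isotope table for ", element,
                                    " has isotopes lighter than the base"))
  k <- max(shifts)
  p <- numeric(k + 1)
  mw <- numeric(k + 1)
  p[shifts + 1] <- iso$abundance
  mw[shifts + 1] <- iso$abundance * iso$mass
  list(prob = p, mw = mw)
}

# Convolve two shift distributions, tracking probability-weighted mass.
conv_dist <- function(a, b, tol = 1e-15) {
  na <- length(a$prob); nb <- length(b$prob)
  p <- numeric(na + nb - 1)
  mw <- numeric(na + nb - 1)
  for (i in seq_len(na)) {
    if (a$prob[i] < tol && a$mw[i] == 0) next
    idx <- i + seq_len(nb) - 1
    p[idx] <- p[idx] + a$prob[i] * b$prob
    mw[idx] <- mw[idx] + a$mw[i] * b$prob + a$prob[i] * b$mw
  }
  keep <- max(which(p > tol), 1)
  list(prob = p[seq_len(keep)], mw = mw[seq_len(keep)])
}

# n-fold self-convolution by binary exponentiation.
conv_pow <- function(d, n) {
  out <- list(prob = 1, mw = 0)
  while (n > 0) {
    if (n %% 2 == 1) out <- conv_dist(out, d)
    d <- conv_dist(d, d)
    n <- n %/% 2
  }
  out
}

#' Aggregated isotope pattern of a composition
#'
#' Computes the isotopologue distribution of a neutral composition by
#' per-element multinomial convolution, aggregated into nominal-mass bins
#' (A, A+1, A+2, ...) with abundance-weighted centroid masses. Fine
#' structure within a bin is not resolved. Peaks are reported with
#' relative abundance (base peak = 1) and truncated at `threshold`.
#'
#' @param composition A composition or formula string.
#' @param threshold Relative-abundance cutoff in (0, 1); default `1e-4`.
#' @return A tibble with columns `shift` (nominal mass increment), `mz`
#'   (neutral centroid mass, Da), `prob` (absolute isotopologue
#'   probability) and `abundance` (relative to the base peak), sorted by
#'   mass. The attribute `prob_sum` holds the pre-truncation probability
#'   total (1 up to numerical truncation of the convolution).
#' @export
#' @examples
#' isotope_pattern("C6H12O6")
isotope_pattern <- function(composition, threshold = 1e-4) {
  if (is.character(composition)) composition <- parse_formula(composition)
  if (length(composition) == 0) abort("composition must be non-empty")
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold >= 1) {
    abort("`threshold` must be a single value in (0, 1)")
  }
  masses <- element_masses()
  unknown <- setdiff(names(composition), names(masses))
  if (length(unknown) > 0) {
    abort(paste0("unknown element symbol(s): ", paste(unknown, collapse = ", ")))
  }
  total <- list(prob = 1, mw = 0)
  for (el in names(composition)) {
    total <- conv_dist(total, conv_pow(element_shift_dist(el), composition[[el]]))
  }
  prob <- total$prob
  centroid <- ifelse(prob > 0, total$mw / prob, NA_real_)
  out <- tibble(
    shift = seq_along(prob) - 1L,
    mz = centroid,
    prob = prob,
    abundance = prob / max(prob)
  )
  prob_sum <- sum(out$prob)
  out <- out |>
    filter(.data$abundance >= threshold) |>
    arrange(.data$mz)
  attr(out, "prob_sum") <- prob_sum
  out
}

#' Isotope pattern of a deprotonated ion
#'
#' Converts the neutral-composition pattern to ion m/z space:
#' `mz = (M_iso - n * carrier) / n`, so the isotope spacing is ~1.0034/n
#' m/z units and follows the charge state.
#'
#' @inheritParams isotope_pattern
#' @inheritParams adduct_mz
#' @return A tibble as [isotope_pattern()], with `mz` in ion m/z units.
#' @export
isotope_pattern_mz <- function(composition, adduct = "-H", threshold = 1e-4,
                               convention = c("proton", "hydrogen")) {
  if (is.character(adduct)) adduct <- gangliotk::adduct(adduct)
  convention <- match.arg(convention)
  carrier <- if (convention == "proton") PROTON_MASS else HYDROGEN_MASS
  pat <- isotope_pattern(composition, threshold = threshold)
  n <- adduct$n_protons_removed
  pat$mz <- (pat$mz - n * carrier) / n
  pat
}
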