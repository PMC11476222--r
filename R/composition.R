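#' @keywords internal
"_PACKAGE"

#' @importFrom rlang %||% .data abort warn
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Cache for packaged lookup tables (isotopes, class registry), filled lazily.
the <- new.env(parent = emptyenv())

#' Bundled isotope table
#'
#' Returns the packaged table of isotopic masses and natural abundances
#' (IUPAC/CODATA values) used for all mass arithmetic. `D` is deuterium
#' treated as an isotopically pure label element, so labelled internal
#' standards such as GM1-d3 can be expressed as ordinary compositions.
#'
#' @return A tibble with columns `element`, `nominal`, `mass`, `abundance`.
#' @export
#' @examples
#' isotope_table()
isotope_table <- function() {
  if (is.null(the$isotopes)) {
    path <- system.file("extdata", "isotopes.tsv", package = "gangliotk")
    the$isotopes <- readr::read_tsv(path, show_col_types = FALSE)
  }
  the$isotopes
}

# monoisotopic mass per element = mass of the most abundant isotope
element_masses <- function() {
  if (is.null(the$element_masses)) {
    tab <- isotope_table()
    mono <- tab |>
      group_by(.data$element) |>
      slice_max(.data$abundance, n = 1, with_ties = FALSE) |>
      ungroup()
    the$element_masses <- stats::setNames(mono$mass, mono$element)
  }
  the$element_masses
}

#' Elemental compositions
#'
#' A composition is a named integer vector mapping element symbols to
#' non-negative counts, e.g. `comp(C = 6, H = 10, O = 5)` for a condensed
#' hexose residue. Arithmetic is closed: compositions can be added,
#' subtracted (an error if any count would go negative) and scaled.
#'
#' @param ... Element counts, e.g. `C = 6, H = 12, O = 6`.
#' @return A named integer vector with zero-count elements dropped.
#' @export
#' @examples
#' comp(C = 6, H = 10, O = 5)
#' comp_add(comp(H = 2, O = 1), comp(C = 1))
comp <- function(...) {
  x <- c(...)
  if (length(x) == 0) {
    return(stats::setNames(integer(0), character(0)))
  }
  if (is.null(names(x)) || any(names(x) == "")) {
    abort("all composition entries must be named by element symbol")
  }
  if (any(x < 0)) abort("element counts must be non-negative")
  if (any(x != round(x))) abort("element counts must be integers")
  x <- x[x > 0]
  tab <- tapply(as.integer(x), names(x), sum)  # merge repeated symbols
  stats::setNames(as.integer(tab), names(tab))
}

#' @rdname comp
#' @param a,b Compositions.
#' @export
comp_add <- function(a, b) {
  syms <- union(names(a), names(b))
  out <- stats::setNames(integer(length(syms)), syms)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + b
  out <- out[out > 0]
  out[order(names(out))]
}

#' @rdname comp
#' @export
comp_subtract <- function(a, b) {
  syms <- union(names(a), names(b))
  out <- stats::setNames(integer(length(syms)), syms)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] - b
  if (any(out < 0)) {
    abort(paste0("subtraction would give negative count for ",
                 paste(syms[out < 0], collapse = ", ")))
  }
  out <- out[out > 0]
  out[order(names(out))]
}

#' @rdname comp
#' @param k Non-negative integer multiplier.
#' @export
comp_scale <- function(a, k) {
  if (length(k) != 1 || k < 0 || k != round(k)) {
    abort("`k` must be a single non-negative integer")
  }
  out <- a * as.integer(k)
  out[out > 0]
}

#' Parse a molecular formula string
#'
#' @param formula A Hill-style formula such as `"C6H10O5"`.
#' @return A composition (see [comp()]).
#' @export
#' @examples
#' parse_formula("C11H17NO8")
parse_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1 || is.na(formula)) {
    abort("`formula` must be a single string")
  }
  s <- gsub("\\s", "", formula)
  parts <- regmatches(s, gregexpr("([A-Z][a-z]?)([0-9]*)", s))[[1]]
  if (length(parts) == 0 || paste(parts, collapse = "") != s) {
    abort(paste0("cannot parse formula: '", formula, "'"))
  }
  syms <- sub("[0-9]*$", "", parts)
  cnts <- as.integer(ifelse(grepl("[0-9]+$", parts),
                            sub("^[A-Za-z]+", "", parts), "1"))
  comp(stats::setNames(cnts, syms))
}

#' Monoisotopic mass of a composition
#'
#' Sum of per-element monoisotopic masses (mass of the most abundant
#' isotope) using the bundled isotope table. The empty composition has
#' mass zero.
#'
#' @param composition A composition (named counts) or a formula string.
#' @return Mass in Da.
#' @export
#' @examples
#' monoisotopic_mass(comp(H = 2, O = 1)) # water, 18.010565
monoisotopic_mass <- function(composition) {
  if (is.character(composition)) composition <- parse_formula(composition)
  if (length(composition) == 0) return(0)
  if (any(composition < 0)) abort("element counts must be non-negative")
  masses <- element_masses()
  unknown <- setdiff(names(composition), names(masses))
  if (length(unknown) > 0) {
    abort(paste0("unknown element symbol(s): ", paste(unknown, collapse = ", ")))
  }
  sum(masses[names(composition)] * composition)
}
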