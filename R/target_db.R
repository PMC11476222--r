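TARGET_DB_COLS <- c("class", "species_name", "base", "acyl", "adduct",
                    "charge", "theoretical_mz",
                    "iso_mz_1", "iso_mz_2", "iso_mz_3",
                    "iso_ab_1", "iso_ab_2", "iso_ab_3",
                    "rt_center", "rt_halfwidth")

#' Default target enumeration settings
#'
#' Sphingoid bases, acyl ranges and per-class adducts that cover the
#' species commonly profiled in negative-mode ganglioside work: bases
#' d18:1, d18:0, d17:0, t18:0 and m17:1; acyl chains of 12-26 carbons
#' with 0-2 double bonds; and -H for neutral/monosialo classes plus -2H
#' for classes carrying two or more sialic acids.
#'
#' @return A list with `bases`, `acyl_carbons`, `acyl_db` and `mz_window`.
#' @export
default_enumeration <- function() {
  list(
    bases = c("d18:1", "d18:0", "d17:0", "t18:0", "m17:1"),
    acyl_carbons = 12:26,
    acyl_db = 0:2,
    mz_window = c(500, 2000)
  )
}

parse_base_token <- function(token) {
  m <- regmatches(token, regexec("^([mdt])([0-9]+):([0-9]+)$", token))[[1]]
  if (length(m) == 0) abort(paste0("cannot parse base token '", token, "'"))
  sphingoid_base(m[2], as.integer(m[3]), as.integer(m[4]))
}

default_adducts_for <- function(class, registry = class_registry()) {
  n_sia <- registry$neuac[match(class, registry$class)]
  if (is.na(n_sia)) abort(paste0("class '", class, "' is not in the registry"))
  if (n_sia >= 2) c("-H", "-2H") else "-H"
}

#' Enumerate theoretical targets
#'
#' Builds one target per (class, base, acyl, adduct) combination whose
#' theoretical m/z lies inside `mz_window` (default 500-2000, matching a
#' typical full-MS acquisition range). Each entry carries the first three
#' isotope peaks in ion m/z space (spacing ~1.0034/charge) so extracted
#' chromatograms can be isotope-verified. Rows are ordered by class,
#' base, acyl carbons, double bonds and charge.
#'
#' @param classes Character vector of registry classes (or isomer names).
#' @param bases Character vector of base tokens, e.g. `c("d18:1")`.
#' @param acyl_carbons,acyl_db Integer vectors of acyl chain lengths and
#'   double-bond counts to cross.
#' @param adducts Adduct labels, or `NULL` to choose per class (-H, plus
#'   -2H for classes with two or more sialic acids).
#' @param extra_oxygens `+nO` variants to enumerate (0 = none).
#' @param mz_window Numeric `(low, high)` acquisition window.
#' @param rt_center,rt_halfwidth Optional retention-time annotation (min)
#'   recycled across entries; default halfwidth 0.5 min.
#' @inheritParams adduct_mz
#' @param registry A [class_registry()] tibble.
#' @return A tibble with columns `class`, `species_name`, `base`, `acyl`,
#'   `adduct`, `charge`, `theoretical_mz`, `iso_mz_1..3`, `iso_ab_1..3`,
#'   `rt_center`, `rt_halfwidth`.
#' @export
#' @examples
#' enumerate_targets("GM3", "d18:1", acyl_carbons = 16:18, acyl_db = 0)
enumerate_targets <- function(classes,
                              bases = default_enumeration()$bases,
                              acyl_carbons = default_enumeration()$acyl_carbons,
                              acyl_db = default_enumeration()$acyl_db,
                              adducts = NULL,
                              extra_oxygens = 0L,
                              mz_window = c(500, 2000),
                              rt_center = NA_real_,
                              rt_halfwidth = 0.5,
                              convention = c("proton", "hydrogen"),
                              registry = class_registry()) {
  if (length(classes) == 0 || length(bases) == 0 || length(acyl_carbons) == 0) {
    abort("`classes`, `bases` and `acyl_carbons` must be non-empty")
  }
  convention <- match.arg(convention)
  grid <- tidyr::expand_grid(
    class = classes, base = bases,
    acyl_c = sort(unique(as.integer(acyl_carbons))),
    acyl_db = sort(unique(as.integer(acyl_db))),
    extra_o = sort(unique(as.integer(extra_oxygens)))
  )
  rows <- purrr::pmap(grid, function(class, base, acyl_c, acyl_db, extra_o) {
    adds <- adducts %||% default_adducts_for(
      isomer_map(registry)[[class]] %||% class, registry)
    mod <- if (extra_o > 0) paste0("+", extra_o, "O") else ""
    name <- paste0(class, "(", base, "_", acyl_c, ":", acyl_db, mod, ")")
    sp <- suppressWarnings(parse_species(name, registry))
    mass <- species_neutral_mass(sp, registry)
    purrr::map(adds, function(a) {
      mz <- adduct_mz(mass, a, convention = convention)
      if (mz < mz_window[1] || mz > mz_window[2]) return(NULL)
      pat <- isotope_pattern_mz(sp$composition, a, convention = convention)
      tibble(
        class = sp$class_name, species_name = name, base = base,
        acyl = paste0(acyl_c, ":", acyl_db, mod), adduct = a,
        charge = adduct(a)$charge, theoretical_mz = mz,
        iso_mz_1 = pat$mz[1], iso_mz_2 = pat$mz[2], iso_mz_3 = pat$mz[3],
        iso_ab_1 = pat$abundance[1], iso_ab_2 = pat$abundance[2],
        iso_ab_3 = pat$abundance[3]
      )
    })
  })
  out <- bind_rows(purrr::flatten(rows))
  if (nrow(out) == 0) {
    warn("no targets fall inside the m/z window")
    out <- tibble(!!!stats::setNames(
      rep(list(logical(0)), length(TARGET_DB_COLS)), TARGET_DB_COLS))
    return(out[0, ])
  }
  out$rt_center <- rep_len(rt_center, nrow(out))
  out$rt_halfwidth <- rep_len(rt_halfwidth, nrow(out))
  out |>
    arrange(.data$class, .data$base, .data$acyl, .data$charge)
}

#' Build targets from explicit species names
#'
#' Convenience constructor for a small target list (e.g. one entry per
#' standard): one row per (name, adduct) pair with optional RT windows.
#'
#' @param names Species names (may include isomer names like `GD1a(...)`).
#' @param adducts Adduct label per name (recycled).
#' @param rt_center,rt_halfwidth RT window annotation in minutes
#'   (recycled; `rt_halfwidth` defaults to 0.5).
#' @inheritParams enumerate_targets
#' @return A target tibble (same schema as [enumerate_targets()]).
#' @export
targets_from_species <- function(names, adducts = "-H",
                                 rt_center = NA_real_, rt_halfwidth = 0.5,
                                 convention = c("proton", "hydrogen"),
                                 registry = class_registry()) {
  convention <- match.arg(convention)
  n <- length(names)
  adducts <- rep_len(adducts, n)
  rt_center <- rep_len(rt_center, n)
  rt_halfwidth <- rep_len(rt_halfwidth, n)
  purrr::pmap(
    list(names, adducts, rt_center, rt_halfwidth),
    function(nm, a, rc, rh) {
      sp <- suppressWarnings(parse_species(nm, registry))
      mass <- species_neutral_mass(sp, registry)
      pat <- isotope_pattern_mz(sp$composition, a, convention = convention)
      tibble(
        class = sp$class_name, species_name = render_species(sp, FALSE),
        base = paste0(sp$base$hydroxyl_class, sp$base$carbons, ":",
                      sp$base$double_bonds),
        acyl = if (is.null(sp$acyl)) NA_character_ else
          paste0(sp$acyl$carbons, ":", sp$acyl$double_bonds),
        adduct = a, charge = adduct(a)$charge,
        theoretical_mz = adduct_mz(mass, a, convention = convention),
        iso_mz_1 = pat$mz[1], iso_mz_2 = pat$mz[2], iso_mz_3 = pat$mz[3],
        iso_ab_1 = pat$abundance[1], iso_ab_2 = pat$abundance[2],
        iso_ab_3 = pat$abundance[3],
        rt_center = rc, rt_halfwidth = rh
      )
    }
  ) |> bind_rows()
}

#' Match an observed m/z against a target list
#'
#' Returns all targets whose theoretical m/z lies within `tolerance_ppm`
#' of the observed value, sorted by ascending ppm error; ties are broken
#' by fewer sialic acids, then by species name.
#'
#' @param targets A target tibble.
#' @param observed A single observed m/z.
#' @param tolerance_ppm Match tolerance in ppm (default 10).
#' @param registry A [class_registry()] tibble.
#' @return The matching rows with a `ppm` column prepended to the sort.
#' @export
match_mz <- function(targets, observed, tolerance_ppm = 10,
                     registry = class_registry()) {
  if (!is.numeric(tolerance_ppm) || tolerance_ppm <= 0) {
    abort("`tolerance_ppm` must be positive")
  }
  out <- targets |>
    mutate(ppm = ppm_error(.data$theoretical_mz, observed)) |>
    filter(.data$ppm <= tolerance_ppm)
  if (nrow(out) == 0) return(out)
  out |>
    mutate(.n_sia = registry$neuac[match(.data$class, registry$class)]) |>
    arrange(.data$ppm, .data$.n_sia, .data$species_name) |>
    select(-".n_sia")
}

#' Read and write target databases
#'
#' CSV round-trip of a target tibble; m/z values are preserved to better
#' than 1e-6. Reading validates that all schema columns are present and
#' reports the first malformed line.
#'
#' @param targets A target tibble.
#' @param path File path.
#' @return `write_target_db()` returns `path` invisibly;
#'   `read_target_db()` returns the target tibble.
#' @export
write_target_db <- function(targets, path) {
  missing <- setdiff(TARGET_DB_COLS, names(targets))
  if (length(missing) > 0) {
    abort(paste0("target table lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  readr::write_csv(targets[, TARGET_DB_COLS], path)
  invisible(path)
}

#' @rdname write_target_db
#' @export
read_target_db <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  out <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(TARGET_DB_COLS, names(out))
  if (length(missing) > 0) {
    abort(paste0("target DB ", path, " is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    abort(paste0("malformed target DB at line ", probs$row[1], ": ",
                 probs$expected[1]))
  }
  out
}
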