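# Condensed (anhydro) residue compositions added onto the ceramide.
RESIDUE_COMPS <- list(
  hex = c(C = 6L, H = 10L, O = 5L),        # 162.052824
  hexnac = c(C = 8L, H = 13L, N = 1L, O = 5L), # 203.079373
  neuac = c(C = 11L, H = 17L, N = 1L, O = 8L), # 291.095417
  sulfate = c(S = 1L, O = 3L),             # 79.956815
  phosphate = c(H = 1L, P = 1L, O = 3L)    # 79.966331
)

#' Sphingolipid class registry
#'
#' The registry maps each supported class (Cer, Hex1Cer..Hex3Cer, the
#' GM/GD/GT/GQ ganglioside series, the asialo GA series, sulfatide ST,
#' sphingosine phosphate SPHP, CerP, CerG2GNAc1, CerG3GNAc2) to its glycan
#' headgroup composition in condensed residues (Hex, HexNAc, NeuAc) plus
#' sulfate/phosphate counts, consistent with the ganglioside biosynthesis
#' pathway: GM2 = GM3 + HexNAc, GM1 = GM2 + Hex, and each additional
#' sialylation adds one NeuAc (GM -> GD -> GT -> GQ). Linkage isomers
#' (GD1a/GD1b, GT1a/b/c, GQ1b/c) share a composition and are listed as
#' isomer groups; they differ only in retention time.
#'
#' @param path Optional path to a registry TSV with columns `class`,
#'   `hex`, `hexnac`, `neuac`, `sulfate`, `phosphate`, `requires_acyl`,
#'   `isomer_group`, `elution_note`; defaults to the bundled registry.
#' @return A tibble, one row per class.
#' @export
#' @examples
#' class_registry()
class_registry <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(the$registry)) {
      p <- system.file("extdata", "class_registry.tsv", package = "gangliotk")
      the$registry <- readr::read_tsv(p, show_col_types = FALSE)
    }
    return(the$registry)
  }
  readr::read_tsv(path, show_col_types = FALSE)
}

# isomer name (e.g. "GD1a") -> parent class ("GD1")
isomer_map <- function(registry = class_registry()) {
  out <- list()
  for (i in seq_len(nrow(registry))) {
    grp <- registry$isomer_group[i]
    if (!is.na(grp) && nzchar(grp)) {
      for (iso in strsplit(grp, ";")[[1]]) out[[iso]] <- registry$class[i]
    }
  }
  out
}

#' Sphingoid bases and fatty acyls
#'
#' A sphingoid base `"d18:1"` is a long-chain amino alcohol with formula
#' `C_c H_(2c+3-2*db) N O_h`, where the prefix m/d/t gives the hydroxyl
#' count h = 1/2/3. A fatty acyl `"18:0"` is counted as the free acid
#' `C_c H_(2c-2*db) O_2`, optionally carrying extra oxygens from a `+nO`
#' modifier; one water is lost on amide condensation with the base.
#'
#' @param hydroxyl_class `"m"`, `"d"` or `"t"`.
#' @param carbons,double_bonds Chain carbons and double bonds.
#' @return A list with the chain fields and `composition`.
#' @export
#' @examples
#' sphingoid_base("d", 18, 1)
#' fatty_acyl(18, 0)
sphingoid_base <- function(hydroxyl_class, carbons, double_bonds) {
  if (!hydroxyl_class %in% c("m", "d", "t")) {
    abort(paste0("unknown hydroxyl class '", hydroxyl_class,
                 "'; expected m, d or t"))
  }
  h <- match(hydroxyl_class, c("m", "d", "t"))
  if (carbons < 1 || double_bonds < 0) abort("invalid chain description")
  hydrogens <- 2 * carbons + 3 - 2 * double_bonds
  if (hydrogens < 1) abort("too many double bonds for chain length")
  list(
    hydroxyl_class = hydroxyl_class, carbons = as.integer(carbons),
    double_bonds = as.integer(double_bonds),
    composition = comp(C = carbons, H = hydrogens, N = 1, O = h)
  )
}

#' @rdname sphingoid_base
#' @param extra_oxygens Additional oxygens from a `+nO` modifier.
#' @export
fatty_acyl <- function(carbons, double_bonds, extra_oxygens = 0) {
  if (carbons < 1 || double_bonds < 0 || extra_oxygens < 0) {
    abort("invalid chain description")
  }
  hydrogens <- 2 * carbons - 2 * double_bonds
  if (hydrogens < 1) abort("too many double bonds for chain length")
  list(
    carbons = as.integer(carbons), double_bonds = as.integer(double_bonds),
    extra_oxygens = as.integer(extra_oxygens),
    composition = comp(C = carbons, H = hydrogens, O = 2 + extra_oxygens)
  )
}

#' Ceramide elemental composition
#'
#' Base plus free fatty acid minus one water (amide condensation).
#' Acyl chain lengths outside 12-26 carbons are allowed with a warning.
#'
#' @param base A [sphingoid_base()].
#' @param acyl A [fatty_acyl()].
#' @return A composition.
#' @export
#' @examples
#' monoisotopic_mass(ceramide_composition(sphingoid_base("d", 18, 1),
#'                                        fatty_acyl(18, 0)))
ceramide_composition <- function(base, acyl) {
  if (acyl$carbons < 12 || acyl$carbons > 26) {
    warn(paste0("acyl chain length ", acyl$carbons,
                " is outside the typical 12-26 range"))
  }
  comp_subtract(comp_add(base$composition, acyl$composition),
                comp(H = 2, O = 1))
}

species_class_pattern <- function(registry = class_registry()) {
  names <- c(registry$class, names(isomer_map(registry)))
  names <- names[order(nchar(names), decreasing = TRUE)]
  paste0("(", paste(gsub("([()])", "\\\\\\1", names), collapse = "|"), ")")
}

#' Parse a shorthand sphingolipid species name
#'
#' Accepts names of the form `CLASS(BASE_ACYL[+nO])[ADDUCT]`, e.g.
#' `"GM3(d18:1_18:0)-H"` or `"Hex1Cer(d17:0_18:2+2O)"`. Whitespace is
#' tolerated anywhere (`"GM 2 (d18:1_16:0)-H"` parses). Both `"_"` and
#' `"-"` separate base and acyl. Isomer names (`GD1a`, `GT1b`, ...) map
#' to their composition class with the isomer retained as an annotation.
#' A deuterium label such as `GM1-d3` adds a `+n*(2H - 1H)` mass shift by
#' swapping n hydrogens for deuterium in the composition. SPHP takes a
#' base only (no acyl).
#'
#' @param name Species name, optionally with a trailing `-H`/`-2H` adduct.
#' @param registry A [class_registry()] tibble.
#' @return An object of class `lipid_species`: a list with `class_name`,
#'   `isomer` (or `NA`), `label_d` (deuterium count), `base`, `acyl`
#'   (or `NULL`), `composition`, and `adduct` (an [adduct()] or `NULL`;
#'   the adduct is carried separately and is not part of the species).
#' @export
#' @examples
#' parse_species("GM3(d18:1_18:0)-H")
#' parse_species("Hex1Cer(d17:0_18:2+2O)")
parse_species <- function(name, registry = class_registry()) {
  if (!is.character(name) || length(name) != 1 || is.na(name)) {
    abort("`name` must be a single string")
  }
  s <- gsub("\\s", "", name)
  rx <- paste0(
    "^", species_class_pattern(registry),
    "(?:-[dD]([0-9]+))?",                       # isotope label, e.g. -d3
    "\\(([mdt])([0-9]+):([0-9]+)",              # sphingoid base
    "(?:[_-]([0-9]+):([0-9]+)(?:\\+([0-9]+)O)?)?", # fatty acyl [+nO]
    "\\)",
    "(-[0-9]*H)?$"                              # trailing adduct token
  )
  m <- regmatches(s, regexec(rx, s, perl = TRUE))[[1]]
  if (length(m) == 0) {
    # locate the first offending character for a useful message
    ok <- regexpr(paste0("^", species_class_pattern(registry)), s)
    pos <- if (ok > 0) attr(ok, "match.length") + 1 else 1
    abort(paste0("cannot parse species name '", name,
                 "' (near character ", pos, " of '", s, "')"))
  }
  cls_token <- m[2]
  imap <- isomer_map(registry)
  isomer <- NA_character_
  cls <- cls_token
  if (!is.null(imap[[cls_token]])) {
    isomer <- cls_token
    cls <- imap[[cls_token]]
  }
  reg <- registry[registry$class == cls, ]
  label_d <- if (nzchar(m[3])) as.integer(m[3]) else 0L
  base <- sphingoid_base(m[4], as.integer(m[5]), as.integer(m[6]))
  acyl <- NULL
  if (nzchar(m[7])) {
    extra_o <- if (nzchar(m[9])) as.integer(m[9]) else 0L
    acyl <- fatty_acyl(as.integer(m[7]), as.integer(m[8]), extra_o)
  }
  if (reg$requires_acyl && is.null(acyl)) {
    abort(paste0("class ", cls, " requires a fatty acyl chain"))
  }
  if (!reg$requires_acyl && !is.null(acyl)) {
    abort(paste0("class ", cls, " does not take a fatty acyl chain"))
  }
  adduct_obj <- if (nzchar(m[10])) adduct(m[10]) else NULL
  sp <- structure(
    list(class_name = cls, isomer = isomer, label_d = label_d,
         base = base, acyl = acyl, adduct = adduct_obj),
    class = "lipid_species"
  )
  sp$composition <- species_composition(sp, registry)
  sp
}

#' Elemental composition of a parsed species
#'
#' Ceramide (or bare sphingoid base for SPHP) plus the class's condensed
#' glycan residues, with `label_d` hydrogens swapped for deuterium.
#'
#' @param sp A `lipid_species`.
#' @param registry A [class_registry()] tibble.
#' @return A composition.
#' @export
species_composition <- function(sp, registry = class_registry()) {
  reg <- registry[registry$class == sp$class_name, ]
  if (nrow(reg) == 0) {
    abort(paste0("class '", sp$class_name, "' is not in the registry"))
  }
  core <- if (is.null(sp$acyl)) {
    sp$base$composition
  } else {
    suppressWarnings(ceramide_composition(sp$base, sp$acyl))
  }
  out <- core
  for (res in names(RESIDUE_COMPS)) {
    n <- reg[[res]]
    if (n > 0) out <- comp_add(out, comp_scale(RESIDUE_COMPS[[res]], n))
  }
  if (sp$label_d > 0) {
    out <- comp_add(comp_subtract(out, comp(H = sp$label_d)),
                    comp(D = sp$label_d))
  }
  out
}

#' Neutral monoisotopic mass of a species
#'
#' @param sp A `lipid_species` or species name string.
#' @param registry A [class_registry()] tibble.
#' @return Mass in Da.
#' @export
#' @examples
#' species_neutral_mass("GM1(d18:1_16:0)")
species_neutral_mass <- function(sp, registry = class_registry()) {
  if (is.character(sp)) sp <- parse_species(sp, registry)
  monoisotopic_mass(sp$composition)
}

#' Canonical rendering of a species
#'
#' Inverse of [parse_species()]: rendering a parsed name reproduces its
#' canonical (whitespace-free, underscore-separated) form.
#'
#' @param sp A `lipid_species`.
#' @param with_adduct Append the adduct token when present.
#' @return A string.
#' @export
render_species <- function(sp, with_adduct = TRUE) {
  cls <- if (!is.na(sp$isomer)) sp$isomer else sp$class_name
  lab <- if (sp$label_d > 0) paste0("-d", sp$label_d) else ""
  chain <- paste0(sp$base$hydroxyl_class, sp$base$carbons, ":",
                  sp$base$double_bonds)
  if (!is.null(sp$acyl)) {
    chain <- paste0(chain, "_", sp$acyl$carbons, ":", sp$acyl$double_bonds)
    if (sp$acyl$extra_oxygens > 0) {
      chain <- paste0(chain, "+", sp$acyl$extra_oxygens, "O")
    }
  }
  out <- paste0(cls, lab, "(", chain, ")")
  if (with_adduct && !is.null(sp$adduct)) out <- paste0(out, sp$adduct$label)
  out
}

#' @export
print.lipid_species <- function(x, ...) {
  cat("<lipid_species> ", render_species(x), "\n", sep = "")
  cat("  neutral mass: ", sprintf("%.6f", species_neutral_mass(x)), " Da\n",
      sep = "")
  invisible(x)
}

#' Theoretical m/z of a named species and adduct
#'
#' Convenience wrapper: parse, assemble the composition, and compute the
#' deprotonated-ion m/z. If the name carries a trailing adduct token it is
#' used unless `adduct` is given explicitly.
#'
#' @param name Species name, e.g. `"GD2(d18:1_18:0)-2H"`.
#' @param adduct Optional adduct label overriding the name's token.
#' @inheritParams adduct_mz
#' @param registry A [class_registry()] tibble.
#' @return Theoretical m/z.
#' @export
#' @examples
#' species_mz("GD2(d18:1_18:0)", "-2H")
species_mz <- function(name, adduct = NULL,
                       convention = c("proton", "hydrogen"),
                       registry = class_registry()) {
  sp <- parse_species(name, registry)
  add <- adduct %||% sp$adduct %||% "-H"
  adduct_mz(species_neutral_mass(sp, registry), add,
            convention = match.arg(convention))
}
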