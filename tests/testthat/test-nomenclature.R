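test_that("shorthand species names parse into class, chains and adduct", {
  sp <- parse_species("GM3(d18:1_18:0)-H")
  expect_identical(sp$class_name, "GM3")
  expect_identical(sp$base$hydroxyl_class, "d")
  expect_identical(sp$base$carbons, 18L)
  expect_identical(sp$base$double_bonds, 1L)
  expect_identical(sp$acyl$carbons, 18L)
  expect_identical(sp$adduct$label, "-H")
  expect_identical(sp$adduct$charge, -1L)

  # +nO acyl modifier and whitespace tolerance
  sp2 <- parse_species("Hex1Cer(d17:0_18:2+2O)-H")
  expect_identical(sp2$acyl$extra_oxygens, 2L)
  expect_identical(render_species(parse_species("GM 2 (d18:1_16:0)-H")),
                   "GM2(d18:1_16:0)-H")

  # "-" as base/acyl separator
  expect_equal(species_neutral_mass(parse_species("GD1(d18:1-20:0)")),
               species_neutral_mass(parse_species("GD1(d18:1_20:0)")))

  expect_error(parse_species("GM3(x18:1_18:0)"), "cannot parse")
  expect_error(parse_species("NotAClass(d18:1_18:0)"), "cannot parse")
  expect_error(parse_species("GM3(d18:1_)"), "cannot parse")
})

test_that("acyl arity follows the class (SPHP is acyl-free)", {
  expect_silent(parse_species("SPHP(d18:1)"))
  expect_error(parse_species("SPHP(d18:1_12:0)"), "does not take")
  expect_error(parse_species("Cer(d18:1)"), "requires")
})

test_that("ceramide assembly is base + free acid - water", {
  d18_1 <- sphingoid_base("d", 18, 1)
  acid18 <- fatty_acyl(18, 0)
  cer <- ceramide_composition(d18_1, acid18)
  expect_identical(cer, comp(C = 36, H = 71, N = 1, O = 3))
  want <- mass_of(C = 18, H = 37, N = 1, O = 2) +
    mass_of(C = 18, H = 36, O = 2) - mass_of(H = 2, O = 1)
  expect_equal(monoisotopic_mass(cer), want, tolerance = 1e-12)
  expect_equal(monoisotopic_mass(cer), 565.543404, tolerance = 1e-7)

  # chain-shortening by C2H4
  cer16 <- ceramide_composition(d18_1, fatty_acyl(16, 0))
  expect_equal(monoisotopic_mass(cer16),
               monoisotopic_mass(cer) - mass_of(C = 2, H = 4),
               tolerance = 1e-12)

  cer_m <- ceramide_composition(sphingoid_base("m", 17, 1),
                                fatty_acyl(12, 0))
  expect_equal(monoisotopic_mass(cer_m), 451.438929, tolerance = 1e-7)

  expect_warning(ceramide_composition(d18_1, fatty_acyl(30, 0)),
                 "outside")
})

test_that("species masses assemble ceramide plus glycan residues", {
  expect_equal(species_neutral_mass("GM1(d18:1_16:0)"), 1517.845366,
               tolerance = 1e-7)
  expect_equal(adduct_mz(species_neutral_mass("GM1(d18:1_16:0)"), "-H"),
               1516.8375, tolerance = 1e-6)  # within 1 ppm of the printed ion
  expect_equal(species_mz("Hex2Cer(m17:1_12:0)", "-H"), 774.5373,
               tolerance = 1e-6)
  # no glycan: Cer mass is the bare ceramide
  expect_equal(species_neutral_mass("Cer(d18:1_18:0)"),
               monoisotopic_mass(ceramide_composition(
                 sphingoid_base("d", 18, 1), fatty_acyl(18, 0))),
               tolerance = 1e-12)
  expect_error(species_composition(
    structure(list(class_name = "NOPE", base = sphingoid_base("d", 18, 1),
                   acyl = fatty_acyl(18, 0), label_d = 0L),
              class = "lipid_species")), "registry")
})

test_that("biosynthesis-pathway residue increments hold for any ceramide", {
  hexnac <- mass_of(C = 8, H = 13, N = 1, O = 5)
  hex <- mass_of(C = 6, H = 10, O = 5)
  neuac <- mass_of(C = 11, H = 17, N = 1, O = 8)
  set.seed(7)
  for (i in 1:10) {
    chain <- sprintf("(d%d:%d_%d:%d)", sample(14:20, 1), sample(0:1, 1),
                     sample(12:26, 1), sample(0:2, 1))
    m <- function(cls) suppressWarnings(
      species_neutral_mass(paste0(cls, chain)))
    expect_equal(m("GM2") - m("GM3"), hexnac, tolerance = 1e-9)
    expect_equal(m("GM1") - m("GM2"), hex, tolerance = 1e-9)
    expect_equal(m("GD1") - m("GM1"), neuac, tolerance = 1e-9)
    expect_equal(m("GT1") - m("GD1"), neuac, tolerance = 1e-9)
    expect_equal(m("GQ1") - m("GT1"), neuac, tolerance = 1e-9)
    # asialo series: GA2/GA1 are GM2/GM1 minus the sialic acid
    expect_equal(m("GM2") - m("GA2"), neuac, tolerance = 1e-9)
    expect_equal(m("GM1") - m("GA1"), neuac, tolerance = 1e-9)
  }
})

test_that("linkage isomers share a composition and differ only by name", {
  for (nm in c("GD1a", "GD1b")) {
    sp <- parse_species(paste0(nm, "(d18:1_20:0)"))
    expect_identical(sp$class_name, "GD1")
    expect_identical(sp$isomer, nm)
    expect_equal(species_neutral_mass(sp),
                 species_neutral_mass("GD1(d18:1_20:0)"))
  }
  masses <- vapply(c("GT1a", "GT1b", "GT1c"), function(nm)
    species_neutral_mass(paste0(nm, "(d18:1_18:0)")), 0)
  expect_true(all(abs(diff(masses)) < 1e-12))
  expect_identical(render_species(parse_species("GD1a(d18:1_20:0)")),
                   "GD1a(d18:1_20:0)")
})

test_that("rendering a parsed name is the identity on canonical forms", {
  for (nm in table2_species) {
    canonical <- gsub("\\s", "", nm)
    expect_identical(
      render_species(suppressWarnings(parse_species(nm))), canonical)
  }
})

test_that("deuterium labels shift the mass by n * (2H - 1H)", {
  shift <- species_neutral_mass("GM1-d3(d18:1_18:0)") -
    species_neutral_mass("GM1(d18:1_18:0)")
  expect_equal(shift, 3 * (2.01410177785 - 1.00782503207),
               tolerance = 1e-9)
  expect_identical(parse_species("GM1-d3(d18:1_18:0)")$label_d, 3L)
  expect_identical(render_species(parse_species("GM1-d3(d18:1_18:0)")),
                   "GM1-d3(d18:1_18:0)")
})
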