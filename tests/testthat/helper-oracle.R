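# Independent oracles used across tests.

# Brute-force isotopologue enumeration: every atom independently takes one
# of its element's isotopes; probabilities multiply and masses add. Only
# feasible for tiny formulas, which is the point — it shares no code with
# the convolution in the package.
brute_force_pattern <- function(composition) {
  tab <- as.data.frame(isotope_table())
  atoms <- rep(names(composition), composition)
  stopifnot(length(atoms) <= 12)
  iso <- lapply(atoms, function(el) {
    d <- tab[tab$element == el, ]
    d$shift <- d$nominal - d$nominal[which.max(d$abundance)]
    d
  })
  idx <- expand.grid(lapply(iso, function(d) seq_len(nrow(d))))
  prob <- rep(1, nrow(idx))
  mass <- rep(0, nrow(idx))
  shift <- rep(0L, nrow(idx))
  for (j in seq_along(iso)) {
    d <- iso[[j]]
    prob <- prob * d$abundance[idx[[j]]]
    mass <- mass + d$mass[idx[[j]]]
    shift <- shift + d$shift[idx[[j]]]
  }
  p <- tapply(prob, shift, sum)
  mw <- tapply(prob * mass, shift, sum)
  data.frame(shift = as.integer(names(p)), prob = as.numeric(p),
             mz = as.numeric(mw) / as.numeric(p))
}

# Atomic-mass sums straight from the bundled table, independent of the
# composition machinery (used to freeze derived chain masses).
mass_of <- function(...) {
  counts <- c(...)
  tab <- as.data.frame(isotope_table())
  sum(vapply(names(counts), function(el) {
    d <- tab[tab$element == el, ]
    d$mass[which.max(d$abundance)] * counts[[el]]
  }, 0))
}

# Deterministic tiny run: one centroid per listed (rt, mz, intensity) row.
run_from_points <- function(points, all_rt = sort(unique(points$rt))) {
  peaks <- lapply(all_rt, function(t) {
    p <- points[points$rt == t, c("mz", "intensity"), drop = FALSE]
    as.matrix(p)
  })
  spectrum_run(all_rt, peaks)
}

table2_species <- c(
  "Hex1Cer(d17:0_18:2+2O)-H", "Hex2Cer(m17:1_12:0)-H",
  "GM3(d18:1_18:0)-H", "GD3(d18:1_16:0)-H", "GT3(t16:1_12:0)-H",
  "GD2(d18:1_18:0)-2H", "GT2(d18:1_21:5)-2H", "GM1(d18:1_16:0)-H",
  "GT1(d18:1_18:0)-2H", "GD1(d18:1_18:0)-2H", "GQ1(d18:1_18:0)-2H",
  "GM2(d18:1_16:0)-H"
)

golden_mz <- c(
  "Hex1Cer(d17:0_18:2+2O)" = 742.5475,
  "Hex2Cer(m17:1_12:0)"    = 774.5373,
  "GM3(d18:1_18:0)"        = 1179.7365,
  "GD3(d18:1_16:0)"        = 720.8967,
  "GD2(d18:1_18:0)"        = 836.4520,
  "GM2(d18:1_16:0)"        = 1354.7847,
  "GM1(d18:1_16:0)"        = 1516.8375,
  "GT1(d18:1_18:0)"        = 1063.0261,
  "GD1(d18:1_20:0)"        = 931.4940
)
golden_adduct <- c("-H", "-H", "-H", "-2H", "-2H", "-H", "-H", "-2H", "-2H")
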