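# Shared fixtures: the flagship tetraether cardiolipin worked example, the
# measured PE/PG core compositions, and a cached default enumeration.

# Tetraether CDL 64:0 with C33 (e17/e16) and C31 (e17/e14) dialkyl cores.
tetraether_cdl64 <- function() {
  build_species("CDL", list(
    core_lipid(list(radyl_chain(17, "ether"), radyl_chain(16, "ether"))),
    core_lipid(list(radyl_chain(17, "ether"), radyl_chain(14, "ether")))))
}

# Printed MS2 peak list of the tetraether CDL 64:0 (observed masses).
tetraether_cdl64_peaks <- function() {
  data.frame(
    mz = c(1298.063, 1280.050, 771.529, 743.497, 691.563, 663.531,
           297.315, 283.299, 255.268, 234.977, 155.010),
    intensity = c(40, 100, 90, 85, 60, 55, 70, 75, 80, 65, 50))
}

# Measured intact-core composition (% of total PGs / PEs respectively).
measured_core_composition <- function() {
  data.frame(
    head_group = c("PG", "PG", "PG", "PG", "PE", "PE", "PE", "PE", "PE"),
    core_class = c("DEG", "AEG", "DAG", "MEG",
                   "DAG", "AEG", "DEG", "MEG", "MAG"),
    percent = c(66.2, 17.0, 9.3, 7.4, 54.0, 7.5, 25.0, 13.5, 0.2),
    stringsAsFactors = FALSE)
}

# Measured CDL ether-class distribution (e0..e4, fractions).
measured_cdl_ether_dist <- function() {
  c(`0` = 0.09, `1` = 0.12, `2` = 0.28, `3` = 0.18, `4` = 0.33)
}

# Default enumeration and index are expensive; build once per test run.
.fixture_env <- new.env(parent = emptyenv())

default_species <- function() {
  if (is.null(.fixture_env$species)) {
    .fixture_env$species <- enumerate_species()
  }
  .fixture_env$species
}

default_index <- function() {
  if (is.null(.fixture_env$index)) {
    .fixture_env$index <- build_species_index(default_species())
  }
  .fixture_env$index
}
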