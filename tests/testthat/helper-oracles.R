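# Independent oracles used across the suite. Each is written from the
# definition of the quantity, not the package's algorithm.

# N50 by direct definition: the largest length L such that contigs of
# length >= L together cover at least half the assembly.
oracle_n50 <- function(lens) {
  total <- sum(lens)
  cand <- sort(unique(lens), decreasing = TRUE)
  for (L in cand) if (sum(lens[lens >= L]) >= total / 2) return(L)
  stop("unreachable")
}

# Division capacity by cell-by-cell simulation: each doubling cycle every
# existing cell divides, and every new cell is charged atp_per_division.
oracle_division <- function(budget, cost) {
  pop <- 1
  spent <- 0
  cycles <- 0L
  repeat {
    cycle_cost <- pop * cost  # one new cell per existing cell
    if (spent + cycle_cost > budget) break
    spent <- spent + cycle_cost
    pop <- pop * 2
    cycles <- cycles + 1L
  }
  list(cycles = cycles, population = pop, spent = spent)
}

# Reference CO2(aq) from (pH, HCO3-) using independent published constant
# fits: Harned & Davis (1943) fresh water at S = 0; Lueker et al. (2000,
# total hydrogen-ion scale, valid S 19-43) for saline waters. The pH is
# interpreted on each fit's own working scale.
oracle_co2_molar <- function(ph, hco3_molar, temperature_c, salinity_psu) {
  tk <- temperature_c + 273.15
  pk1 <- if (salinity_psu == 0) {
    -14.8435 + 3404.71 / tk + 0.032786 * tk
  } else if (salinity_psu >= 19) {
    3633.86 / tk - 61.2172 + 9.67770 * log(tk) -
      0.011555 * salinity_psu + 0.0001152 * salinity_psu^2
  } else {
    stop("oracle has no independent fit for 0 < S < 19")
  }
  hco3_molar * 10^(-ph) / 10^(-pk1)
}

# Percent identity by per-column hand counting, used to cross-check the
# vectorized implementation.
oracle_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  num <- 0L
  den <- 0L
  for (i in seq_along(ca)) {
    if (ca[i] != "-" && cb[i] != "-") {
      den <- den + 1L
      if (ca[i] == cb[i] && ca[i] != "N") num <- num + 1L
    }
  }
  100 * num / den
}

basin_water <- function(date = "jun") {
  if (date == "jun")
    water_sample("basin-jun2012", 29.6, 7.03, 2e-3,
                 conductivity_ms_cm = 28.9, calcium_molar = 11.1e-3)
  else
    water_sample("basin-oct2013", 31.7, 7.32, 2e-3,
                 conductivity_ms_cm = 32.6, calcium_molar = 11.1e-3)
}
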