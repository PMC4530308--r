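test_that("equilibrium constants reproduce published anchor values", {
  fresh <- compute_constants(25, 0)
  expect_equal(-log10(fresh$k1), 6.35, tolerance = 0.02 / 6.35)
  expect_equal(-log10(fresh$k2), 10.33, tolerance = 0.02 / 10.33)

  sea <- compute_constants(25, 35)
  expect_gt(-log10(sea$k1), 5.83)
  expect_lt(-log10(sea$k1), 5.90)
  expect_equal(sea$ksp_calcite, 4.27e-7, tolerance = 0.02)

  # ionic-strength monotonicity: K1 strictly larger in saline water
  expect_gt(sea$k1, fresh$k1)
  expect_true(fresh$k1 > fresh$k2)
  expect_identical(sea$formulation_id, "millero2006")
})

test_that("constants are deterministic and validity bounds are enforced", {
  expect_identical(compute_constants(29.6, 17.5), compute_constants(29.6, 17.5))
  expect_error(compute_constants(-5, 10), "\\[0, 50\\]")
  expect_error(compute_constants(25, 60), "\\[0, 50\\]")
})

test_that("speciation satisfies its definitional identities", {
  cs <- compute_constants(25, 0)
  # at pH = pK1 (on the constants' own scale) CO2(aq) equals bicarbonate
  ws <- water_sample("eq", 25, -log10(cs$k1), 2e-3, salinity_psu = 0)
  sp <- speciate(ws, cs, ph_scale = "sws")
  expect_equal(sp$co2_aq_molar, sp$hco3_molar)

  # closed form: fresh water, pH one unit above pK1 -> CO2 = HCO3/10
  ws2 <- water_sample("fresh", 25, 7.35, 2e-3, salinity_psu = 0)
  sp2 <- speciate(ws2, cs, ph_scale = "sws")
  expect_equal(sp2$co2_aq_molar, 2e-4, tolerance = 0.01)
})

test_that("DIC conservation holds to 1e-12 relative across valid inputs", {
  set.seed(42)
  for (i in 1:50) {
    ws <- water_sample("p", runif(1, 0, 50), runif(1, 6, 9),
                       runif(1, 1e-4, 5e-3), salinity_psu = runif(1, 0, 50))
    sp <- speciate(ws)
    expect_equal(sp$dic_molar,
                 sp$co2_aq_molar + sp$hco3_molar + sp$co3_molar,
                 tolerance = 1e-12)
    expect_true(all(c(sp$co2_aq_molar, sp$hco3_molar, sp$co3_molar) >= 0))
  }
})

test_that("CO2(aq) is strictly decreasing in pH at fixed HCO3-, T, S", {
  cs <- compute_constants(29.6, 17.5)
  phs <- seq(6.5, 8.5, by = 0.25)
  co2 <- vapply(phs, function(ph)
    speciate(water_sample("x", 29.6, ph, 2e-3, salinity_psu = 17.5), cs)$co2_aq_molar,
    0)
  expect_true(all(diff(co2) < 0))
})

test_that("basin speciation lands near the reported ~200 uM CO2(aq)", {
  sp <- speciate(basin_water("jun"))
  co2_um <- sp$co2_aq_molar * 1e6
  expect_gt(co2_um, 140)  # within the 'about' qualifier, +/-30%
  expect_lt(co2_um, 260)
})

test_that("speciation agrees with independent constant fits within 5%", {
  for (tc in c(20, 25, 30, 35)) {
    for (s in c(0, 19, 25, 35)) {
      cs <- compute_constants(tc, s)
      for (ph in c(6.5, 7.0, 7.5, 8.0, 8.5)) {
        ws <- water_sample("g", tc, ph, 2e-3, salinity_psu = s)
        got <- speciate(ws, cs, ph_scale = "sws")$co2_aq_molar
        ref <- oracle_co2_molar(ph, 2e-3, tc, s)
        expect_lt(abs(got - ref) / ref, 0.05)
      }
    }
  }
})

test_that("calcite saturation state behaves as defined", {
  expect_equal(omega_calcite(2e-3, 5e-5, 1e-7), 1)
  expect_equal(omega_calcite(4e-3, 5e-5, 1e-7),
               2 * omega_calcite(2e-3, 5e-5, 1e-7))
  expect_error(omega_calcite(0, 1e-5, 1e-7), "> 0")

  # the basin is undersaturated on the June column but supersaturated in
  # October, when calcium was measured (higher pH shifts carbonate up)
  expect_lt(speciate(basin_water("jun"))$omega_calcite, 1)
  expect_gt(speciate(basin_water("oct"))$omega_calcite, 1)
})

test_that("calcite proton yield is exactly 1:1 and linear", {
  expect_equal(calcite_proton_yield(0), 0)
  expect_equal(calcite_proton_yield(1), 1)
  expect_equal(calcite_proton_yield(5e-11), 5e-11)  # 0.05 nmol per cell
  a <- runif(1); b <- runif(1)
  expect_equal(calcite_proton_yield(a + b),
               calcite_proton_yield(a) + calcite_proton_yield(b))
  expect_error(calcite_proton_yield(-1), ">= 0")
})

test_that("conductivity-to-salinity conversion hits its anchors", {
  expect_equal(conductivity_to_salinity(53, 25), 35)
  expect_equal(conductivity_to_salinity(0, 25), 0)
  # basin conductivities at basin temperatures: roughly half seawater
  s <- conductivity_to_salinity(c(28.9, 32.6), c(29.6, 31.7))
  expect_true(all(s >= 16 & s <= 19))
  expect_true(all(diff(conductivity_to_salinity(seq(1, 60, 1), 25)) > 0))
})

test_that("water samples round-trip through CSV and drive speciation", {
  path <- system.file("extdata", "water_geochemistry.csv",
                      package = "achrotools")
  samples <- read_water_samples(path)
  expect_named(samples)
  basin <- samples[["basin-jun2012"]]
  expect_equal(basin$ph, 7.03)
  expect_equal(basin$bicarbonate_molar, 2e-3)
  expect_equal(basin$salinity_psu, conductivity_to_salinity(28.9, 29.6))
  sp <- speciate(basin)
  expect_gt(sp$co2_aq_molar * 1e6, 140)

  out <- tempfile(fileext = ".json")
  write_speciation(sp, out)
  back <- jsonlite::read_json(out)
  expect_equal(back$co2_aq_molar, sp$co2_aq_molar)
})

test_that("invalid water samples are rejected with the offending field", {
  expect_error(water_sample("x", 70, 7, 1e-3, salinity_psu = 10),
               "temperature_c")
  expect_error(water_sample("x", 25, 1, 1e-3, salinity_psu = 10), "ph")
  expect_error(water_sample("x", 25, 7, -1, salinity_psu = 10),
               "bicarbonate")
  expect_error(water_sample("x", 25, 7, 1e-3), "salinity|conductivity")
  ws <- water_sample("x", 25, 7, 1e-3, salinity_psu = 10)
  ws$bicarbonate_molar <- 0
  expect_error(speciate(ws), "bicarbonate")
})
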