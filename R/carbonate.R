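# Carbonate-system chemistry: equilibrium constants, speciation from
# (pH, bicarbonate), calcite saturation state, and the proton yield of
# calcite precipitation.

#' Construct a water-chemistry observation
#'
#' Bundles one observation of spring- or sea-water chemistry: temperature,
#' salinity (measured directly or derived from conductivity), pH on the NBS
#' (field-meter) scale, bicarbonate, and optionally calcium and dissolved
#' sulfide. This is the input unit for [speciate()].
#'
#' @param label Sample label.
#' @param temperature_c Water temperature, degrees Celsius (0--50).
#' @param ph pH on the NBS scale as reported by field meters (2--12).
#' @param bicarbonate_molar Bicarbonate concentration, mol/L.
#' @param salinity_psu Practical salinity (0--50). If `NULL`,
#'   `conductivity_ms_cm` must be given and salinity is derived with
#'   [conductivity_to_salinity()].
#' @param conductivity_ms_cm Specific conductivity, mS/cm (optional).
#' @param calcium_molar Dissolved calcium, mol/L (optional; required only for
#'   the calcite saturation state).
#' @param sulfide_um Total dissolved sulfide, micromolar (optional).
#'
#' @return An object of class `water_sample` (a named list).
#' @examples
#' basin <- water_sample("basin", temperature_c = 29.6, ph = 7.03,
#'                       bicarbonate_molar = 2e-3, conductivity_ms_cm = 28.9,
#'                       calcium_molar = 11.1e-3)
#' basin$salinity_psu
#' @export
water_sample <- function(label, temperature_c, ph, bicarbonate_molar,
                         salinity_psu = NULL, conductivity_ms_cm = NULL,
                         calcium_molar = NA_real_, sulfide_um = NA_real_) {
  stopifnot(is.character(label), length(label) == 1)
  if (!is.finite(temperature_c) || temperature_c < 0 || temperature_c > 50)
    stop("temperature_c must be in [0, 50] degC, got ", temperature_c)
  if (!is.finite(ph) || ph < 2 || ph > 12)
    stop("ph must be in [2, 12], got ", ph)
  if (!is.finite(bicarbonate_molar) || bicarbonate_molar < 0)
    stop("bicarbonate_molar must be >= 0")
  if (is.null(salinity_psu)) {
    if (is.null(conductivity_ms_cm) || !is.finite(conductivity_ms_cm))
      stop("supply either salinity_psu or conductivity_ms_cm")
    salinity_psu <- conductivity_to_salinity(conductivity_ms_cm, temperature_c)
  }
  if (!is.finite(salinity_psu) || salinity_psu < 0 || salinity_psu > 50)
    stop("salinity_psu must be in [0, 50], got ", salinity_psu)
  if (!is.na(calcium_molar) && calcium_molar < 0) stop("calcium_molar must be >= 0")
  if (!is.na(sulfide_um) && sulfide_um < 0) stop("sulfide_um must be >= 0")
  structure(list(label = label, temperature_c = temperature_c,
                 salinity_psu = salinity_psu, ph = ph,
                 bicarbonate_molar = bicarbonate_molar,
                 calcium_molar = calcium_molar,
                 conductivity_ms_cm = if (is.null(conductivity_ms_cm)) NA_real_ else conductivity_ms_cm,
                 sulfide_um = sulfide_um),
            class = "water_sample")
}

#' @export
print.water_sample <- function(x, ...) {
  cat(sprintf("<water_sample> %s: T = %.1f degC, S = %.1f, pH = %.2f, HCO3- = %.3g mol/L\n",
              x$label, x$temperature_c, x$salinity_psu, x$ph, x$bicarbonate_molar))
  invisible(x)
}

#' Carbonate-system equilibrium constants
#'
#' Computes the first and second stoichiometric dissociation constants of
#' carbonic acid and the stoichiometric solubility product of calcite at the
#' requested temperature and salinity.
#'
#' The default formulation (`"millero2006"`) uses the brackish-to-marine
#' carbonic-acid fits of Millero and co-workers (valid S 0--50, T 0--50
#' degC, seawater pH scale, mol/kg-solution) together with the classic Mucci
#' calcite solubility fit. Below S = 5 the calcite Ksp is an extrapolation of
#' the Mucci fit; the saturation state is reported there with that caveat.
#' Constants are treated as interchangeable with mol/L within the ~1--3%
#' seawater-density difference, far below the precision of field bicarbonate
#' data.
#'
#' @param temperature_c Temperature, degrees Celsius (0--50).
#' @param salinity_psu Practical salinity (0--50).
#' @param formulation_id Constant formulation; only `"millero2006"` is
#'   currently implemented.
#'
#' @return An object of class `constant_set`: list with `k1`, `k2`,
#'   `ksp_calcite`, `temperature_c`, `salinity_psu`, `formulation_id`.
#' @references
#' Millero, F. J. et al. (2006) Dissociation constants of carbonic acid in
#' seawater as a function of salinity and temperature. Marine Chemistry 100,
#' 80--94. Mucci, A. (1983) The solubility of calcite and aragonite in
#' seawater at various salinities. American Journal of Science 283, 780--799.
#' @examples
#' cs <- compute_constants(25, 0)
#' -log10(cs$k1)  # ~6.35 in fresh water
#' @export
compute_constants <- function(temperature_c, salinity_psu,
                              formulation_id = "millero2006") {
  if (!is.finite(temperature_c) || temperature_c < 0 || temperature_c > 50)
    stop("temperature_c out of formulation validity range [0, 50] degC: ",
         temperature_c)
  if (!is.finite(salinity_psu) || salinity_psu < 0 || salinity_psu > 50)
    stop("salinity_psu out of formulation validity range [0, 50]: ",
         salinity_psu)
  formulation_id <- match.arg(formulation_id, "millero2006")
  tk <- temperature_c + 273.15
  sr <- sqrt(salinity_psu)
  s <- salinity_psu

  pk1 <- (-126.34048 + 6320.813 / tk + 19.568224 * log(tk)) +
    (13.4191 * sr + 0.0331 * s - 5.33e-5 * s^2) +
    (-530.123 * sr - 6.103 * s) / tk +
    (-2.06950 * sr) * log(tk)
  pk2 <- (-90.18333 + 5143.692 / tk + 14.613358 * log(tk)) +
    (21.0894 * sr + 0.1248 * s - 3.687e-4 * s^2) +
    (-772.483 * sr - 20.051 * s) / tk +
    (-3.3336 * sr) * log(tk)
  log_ksp <- -171.9065 - 0.077993 * tk + 2839.319 / tk + 71.595 * log10(tk) +
    (-0.77712 + 0.0028426 * tk + 178.34 / tk) * sr -
    0.07711 * s + 0.0041249 * s^1.5

  structure(list(k1 = 10^(-pk1), k2 = 10^(-pk2), ksp_calcite = 10^log_ksp,
                 temperature_c = temperature_c, salinity_psu = salinity_psu,
                 formulation_id = formulation_id),
            class = "constant_set")
}

#' @export
print.constant_set <- function(x, ...) {
  cat(sprintf("<constant_set> %s @ T = %.1f degC, S = %.1f: pK1 = %.3f, pK2 = %.3f, log10 Ksp = %.3f\n",
              x$formulation_id, x$temperature_c, x$salinity_psu,
              -log10(x$k1), -log10(x$k2), log10(x$ksp_calcite)))
  invisible(x)
}

# Takahashi/CO2SYS hydrogen-ion activity factor fH linking the NBS pH scale
# (an activity scale) to seawater-scale concentrations: aH(NBS) = fH [H+].
activity_factor_fh <- function(temperature_c, salinity_psu) {
  tk <- temperature_c + 273.15
  1.29 - 0.00204 * tk + (0.00046 - 0.00000148 * tk) * salinity_psu^2
}

#' Carbonate speciation from pH and bicarbonate
#'
#' Splits dissolved inorganic carbon into CO2(aq), bicarbonate, and carbonate
#' from a measured (pH, HCO3-) pair:
#' `CO2(aq) = [HCO3-] * [H+] / K1` and `CO3^2- = [HCO3-] * K2 / [H+]`.
#' When the sample carries a calcium concentration, the calcite saturation
#' state Omega is computed as well.
#'
#' Field pH meters report the NBS (activity) scale while the stoichiometric
#' constants are defined on the seawater (concentration) scale. With the
#' default `ph_scale = "nbs"` the hydrogen-ion activity is converted to a
#' seawater-scale concentration through the Takahashi activity factor, as
#' speciation programs in the CO2SYS family do. Use `ph_scale = "sws"` if
#' the pH is already on the constants' working scale.
#'
#' @param sample A [water_sample()].
#' @param constants A [compute_constants()] result; defaults to constants at
#'   the sample's temperature and salinity.
#' @param ph_scale `"nbs"` (default; convert activity to concentration) or
#'   `"sws"` (no conversion).
#'
#' @return An object of class `carbonate_speciation`: list with
#'   `co2_aq_molar`, `hco3_molar`, `co3_molar`, `dic_molar`,
#'   `omega_calcite` (`NA` when calcium is absent), plus the pH scale and
#'   formulation used.
#' @examples
#' basin <- water_sample("basin", 29.6, 7.03, 2e-3, salinity_psu = 17.5,
#'                       calcium_molar = 11.1e-3)
#' sp <- speciate(basin)
#' sp$co2_aq_molar * 1e6  # micromolar CO2(aq)
#' @export
speciate <- function(sample, constants = NULL, ph_scale = c("nbs", "sws")) {
  stopifnot(inherits(sample, "water_sample"))
  ph_scale <- match.arg(ph_scale)
  if (!is.finite(sample$bicarbonate_molar) || sample$bicarbonate_molar <= 0)
    stop("sample has no usable bicarbonate concentration (must be > 0)")
  if (is.null(constants))
    constants <- compute_constants(sample$temperature_c, sample$salinity_psu)
  stopifnot(inherits(constants, "constant_set"))

  h <- 10^(-sample$ph)
  if (ph_scale == "nbs")
    h <- h / activity_factor_fh(constants$temperature_c, constants$salinity_psu)

  hco3 <- sample$bicarbonate_molar
  co2 <- hco3 * h / constants$k1
  co3 <- hco3 * constants$k2 / h
  omega <- if (is.finite(sample$calcium_molar) && sample$calcium_molar > 0)
    omega_calcite(sample$calcium_molar, co3, constants$ksp_calcite)
  else NA_real_

  structure(list(co2_aq_molar = co2, hco3_molar = hco3, co3_molar = co3,
                 dic_molar = co2 + hco3 + co3, omega_calcite = omega,
                 ph_scale = ph_scale,
                 formulation_id = constants$formulation_id),
            class = "carbonate_speciation")
}

#' @export
print.carbonate_speciation <- function(x, ...) {
  cat(sprintf("<carbonate_speciation> CO2(aq) = %.1f uM, HCO3- = %.1f uM, CO3^2- = %.2f uM, DIC = %.1f uM\n",
              x$co2_aq_molar * 1e6, x$hco3_molar * 1e6, x$co3_molar * 1e6,
              x$dic_molar * 1e6))
  if (is.finite(x$omega_calcite))
    cat(sprintf("  Omega_calcite = %.2f (%ssaturated)\n", x$omega_calcite,
                if (x$omega_calcite > 1) "super" else "under"))
  invisible(x)
}

#' Calcite saturation state
#'
#' `Omega = [Ca2+][CO3^2-] / Ksp`; values above 1 mean calcite precipitation
#' is thermodynamically favoured.
#'
#' @param calcium_molar Dissolved calcium, mol/L (> 0).
#' @param co3_molar Carbonate ion, mol/L (> 0).
#' @param ksp Stoichiometric calcite solubility product, (mol/L)^2 (> 0).
#' @return Dimensionless saturation state.
#' @export
omega_calcite <- function(calcium_molar, co3_molar, ksp) {
  if (!is.finite(calcium_molar) || calcium_molar <= 0)
    stop("calcium_molar must be > 0")
  if (!is.finite(co3_molar) || co3_molar <= 0) stop("co3_molar must be > 0")
  if (!is.finite(ksp) || ksp <= 0) stop("ksp must be > 0")
  calcium_molar * co3_molar / ksp
}

#' Proton yield of calcite precipitation
#'
#' At circumneutral cytoplasmic pH, precipitating calcite from calcium and
#' bicarbonate releases one proton per formula unit:
#' `Ca2+ + HCO3- -> CaCO3 + H+`. The yield is therefore exactly 1:1 and
#' linear in the amount precipitated.
#'
#' @param calcite_mol Moles of calcite precipitated (>= 0).
#' @param h_per_calcite Stoichiometric protons per mole calcite (default 1).
#' @return Moles of protons released.
#' @examples
#' calcite_proton_yield(5e-11)  # an average cell's calcite inventory
#' @export
calcite_proton_yield <- function(calcite_mol, h_per_calcite = 1) {
  if (any(!is.finite(calcite_mol)) || any(calcite_mol < 0))
    stop("calcite_mol must be >= 0")
  if (!is.finite(h_per_calcite) || h_per_calcite <= 0)
    stop("h_per_calcite must be > 0")
  calcite_mol * h_per_calcite
}

#' Approximate practical salinity from specific conductivity
#'
#' A deliberately simple ratio-to-seawater conversion: conductivity is first
#' referenced to 25 degC with a 2% per degC correction, then scaled by the
#' seawater anchor point 53 mS/cm == 35 practical salinity. Monotone
#' increasing in conductivity; intended for brackish field data where
#' salinity is only needed to ~1 unit, and flagged as approximate.
#'
#' @param conductivity_ms_cm Specific conductivity, mS/cm (> 0; 0 allowed and
#'   maps to 0).
#' @param temperature_c Temperature at which conductivity was measured.
#' @return Approximate practical salinity.
#' @examples
#' conductivity_to_salinity(53, 25)    # ~35, seawater
#' conductivity_to_salinity(28.9, 29.6) # ~17.5, about half seawater
#' @export
conductivity_to_salinity <- function(conductivity_ms_cm, temperature_c = 25) {
  if (any(!is.finite(conductivity_ms_cm)) || any(conductivity_ms_cm < 0))
    stop("conductivity_ms_cm must be >= 0")
  c25 <- conductivity_ms_cm / (1 + 0.02 * (temperature_c - 25))
  35 * c25 / 53
}

#' Read water-chemistry samples from CSV
#'
#' Expects a header row with columns `label`, `temperature_c`, `ph`,
#' `bicarbonate_mM`, and either `salinity_psu` or `conductivity_ms_cm`;
#' optional `calcium_mM` and `sulfide_uM` (blank when missing).
#' Millimolar columns are converted to mol/L.
#'
#' @param path CSV file path.
#' @return A list of [water_sample()] objects, named by label.
#' @export
read_water_samples <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "temperature_c", "ph", "bicarbonate_mM")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("water sample CSV missing columns: ",
                         paste(miss, collapse = ", "))
  get <- function(col, i) if (col %in% names(df)) df[[col]][i] else NA_real_
  out <- lapply(seq_len(nrow(df)), function(i) {
    sal <- get("salinity_psu", i)
    cond <- get("conductivity_ms_cm", i)
    water_sample(label = as.character(df$label[i]),
                 temperature_c = df$temperature_c[i], ph = df$ph[i],
                 bicarbonate_molar = df$bicarbonate_mM[i] * 1e-3,
                 salinity_psu = if (is.finite(sal)) sal else NULL,
                 conductivity_ms_cm = if (is.finite(cond)) cond else NULL,
                 calcium_molar = ifelse(is.finite(get("calcium_mM", i)),
                                        get("calcium_mM", i) * 1e-3, NA_real_),
                 sulfide_um = get("sulfide_uM", i))
  })
  names(out) <- vapply(out, `[[`, "", "label")
  out
}

#' Serialize a speciation result
#'
#' Writes a [speciate()] result as JSON or CSV with explicit unit fields
#' (all concentrations mol/L).
#'
#' @param x A `carbonate_speciation` object.
#' @param path Output file; format chosen by extension (`.json` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_speciation <- function(x, path) {
  stopifnot(inherits(x, "carbonate_speciation"))
  rec <- data.frame(quantity = c("co2_aq", "hco3", "co3", "dic", "omega_calcite"),
                    value = c(x$co2_aq_molar, x$hco3_molar, x$co3_molar,
                              x$dic_molar, x$omega_calcite),
                    unit = c("mol/L", "mol/L", "mol/L", "mol/L", "dimensionless"),
                    stringsAsFactors = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  } else {
    utils::write.csv(rec, path, row.names = FALSE)
  }
  invisible(path)
}
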