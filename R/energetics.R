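# Chemiosmotic energetics of intracellular calcite precipitation: ATP
# generable from a cell's calcite inventory via vacuolar proton pumping,
# division cycles fundable by an ATP budget, and comparison against the
# nitrate-storage strategy of other large sulfur bacteria.

#' Stoichiometric parameters for calcite/nitrate energetics
#'
#' Defaults describe an average calcite-filled sulfur-oxidizing cell:
#' 1 proton released per mole of calcite precipitated, ~3 protons consumed
#' per ATP by the ATP synthase under aerobic conditions, 0.1--0.2 pmol ATP
#' required to build one new cell (E. coli-scale costs), and a
#' nitrate-vacuole alternative in which vacuoles occupying 80% of cell
#' volume hold 250 mM nitrate yielding ~16 ATP per mole nitrate when coupled
#' to sulfur oxidation.
#'
#' @param h_per_calcite mol H+ released per mol CaCO3 precipitated.
#' @param h_per_atp mol H+ consumed per mol ATP synthesized (aerobic default
#'   3; anaerobic stoichiometry is not pinned down and can be overridden).
#' @param atp_per_division_pmol_low,atp_per_division_pmol_high pmol ATP per
#'   new cell, lower/upper bound.
#' @param vacuole_volume_fraction Fraction of cell volume occupied by the
#'   (hypothetical) nitrate vacuole, in (0, 1].
#' @param vacuole_nitrate_molar Nitrate concentration in the vacuole, mol/L.
#' @param atp_per_nitrate mol ATP gained per mol nitrate reduced.
#' @return An object of class `energetics_params`.
#' @export
energetics_params <- function(h_per_calcite = 1, h_per_atp = 3,
                              atp_per_division_pmol_low = 0.1,
                              atp_per_division_pmol_high = 0.2,
                              vacuole_volume_fraction = 0.8,
                              vacuole_nitrate_molar = 0.25,
                              atp_per_nitrate = 16) {
  vals <- c(h_per_calcite, h_per_atp, atp_per_division_pmol_low,
            atp_per_division_pmol_high, vacuole_volume_fraction,
            vacuole_nitrate_molar, atp_per_nitrate)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all energetics parameters must be strictly positive")
  if (atp_per_division_pmol_low > atp_per_division_pmol_high)
    stop("atp_per_division_pmol_low must be <= atp_per_division_pmol_high")
  if (vacuole_volume_fraction > 1)
    stop("vacuole_volume_fraction must be in (0, 1]")
  structure(list(h_per_calcite = h_per_calcite, h_per_atp = h_per_atp,
                 atp_per_division_pmol_low = atp_per_division_pmol_low,
                 atp_per_division_pmol_high = atp_per_division_pmol_high,
                 vacuole_volume_fraction = vacuole_volume_fraction,
                 vacuole_nitrate_molar = vacuole_nitrate_molar,
                 atp_per_nitrate = atp_per_nitrate),
            class = "energetics_params")
}

#' ATP generable from a cell's calcite inventory
#'
#' Precipitating the full calcite inventory releases
#' `calcite_mol * h_per_calcite` protons; pumped across the
#' inclusion-vacuole membrane by V-type ATPase/pyrophosphatase these fund
#' `protons / h_per_atp` moles of ATP. Linear in the inventory.
#'
#' @param calcite_mol Calcite inventory, mol per cell (default 5e-11 mol,
#'   i.e. 0.05 nmol, an average cell).
#' @param params An [energetics_params()] object.
#' @return Moles of ATP.
#' @examples
#' atp <- atp_from_calcite(5e-11)
#' trunc(atp * 1e12)  # 16 pmol, reported as an integer
#' @export
atp_from_calcite <- function(calcite_mol = 5e-11,
                             params = energetics_params()) {
  stopifnot(inherits(params, "energetics_params"))
  if (any(!is.finite(calcite_mol)) || any(calcite_mol < 0))
    stop("calcite_mol must be >= 0")
  calcite_mol * params$h_per_calcite / params$h_per_atp
}

#' Truncate a molar ATP amount to integer picomoles
#'
#' Reporting convention for headline ATP budgets: full precision is kept
#' internally, the report truncates to whole picomoles.
#'
#' @param atp_mol ATP in moles.
#' @return Integer picomoles.
#' @export
atp_integer_pmol <- function(atp_mol) trunc(atp_mol * 1e12)

#' Division cycles fundable by an ATP budget
#'
#' Under cumulative-doubling accounting, `n` complete doubling cycles
#' starting from one cell create `2^n - 1` new cells, each costing
#' `atp_per_division`. The capacity is the largest `n` whose cumulative cost
#' fits the budget; the final population is `2^cycles`. Budget and cost may
#' be in any single consistent unit (e.g. both pmol).
#'
#' The literature's alternative "simple" accounting (`budget / cost` new
#' cells, ignoring that later cycles must fund exponentially many cells) is
#' available as [affordable_new_cells()].
#'
#' @param atp_budget Total ATP available (> 0).
#' @param atp_per_division ATP cost per new cell (> 0), same unit.
#' @return An object of class `division_capacity`: list with `cycles`,
#'   `population` (= 2^cycles), `atp_spent`, `atp_budget`.
#' @examples
#' division_capacity(16, 0.2)  # 6 cycles, population 64
#' division_capacity(16, 0.1)  # 7 cycles, population 128
#' @export
division_capacity <- function(atp_budget, atp_per_division) {
  if (!is.finite(atp_budget) || atp_budget <= 0)
    stop("atp_budget must be > 0")
  if (!is.finite(atp_per_division) || atp_per_division <= 0)
    stop("atp_per_division must be > 0")
  n <- 0L
  # largest n with (2^n - 1) * cost <= budget
  while ((2^(n + 1L) - 1) * atp_per_division <= atp_budget) n <- n + 1L
  structure(list(cycles = n, population = 2^n,
                 atp_spent = (2^n - 1) * atp_per_division,
                 atp_budget = atp_budget),
            class = "division_capacity")
}

#' @export
print.division_capacity <- function(x, ...) {
  cat(sprintf("<division_capacity> %d cycles -> population %s (spent %.3g of %.3g ATP)\n",
              x$cycles, format(x$population, big.mark = ","), x$atp_spent,
              x$atp_budget))
  invisible(x)
}

#' New cells affordable under simple (non-compounding) accounting
#'
#' `floor(budget / cost)`: how many single new cells the budget pays for,
#' the convention behind order-of-magnitude comparisons of an ATP budget to
#' a per-cell construction cost.
#'
#' @inheritParams division_capacity
#' @return Integer count of new cells.
#' @export
affordable_new_cells <- function(atp_budget, atp_per_division) {
  if (!is.finite(atp_budget) || atp_budget <= 0) stop("atp_budget must be > 0")
  if (!is.finite(atp_per_division) || atp_per_division <= 0)
    stop("atp_per_division must be > 0")
  floor(atp_budget / atp_per_division)
}

#' ATP gain from a nitrate storage vacuole
#'
#' For a cell of given volume, a vacuole occupying
#' `vacuole_volume_fraction` of the cell and holding
#' `vacuole_nitrate_molar` nitrate yields
#' `volume * fraction * concentration * atp_per_nitrate` moles of ATP when
#' the stored nitrate is respired coupled to sulfur oxidation.
#'
#' @param cell_volume_l Cell volume in litres (> 0).
#' @param params An [energetics_params()] object.
#' @return Moles of ATP.
#' @examples
#' nitrate_vacuole_atp(1e-9)  # a 1-nL cell: 3.2e-9 mol ATP
#' @export
nitrate_vacuole_atp <- function(cell_volume_l, params = energetics_params()) {
  stopifnot(inherits(params, "energetics_params"))
  if (!is.finite(cell_volume_l) || cell_volume_l <= 0)
    stop("cell_volume_l must be > 0")
  cell_volume_l * params$vacuole_volume_fraction *
    params$vacuole_nitrate_molar * params$atp_per_nitrate
}

#' Compare calcite-derived and nitrate-derived ATP yields
#'
#' @param calcite_atp ATP from calcite precipitation, mol (> 0).
#' @param nitrate_atp ATP from stored nitrate, mol.
#' @return List with `ratio` (= nitrate/calcite) and `orders_of_magnitude`
#'   (= log10 of the ratio, unrounded).
#' @examples
#' compare_strategies(16e-12, 0.08e-6)  # ratio 5000, 3.7 orders
#' @export
compare_strategies <- function(calcite_atp, nitrate_atp) {
  if (!is.finite(calcite_atp) || calcite_atp <= 0)
    stop("calcite_atp must be > 0 for a defined ratio")
  if (!is.finite(nitrate_atp) || nitrate_atp < 0)
    stop("nitrate_atp must be >= 0")
  ratio <- nitrate_atp / calcite_atp
  list(ratio = ratio, orders_of_magnitude = log10(ratio))
}
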