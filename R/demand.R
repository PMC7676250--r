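# ---------------------------------------------------------------------------
# Demand: household-waste ratio and the nested dietary composition tree.
# ---------------------------------------------------------------------------

#' Demand-to-intake (waste) ratio
#'
#' `D/I = epsilon * Y / (zeta + Y) + 1`: at zero income there is no
#' household waste; the excess saturates at `1 + epsilon` for very high
#' incomes and reaches half the excess at `Y = zeta`.
#'
#' @param income Per-capita income (>= 0; vectorized).
#' @param waste_params Named vector `c(epsilon = , zeta = )`.
#' @return Dimensionless ratio >= 1.
#' @export
#' @examples
#' waste_ratio(0, c(epsilon = 0.45, zeta = 1e4))      # 1
#' waste_ratio(1e4, c(epsilon = 0.45, zeta = 1e4))    # 1.225
waste_ratio <- function(income, waste_params = default_parameters()$waste) {
  if (any(income < 0)) stop("negative income")
  eps <- waste_params[["epsilon"]]
  zeta <- waste_params[["zeta"]]
  stopifnot(eps >= 0, zeta > 0)
  eps * income / (zeta + income) + 1
}

#' Food demand, intake and waste from an intake and a waste ratio
#'
#' `D = ratio * I` and `X = D - I`. A ratio below one (intake exceeding
#' availability) is surfaced as an error rather than clipped: it indicates
#' a data problem.
#'
#' @param intake Intake in kcal/cap/day (>= 0).
#' @param ratio Demand/intake ratio (>= 1).
#' @return Tibble `intake_kcal`, `demand_kcal`, `waste_kcal`, `waste_ratio`.
#' @export
#' @examples
#' demand_from_intake(2000, 1.25)  # D = 2500, X = 500
demand_from_intake <- function(intake, ratio) {
  if (any(intake < 0)) stop("negative intake")
  if (any(ratio < 1)) stop("waste ratio below 1: demand would fall short of intake")
  tibble::tibble(
    intake_kcal = intake,
    demand_kcal = ratio * intake,
    waste_kcal = (ratio - 1) * intake,
    waste_ratio = ratio + 0 * intake
  )
}

.tree_share <- function(income, asymptote, halfsat) {
  asymptote * income / (halfsat + income)
}

#' Split total demand into the four-group dietary composition
#'
#' Nested saturating tree, split in fixed order so the groups are exactly
#' consistent with total calories: first animal calories
#' `L = eta Y/(theta+Y) D`, then empty calories
#' `E = iota Y/(kappa+Y) (D-L)`, then fruits/vegetables/nuts
#' `V = lambda Y/(mu+Y) (D-L-E)`, and staples as the remainder
#' `R = D - L - E - V`. All components are non-negative by the share
#' bounds, and `L + E + V + R = D` holds to round-off by construction.
#'
#' @param demand Total demand D in kcal/cap/day (>= 0; vectorized).
#' @param income Per-capita income (>= 0; recycled).
#' @param diet_params Tibble `group`, `asymptote`, `halfsat` with rows
#'   `animal`, `empty`, `fruitveg` (the `ns_params$diet` layout).
#' @return Tibble `animal_kcal`, `empty_kcal`, `fvn_kcal`, `staple_kcal`,
#'   `total_kcal`.
#' @export
#' @examples
#' split_diet(3000, 8000)  # at Y = theta the animal share is eta/2
split_diet <- function(demand, income, diet_params = default_parameters()$diet) {
  if (any(demand < 0)) stop("negative demand")
  if (any(income < 0)) stop("negative income")
  g <- function(name) {
    row <- diet_params[diet_params$group == name, ]
    stopifnot(nrow(row) == 1)
    .tree_share(income, row$asymptote, row$halfsat)
  }
  L <- g("animal") * demand
  E <- g("empty") * (demand - L)
  V <- g("fruitveg") * (demand - L - E)
  R <- demand - L - E - V
  tibble::tibble(animal_kcal = L, empty_kcal = E, fvn_kcal = V,
                 staple_kcal = R, total_kcal = demand)
}

#' Animal-source calorie share of total demand
#'
#' @param composition Tibble as returned by [split_diet()].
#' @return Fraction `L / D` in `[0, eta)`.
#' @export
animal_share <- function(composition) {
  if (any(composition$total_kcal <= 0)) stop("zero total demand; share undefined")
  composition$animal_kcal / composition$total_kcal
}
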