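# Energy system constants (Mcal and kg throughout).  The linear
# maintenance-to-gain relation is NE_g = 0.877 * NE_m - 0.41, so solved
# maintenance values must exceed 0.41/0.877 for gain energy to be positive.
.ne <- list(
  maint_coef = 0.077,   # Mcal/d per kg^0.75 shrunk BW
  gain_coef  = 0.0493,  # Mcal/d per kg^0.75 at ADG = 1 kg/d
  adg_exp    = 1.097,
  bw_exp     = 0.75,
  neg_slope  = 0.877,
  neg_int    = 0.41
)

#' Lower bound on a feasible dietary NE for maintenance
#'
#' The maintenance value at which the implied NE for gain is exactly zero
#' (0.41/0.877 Mcal/kg).  Solved dietary NE_m must exceed this bound.
#'
#' @return A single numeric, Mcal/kg.
#' @export
nem_lower_bound <- function() .ne$neg_int / .ne$neg_slope

#' Daily retained (gain) energy
#'
#' Energy deposited in gain by a growing steer,
#' \eqn{EG = ADG^{1.097} \times 0.0493\, W^{0.75}} (Mcal/d), where `W` is the
#' median feeding shrunk body weight.
#'
#' @param adg Average daily gain, kg/d.  Must be positive (the ADG -> 0
#'   limit of EG is 0, but zero gain itself is outside the model).
#' @param median_w Median feeding shrunk body weight, kg: the mean of the
#'   initial shrunk BW and the carcass-adjusted final BW.
#' @return Retained energy, Mcal/d.  Vectorised.
#' @seealso [maintenance_energy()], [solve_dietary_nem()]
#' @examples
#' retained_energy(1.74, 513)
#' @export
retained_energy <- function(adg, median_w) {
  stopifnot(is.numeric(adg), is.numeric(median_w))
  if (any(adg <= 0)) stop("`adg` must be positive")
  if (any(median_w <= 0)) stop("`median_w` must be positive")
  adg^.ne$adg_exp * .ne$gain_coef * median_w^.ne$bw_exp
}

#' Daily maintenance energy requirement
#'
#' \eqn{EM = 0.077\, W^{0.75}} Mcal/d at median feeding shrunk body weight
#' `W` (kg).
#'
#' @inheritParams retained_energy
#' @return Maintenance energy, Mcal/d.  Vectorised.
#' @examples
#' maintenance_energy(513)
#' @export
maintenance_energy <- function(median_w) {
  stopifnot(is.numeric(median_w))
  if (any(median_w <= 0)) stop("`median_w` must be positive")
  .ne$maint_coef * median_w^.ne$bw_exp
}

#' Back-solve observed dietary NE for maintenance from pen performance
#'
#' Daily intake splits between maintenance and gain as
#' \eqn{DMI = EM/NE_m + EG/(0.877 NE_m - 0.41)}.  Clearing denominators
#' gives a quadratic in \eqn{NE_m} with coefficients
#' \eqn{a = -0.41\,EM}, \eqn{b = 0.877\,EM + 0.41\,DMI + EG},
#' \eqn{c = -0.877\,DMI}; the physically meaningful root is
#' \eqn{x = (-b - \sqrt{b^2 - 4ac}) / (2c)} (the larger positive root).
#' The returned value is verified to satisfy the intake identity to a
#' relative error of 1e-9.
#'
#' @param dmi Dry matter intake, kg DM/steer/d.
#' @param em Maintenance energy, Mcal/d (see [maintenance_energy()]).
#' @param eg Retained energy, Mcal/d (see [retained_energy()]); zero is
#'   allowed and collapses to the maintenance-only closed form `em/dmi`.
#' @return Observed dietary NE for maintenance, Mcal/kg.  Vectorised.
#' @examples
#' w  <- (386 + 640) / 2
#' solve_dietary_nem(10.69, maintenance_energy(w), retained_energy(1.74, w))
#' @export
solve_dietary_nem <- function(dmi, em, eg) {
  stopifnot(is.numeric(dmi), is.numeric(em), is.numeric(eg))
  if (any(dmi <= 0)) stop("`dmi` must be positive")
  if (any(em <= 0)) stop("`em` must be positive")
  if (any(eg < 0)) stop("`eg` must be non-negative")
  a <- -.ne$neg_int * em
  b <- .ne$neg_slope * em + .ne$neg_int * dmi + eg
  cc <- -.ne$neg_slope * dmi
  disc <- b^2 - 4 * a * cc
  if (any(disc < 0)) {
    stop("infeasible performance: negative discriminant in the NE_m solve ",
         "(DMI, EM, EG) = (", dmi[which(disc < 0)[1]], ", ",
         em[which(disc < 0)[1]], ", ", eg[which(disc < 0)[1]], ")")
  }
  x <- (-b - sqrt(disc)) / (2 * cc)
  bad <- x <= nem_lower_bound() | (eg > 0 & x * .ne$neg_slope - .ne$neg_int <= 0)
  if (any(bad)) {
    stop("infeasible performance: solved NE_m (", signif(x[which(bad)[1]], 6),
         " Mcal/kg) does not exceed the zero-gain bound ",
         signif(nem_lower_bound(), 6))
  }
  # guard against a wrong-root or conditioning failure (for eg = 0 the
  # denominator is strictly positive because x exceeds the bound)
  resid <- dmi - em / x - eg / (.ne$neg_slope * x - .ne$neg_int)
  if (any(abs(resid) > 1e-9 * dmi)) {
    stop("internal error: NE_m root fails the intake identity")
  }
  x
}

#' Dietary NE for gain from NE for maintenance
#'
#' The linear relation \eqn{NE_g = 0.877\, NE_m - 0.41} (Mcal/kg).
#'
#' @param nem Dietary NE for maintenance, Mcal/kg; must exceed
#'   [nem_lower_bound()].
#' @return Dietary NE for gain, Mcal/kg.  Vectorised.
#' @examples
#' neg_from_nem(2.11)
#' @export
neg_from_nem <- function(nem) {
  stopifnot(is.numeric(nem))
  if (any(nem < nem_lower_bound())) {
    stop("`nem` below the zero-gain bound ", signif(nem_lower_bound(), 6))
  }
  .ne$neg_slope * nem - .ne$neg_int
}

#' Predict ADG from dietary NE, intake and body weight
#'
#' Exact algebraic inverse of the energy-balance chain: energy above
#' maintenance, \eqn{(DMI - EM/NE_m)}, deposits at the diet's NE for gain,
#' and the retained-energy equation is inverted for ADG.  Composing
#' [pen_energetics()] over this function recovers the input NE_m; it is
#' the forward model of the synthetic-study generator.
#'
#' @inheritParams neg_from_nem
#' @param dmi Dry matter intake, kg DM/steer/d; must exceed maintenance
#'   intake `EM/nem`.
#' @param median_w Median feeding shrunk body weight, kg.
#' @return Average daily gain, kg/d.  Vectorised.
#' @examples
#' predict_adg(2.113, 10.69, 513)
#' @export
predict_adg <- function(nem, dmi, median_w) {
  em <- maintenance_energy(median_w)
  neg <- neg_from_nem(nem)
  surplus <- dmi - em / nem
  if (any(surplus < 0)) {
    stop("gain-infeasible: intake below maintenance (DMI = ",
         dmi[which(surplus < 0)[1]], ", EM/NE_m = ",
         signif((em / nem)[which(surplus < 0)[1]], 6), ")")
  }
  eg <- surplus * neg
  (eg / (.ne$gain_coef * median_w^.ne$bw_exp))^(1 / .ne$adg_exp)
}

#' Full energetics summary for one pen (or one treatment mean)
#'
#' Composes the median-weight, maintenance/retained-energy, quadratic
#' NE_m solve and NE_g relation, and reports observed-to-expected ratios
#' against tabular (book) diet NE values.
#'
#' @param initial_shrunk_bw_kg Initial shrunk BW, kg/steer.
#' @param carcass_adjusted_final_bw_kg Carcass-adjusted final BW
#'   (HCW / common dressed yield), kg/steer.
#' @param adg_kg_d Average daily gain, kg/d.
#' @param dmi_kg_d Dry matter intake, kg DM/steer/d.
#' @param tabular_nem,tabular_neg Tabular diet NE values, Mcal/kg, used as
#'   the expected values in the observed:expected ratios.
#' @return A data.frame with columns `median_w_kg`, `em_mcal_d`,
#'   `eg_mcal_d`, `nem_mcal_kg`, `neg_mcal_kg`, `obs_exp_nem`,
#'   `obs_exp_neg`.  Vectorised over pens.
#' @examples
#' pen_energetics(386, 640, 1.74, 10.69, 2.09, 1.40)
#' @export
pen_energetics <- function(initial_shrunk_bw_kg, carcass_adjusted_final_bw_kg,
                           adg_kg_d, dmi_kg_d,
                           tabular_nem = NA_real_, tabular_neg = NA_real_) {
  if (any(adg_kg_d >= dmi_kg_d)) {
    stop("ADG must be smaller than DMI (kg gained cannot exceed kg DM eaten)")
  }
  w <- (initial_shrunk_bw_kg + carcass_adjusted_final_bw_kg) / 2
  em <- maintenance_energy(w)
  eg <- retained_energy(adg_kg_d, w)
  nem <- solve_dietary_nem(dmi_kg_d, em, eg)
  neg <- neg_from_nem(nem)
  data.frame(
    median_w_kg = w, em_mcal_d = em, eg_mcal_d = eg,
    nem_mcal_kg = nem, neg_mcal_kg = neg,
    obs_exp_nem = nem / tabular_nem, obs_exp_neg = neg / tabular_neg
  )
}

#' Replacement-technique NE value of a test ingredient
#'
#' Attributes the whole diet-level NE difference between a test diet and
#' the control diet to the substituted ingredient, scaled by its
#' inclusion, plus the NE of the corn it displaced:
#' \deqn{NE_{ingr} = (NE_{test\,diet} - NE_{control\,diet}) / y + NE_{corn}}
#' where `y` is the ingredient's inclusion (DM fraction of the diet).
#' Applied separately on the maintenance and the gain scale.
#'
#' @param test_diet_ne Observed NE of the test diet, Mcal/kg.
#' @param control_diet_ne Observed NE of the control diet, Mcal/kg.
#' @param inclusion_fraction DM inclusion of the test ingredient, in (0, 1].
#' @param displaced_corn_ne NE of the displaced corn blend, Mcal/kg.
#' @return Ingredient NE, Mcal/kg.  Vectorised.
#' @examples
#' replacement_ne(2.09, 2.11, 0.2037, 2.24)  # maintenance scale
#' replacement_ne(1.41, 1.44, 0.2025, 1.52)  # gain scale
#' @export
replacement_ne <- function(test_diet_ne, control_diet_ne, inclusion_fraction,
                           displaced_corn_ne) {
  stopifnot(is.numeric(test_diet_ne), is.numeric(control_diet_ne),
            is.numeric(inclusion_fraction), is.numeric(displaced_corn_ne))
  if (any(inclusion_fraction <= 0 | inclusion_fraction > 1)) {
    stop("`inclusion_fraction` must be in (0, 1]")
  }
  (test_diet_ne - control_diet_ne) / inclusion_fraction + displaced_corn_ne
}
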