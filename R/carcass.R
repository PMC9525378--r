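# Carcass-trait derivations.  Traits arrive metric (cm, cm^2, kg, %);
# the USDA cutability regressions are defined on imperial units, so
# exact conversion constants are applied internally.

.conv <- list(cm_per_in = 2.54, cm2_per_in2 = 6.4516, lb_per_kg = 2.20462)

# Constant sets for the cutability equations.  These are pinned defaults
# (named so alternates can be swapped); the yield-grade set reproduces
# standard USDA calculated yield grades exactly.
.yg_coef <- c(intercept = 2.50, rf_in = 2.5, kph = 0.2,
              hcw_lb = 0.0038, rea_in2 = -0.32)
.ry_coef <- c(intercept = 51.34, rf_in = -5.784, kph = -0.462,
              hcw_lb = -0.0093, rea_in2 = 0.740)
# Empty-body-fat equation (Guiroy-type), metric inputs, quality-grade
# code on a scale where marbling 400 (Small00, low Choice) codes as 5.0.
.ebf_coef <- c(intercept = 17.76207, rf_cm = 4.68142, hcw_kg = 0.01945,
               qg = 0.81855, rea_cm2 = -0.06754)
.afbw_kg_per_ebf_point <- 14.26

#' Dressing percentage
#'
#' `100 * HCW / (final BW * (1 - shrink))`: hot carcass weight over the
#' shrunk final live weight, as a percentage.
#'
#' @param hcw_kg Hot carcass weight, kg.
#' @param final_bw_kg Final live BW, kg.
#' @param shrink_fraction Shrink applied to the final live BW
#'   (default 0.04).
#' @return Percent.  Vectorised.
#' @examples
#' dressing_percentage(320, 500)   # 66.67
#' @export
dressing_percentage <- function(hcw_kg, final_bw_kg, shrink_fraction = 0.04) {
  if (any(final_bw_kg <= 0)) stop("`final_bw_kg` must be positive")
  if (any(hcw_kg <= 0)) stop("`hcw_kg` must be positive")
  100 * hcw_kg / shrink_bw(final_bw_kg, shrink_fraction)
}

#' USDA calculated yield grade
#'
#' The USDA cutability regression
#' `2.50 + 2.5 RF(in) + 0.2 KPH(%) + 0.0038 HCW(lb) - 0.32 REA(in^2)`,
#' evaluated from metric traits with exact unit conversions
#' (2.54 cm/in, 2.20462 lb/kg, 6.4516 cm^2/in^2).
#'
#' @param rf_cm Rib (subcutaneous) fat depth, cm.
#' @param kph_pct Kidney-pelvic-heart fat, percent of carcass.
#' @param hcw_kg Hot carcass weight, kg.
#' @param rea_cm2 Ribeye (longissimus) area, cm^2.
#' @return Yield grade score (lower = leaner).  Vectorised.
#' @examples
#' usda_calculated_yield_grade(1.32, 1.82, 411, 97.29)  # 2.78
#' @export
usda_calculated_yield_grade <- function(rf_cm, kph_pct, hcw_kg, rea_cm2) {
  if (any(rf_cm < 0 | kph_pct < 0 | hcw_kg < 0 | rea_cm2 < 0)) {
    stop("carcass traits must be non-negative")
  }
  .yg_coef[["intercept"]] +
    .yg_coef[["rf_in"]] * rf_cm / .conv$cm_per_in +
    .yg_coef[["kph"]] * kph_pct +
    .yg_coef[["hcw_lb"]] * hcw_kg * .conv$lb_per_kg +
    .yg_coef[["rea_in2"]] * rea_cm2 / .conv$cm2_per_in2
}

#' Estimated retail yield
#'
#' Estimated percentage of closely trimmed boneless retail cuts from the
#' round, loin, rib and chuck, from the classical four-trait cutability
#' regression on imperial units (evaluated from metric traits).
#'
#' @inheritParams usda_calculated_yield_grade
#' @return Percent.  Vectorised.
#' @export
retail_yield <- function(rf_cm, kph_pct, hcw_kg, rea_cm2) {
  if (any(rf_cm < 0 | kph_pct < 0 | hcw_kg < 0 | rea_cm2 < 0)) {
    stop("carcass traits must be non-negative")
  }
  .ry_coef[["intercept"]] +
    .ry_coef[["rf_in"]] * rf_cm / .conv$cm_per_in +
    .ry_coef[["kph"]] * kph_pct +
    .ry_coef[["hcw_lb"]] * hcw_kg * .conv$lb_per_kg +
    .ry_coef[["rea_in2"]] * rea_cm2 / .conv$cm2_per_in2
}

#' Numeric quality-grade code from a marbling score
#'
#' Maps the marbling scale (400 = Small00 = USDA low Choice) onto the
#' continuous quality-grade code used by the empty-body-fat equation:
#' `marbling / 100 + 1`, so 400 codes as 5.0.  The coding is a
#' configuration default, not a measurement; see the methods vignette.
#'
#' @param marbling Marbling score (typically 200-900).
#' @return Numeric quality-grade code.  Vectorised.
#' @export
quality_grade_code <- function(marbling) {
  if (any(marbling < 100 | marbling > 1100)) {
    stop("`marbling` outside the plausible 100-1100 scale")
  }
  marbling / 100 + 1
}

#' Estimated empty-body fat percentage
#'
#' Linear carcass-trait equation (Guiroy-type) for empty-body fat:
#' intercept + coefficients on rib fat (cm), HCW (kg), quality-grade
#' code and ribeye area (cm^2).
#'
#' @inheritParams usda_calculated_yield_grade
#' @param quality_grade_code Numeric quality-grade code
#'   (see [quality_grade_code()]).
#' @return EBF, percent.  Vectorised.
#' @examples
#' empty_body_fat(1.32, 411, 97.29, quality_grade_code(487))
#' @export
empty_body_fat <- function(rf_cm, hcw_kg, rea_cm2, quality_grade_code) {
  if (any(rf_cm < 0 | hcw_kg <= 0 | rea_cm2 <= 0)) {
    stop("carcass traits must be positive")
  }
  .ebf_coef[["intercept"]] + .ebf_coef[["rf_cm"]] * rf_cm +
    .ebf_coef[["hcw_kg"]] * hcw_kg + .ebf_coef[["qg"]] * quality_grade_code +
    .ebf_coef[["rea_cm2"]] * rea_cm2
}

#' Final BW adjusted to a common empty-body-fat endpoint
#'
#' `AFBW = final BW + (target EBF - EBF) * 14.26` kg per percentage
#' point of EBF: the weight at which the animal would have reached the
#' common fat endpoint (28% by default).  At `EBF == target` the
#' adjusted weight equals the input weight.
#'
#' @param ebf_pct Estimated empty-body fat, percent.
#' @param final_bw_kg Final shrunk (carcass-adjusted) BW, kg.
#' @param target_ebf_pct Common endpoint, percent (default 28).
#' @return AFBW, kg.  Vectorised.
#' @export
adjusted_final_bw <- function(ebf_pct, final_bw_kg, target_ebf_pct = 28) {
  final_bw_kg + (target_ebf_pct - ebf_pct) * .afbw_kg_per_ebf_point
}

#' USDA quality-grade class from a marbling score
#'
#' 100-point bands anchored at 400 = Small00 (low Choice):
#' Select < 400, LowChoice 400-499, AvgChoice 500-599, HighChoice
#' 600-699, Prime >= 700.
#'
#' @param marbling Marbling score.
#' @return Factor with levels Select, LowChoice, AvgChoice, HighChoice,
#'   Prime.
#' @export
quality_grade_class <- function(marbling) {
  cut(marbling, breaks = c(-Inf, 400, 500, 600, 700, Inf), right = FALSE,
      labels = c("Select", "LowChoice", "AvgChoice", "HighChoice", "Prime"))
}

#' USDA yield-grade class from a calculated yield grade
#'
#' The integer class is the floor of the calculated grade, bounded to
#' 1-5.
#'
#' @param calc_yield_grade Calculated yield grade score.
#' @return Integer vector in 1..5.
#' @export
yield_grade_class <- function(calc_yield_grade) {
  pmin(pmax(floor(calc_yield_grade), 1L), 5L)
}

#' Derived carcass metrics per steer
#'
#' @param carcass Data.frame with `steer_id`, `hcw_kg`, `rea_cm2`,
#'   `rf_cm`, `kph_pct`, `marbling`.
#' @param final_bw_kg Final live BW per steer (same order as `carcass`),
#'   used for the dressing percentage.
#' @param shrink Shrink fraction for the dressing denominator.
#' @param common_dressed_yield Study-wide dressed yield used for the
#'   carcass-adjusted BW that anchors the AFBW adjustment.
#' @return `carcass` plus `dressing_pct`, `calc_yield_grade`,
#'   `retail_yield_pct`, `ebf_pct`, `afbw_kg`, `usda_quality_grade`,
#'   `usda_yield_grade_class`.
#' @export
carcass_derived <- function(carcass, final_bw_kg, shrink = 0.04,
                            common_dressed_yield) {
  .check_cols(carcass, c("steer_id", "hcw_kg", "rea_cm2", "rf_cm",
                         "kph_pct", "marbling"), "carcass")
  out <- carcass
  out$dressing_pct <- dressing_percentage(carcass$hcw_kg, final_bw_kg, shrink)
  out$calc_yield_grade <- usda_calculated_yield_grade(
    carcass$rf_cm, carcass$kph_pct, carcass$hcw_kg, carcass$rea_cm2)
  out$retail_yield_pct <- retail_yield(
    carcass$rf_cm, carcass$kph_pct, carcass$hcw_kg, carcass$rea_cm2)
  out$ebf_pct <- empty_body_fat(carcass$rf_cm, carcass$hcw_kg,
                                carcass$rea_cm2,
                                quality_grade_code(carcass$marbling))
  out$afbw_kg <- adjusted_final_bw(
    out$ebf_pct, carcass_adjusted_final_bw(carcass$hcw_kg,
                                           common_dressed_yield))
  out$usda_quality_grade <- quality_grade_class(carcass$marbling)
  out$usda_yield_grade_class <- yield_grade_class(out$calc_yield_grade)
  out
}

#' Per-pen USDA grade distributions
#'
#' Tallies quality-grade and yield-grade classes into per-pen counts and
#' proportions, the unit at which grade distributions are analysed.
#'
#' @param derived Output of [carcass_derived()].
#' @param pen_id Pen identifier per steer (same order as `derived`).
#' @return Long data.frame: `pen_id`, `class_type`
#'   (`"quality"`/`"yield"`), `class`, `count`, `n`, `proportion`.
#'   Proportions sum to 1 within pen and class type.
#' @export
grade_distribution <- function(derived, pen_id) {
  pen <- as.character(pen_id)
  one <- function(cls, type) {
    tab <- table(pen = pen, class = cls)
    df <- as.data.frame(tab, stringsAsFactors = FALSE)
    names(df) <- c("pen_id", "class", "count")
    n <- as.numeric(table(pen)[df$pen_id])
    data.frame(pen_id = df$pen_id, class_type = type, class = df$class,
               count = df$count, n = n, proportion = df$count / n,
               stringsAsFactors = FALSE)
  }
  rbind(
    one(derived$usda_quality_grade, "quality"),
    one(factor(derived$usda_yield_grade_class, levels = 1:5), "yield")
  )
}
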