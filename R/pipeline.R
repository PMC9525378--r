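# Orchestration and publication-style table rendering.  The pipeline is
# a pure function of its input tables and configuration: performance ->
# energetics -> carcass -> RCBD statistics, emitting treatment-column
# tables in the shape of a finishing-trial results section.

#' Analysis configuration for [run_pipeline()]
#'
#' @param shrink Initial/final BW shrink fraction (default 0.04).
#' @param common_dressed_yield Study-wide dressed yield; `NULL` (default)
#'   computes it from the data as the mean per-steer dressing ratio.
#' @param control Label of the control treatment.
#' @param tabular_nem,tabular_neg Named tabular diet NE per treatment,
#'   Mcal/kg, for the observed:expected ratios.
#' @param inclusion Named DM inclusion fraction of the test ingredient in
#'   each test diet (control omitted).
#' @param displaced_corn_nem,displaced_corn_neg NE of the corn blend the
#'   test ingredients displaced, Mcal/kg.
#' @param block_effect `"fixed"` or `"random"` block effect for the RCBD
#'   fits.
#' @param alpha,alpha_tendency Significance and tendency thresholds.
#' @param printed_precision Round treatment-mean diet NE to 2 decimals
#'   before the replacement-technique difference (default TRUE, matching
#'   how such values are reported; set FALSE for full precision).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(shrink = 0.04, common_dressed_yield = NULL,
                            control = "CON",
                            tabular_nem = c(CON = 2.09, CBCDS = 2.09,
                                            WCGF = 2.08),
                            tabular_neg = c(CON = 1.40, CBCDS = 1.40,
                                            WCGF = 1.40),
                            inclusion = c(CBCDS = 0.2037, WCGF = 0.2025),
                            displaced_corn_nem = 2.24,
                            displaced_corn_neg = 1.52,
                            block_effect = c("fixed", "random"),
                            alpha = 0.05, alpha_tendency = 0.10,
                            printed_precision = TRUE) {
  block_effect <- match.arg(block_effect)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Replacement-technique summary from treatment-mean diet NE
#'
#' Applies [replacement_ne()] on both the maintenance and gain scales
#' for each test treatment against the control.  When
#' `printed_precision` is set the treatment-mean diet NE values are
#' first rounded to 2 decimals (round-half-even), the precision at which
#' such means are reported.
#'
#' @param nem_means,neg_means Named treatment-mean observed diet NE,
#'   Mcal/kg.
#' @param config A [pipeline_config()].
#' @return Data.frame: `ingredient`, `nem`, `neg`.
#' @examples
#' replacement_summary(c(CON = 2.11, CBCDS = 2.09, WCGF = 2.08),
#'                     c(CON = 1.44, CBCDS = 1.42, WCGF = 1.41))
#' @export
replacement_summary <- function(nem_means, neg_means,
                                config = pipeline_config()) {
  if (config$printed_precision) {
    nem_means <- round_half_even(nem_means, 2)
    neg_means <- round_half_even(neg_means, 2)
  }
  tests <- names(config$inclusion)
  data.frame(
    ingredient = tests,
    nem = vapply(tests, function(tr) {
      replacement_ne(nem_means[[tr]], nem_means[[config$control]],
                     config$inclusion[[tr]], config$displaced_corn_nem)
    }, numeric(1)),
    neg = vapply(tests, function(tr) {
      replacement_ne(neg_means[[tr]], neg_means[[config$control]],
                     config$inclusion[[tr]], config$displaced_corn_neg)
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
}

#' Run the full pen-level analysis pipeline
#'
#' Performance cleaning, per-pen energetics, per-steer carcass
#' derivation, grade tallies, and RCBD statistics for every response,
#' in one call.
#'
#' @param steers,feed,carcass Input tables (see [pen_performance()]).
#' @param config A [pipeline_config()].
#' @return List: `performance` (per pen, with energetics columns),
#'   `carcass_derived` (per steer), `grades` (per-pen proportions),
#'   `stats` (data.frame of RCBD results across responses),
#'   `grade_stats` (binomial fits per grade class), `replacement`
#'   (ingredient NE), `common_dressed_yield`, `config`.
#' @export
run_pipeline <- function(steers, feed, carcass,
                         config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  perf <- pen_performance(steers, feed, carcass, shrink = config$shrink,
                          common_dressed_yield = config$common_dressed_yield)
  yield <- attr(perf, "common_dressed_yield")
  trt <- as.character(perf$treatment)
  en <- pen_energetics(perf$initial_shrunk_bw_kg,
                       perf$carcass_adjusted_final_bw_kg,
                       perf$adg_kg_d, perf$dmi_kg_d,
                       tabular_nem = config$tabular_nem[trt],
                       tabular_neg = config$tabular_neg[trt])
  perf <- cbind(perf, en)

  ss <- steer_summary(steers)
  fin <- exclude_deads_removals(ss)
  idx <- match(fin$steer_id, carcass$steer_id)
  cd <- carcass_derived(carcass[idx, , drop = FALSE], fin$final_bw_kg,
                        shrink = config$shrink,
                        common_dressed_yield = yield)
  cd$pen_id <- fin$pen_id
  cd$block <- fin$block
  cd$treatment <- fin$treatment
  grades <- grade_distribution(cd, cd$pen_id)

  # pen-mean carcass responses join the performance table for analysis
  pm <- function(x) as.numeric(tapply(x, as.character(cd$pen_id),
                                      mean)[as.character(perf$pen_id)])
  perf$dressing_pct <- pm(cd$dressing_pct)
  perf$hcw_kg <- pm(cd$hcw_kg)
  perf$rea_cm2 <- pm(cd$rea_cm2)
  perf$rf_cm <- pm(cd$rf_cm)
  perf$marbling <- pm(cd$marbling)
  perf$kph_pct <- pm(cd$kph_pct)
  perf$calc_yield_grade <- pm(cd$calc_yield_grade)
  perf$retail_yield_pct <- pm(cd$retail_yield_pct)
  perf$ebf_pct <- pm(cd$ebf_pct)
  perf$afbw_kg <- pm(cd$afbw_kg)

  responses <- c("initial_shrunk_bw_kg", "carcass_adjusted_final_bw_kg",
                 "adg_kg_d", "dmi_kg_d", "gf", "nem_mcal_kg",
                 "neg_mcal_kg", "obs_exp_nem", "obs_exp_neg",
                 "dressing_pct", "hcw_kg", "rea_cm2", "rf_cm", "marbling",
                 "kph_pct", "calc_yield_grade", "retail_yield_pct",
                 "ebf_pct", "afbw_kg")
  fits <- lapply(responses, function(r) {
    fit_rcbd(perf, r, block_effect = config$block_effect,
             alpha = config$alpha, alpha_tendency = config$alpha_tendency)
  })
  names(fits) <- responses
  trts <- levels(factor(perf$treatment,
                        levels = unique(as.character(perf$treatment))))
  stats_tab <- do.call(rbind, lapply(fits, function(f) {
    row <- as.data.frame(as.list(f$ls_means))
    names(row) <- trts
    row$SEM <- f$sem
    row$p_value <- f$p_value
    row$classification <- f$classification
    row$letters <- paste(f$letter_groups[trts], collapse = "/")
    row
  }))
  stats_tab <- cbind(response = responses, stats_tab)
  rownames(stats_tab) <- NULL

  # binomial grade-class analysis, pen as the observation
  grade_stats <- list()
  for (ct in unique(grades$class_type)) {
    g <- grades[grades$class_type == ct, ]
    for (cl in unique(g$class)) {
      gc <- g[g$class == cl, ]
      m <- match(as.character(perf$pen_id), gc$pen_id)
      dat <- data.frame(successes = gc$count[m], n = gc$n[m],
                        treatment = perf$treatment, block = perf$block)
      grade_stats[[paste(ct, cl, sep = ":")]] <-
        fit_binomial_proportions(dat, "successes", "n",
                                 alpha = config$alpha,
                                 alpha_tendency = config$alpha_tendency)
    }
  }

  nem_means <- vapply(split(perf$nem_mcal_kg, as.character(perf$treatment)),
                      mean, numeric(1))
  neg_means <- vapply(split(perf$neg_mcal_kg, as.character(perf$treatment)),
                      mean, numeric(1))
  list(performance = perf, carcass_derived = cd, grades = grades,
       stats = stats_tab, fits = fits, grade_stats = grade_stats,
       replacement = replacement_summary(nem_means, neg_means, config),
       common_dressed_yield = yield, config = config)
}

#' Decimal round-half-even
#'
#' Rounds to `digits` decimal places with exact halves going to the even
#' neighbour, treating values within 1e-9 of a half-step as exact halves
#' (so decimal constants like 1.435 behave as written rather than as
#' their nearest binary double).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @examples
#' round_half_even(c(1.435, 1.445, 2.5, 0.163), c(2, 2, 0, 3))
#' @export
round_half_even <- function(x, digits = 0) {
  s <- x * 10^digits
  f <- floor(s)
  r <- s - f
  is_half <- abs(r - 0.5) < 1e-9
  out <- round(s)
  out[is_half] <- ifelse(f[is_half] %% 2 == 0, f[is_half], f[is_half] + 1)
  out / 10^digits
}

.layout_digits <- list(
  performance = c(initial_shrunk_bw_kg = 0, carcass_adjusted_final_bw_kg = 0,
                  final_bw_kg = 0, adg_kg_d = 2, dmi_kg_d = 2, gf = 3,
                  days_on_feed = 1, n_head_final = 0),
  energetics = c(nem_mcal_kg = 2, neg_mcal_kg = 2, obs_exp_nem = 2,
                 obs_exp_neg = 2, em_mcal_d = 2, eg_mcal_d = 2,
                 median_w_kg = 0),
  carcass = c(dressing_pct = 2, hcw_kg = 0, rea_cm2 = 2, rf_cm = 2,
              marbling = 0, kph_pct = 2, calc_yield_grade = 2,
              retail_yield_pct = 2, ebf_pct = 2, afbw_kg = 0),
  grades = c(proportion_pct = 2)
)

#' Render a results block as fixed-layout text
#'
#' Formats rows of the pipeline `stats` table in treatment-column order
#' with SEM and P-value, at the conventional printed precision for each
#' response (BW integer kg; ADG and NE 2 decimals; G:F 3 decimals;
#' percentages 2 decimals), using [round_half_even()] throughout.
#' Superscript-style letters are appended when the treatment P-value is
#' at or below the tendency threshold.
#'
#' @param stats_tab The `stats` element of [run_pipeline()] output (any
#'   subset of rows).
#' @param layout One of `"performance"`, `"energetics"`, `"carcass"`,
#'   `"grades"` — selects the per-response precision set.
#' @param alpha_tendency Letter-display threshold (default 0.10).
#' @return Character vector of lines (header first).
#' @export
render_table <- function(stats_tab,
                         layout = c("performance", "energetics", "carcass",
                                    "grades"),
                         alpha_tendency = 0.10) {
  layout <- match.arg(layout)
  digits_map <- .layout_digits[[layout]]
  trts <- setdiff(names(stats_tab),
                  c("response", "SEM", "p_value", "classification",
                    "letters"))
  header <- paste(c("Item", trts, "SEM", "P-value"), collapse = "\t")
  if (!nrow(stats_tab)) return(header)
  all_digits <- unlist(.layout_digits)
  names(all_digits) <- sub("^[a-z]+\\.", "", names(all_digits))
  lines <- vapply(seq_len(nrow(stats_tab)), function(i) {
    r <- stats_tab[i, ]
    dg <- digits_map[r$response]
    if (is.na(dg)) dg <- all_digits[r$response]  # fall back across layouts
    if (is.na(dg)) dg <- 2
    dg <- unname(dg)
    vals <- vapply(trts, function(tr) {
      v <- formatC(round_half_even(r[[tr]], dg), format = "f", digits = dg)
      if (!is.na(r$p_value) && r$p_value <= alpha_tendency &&
          nzchar(r$letters)) {
        lab <- strsplit(r$letters, "/", fixed = TRUE)[[1]]
        names(lab) <- trts
        if (nzchar(lab[[tr]])) v <- paste0(v, "^", lab[[tr]], "^")
      }
      v
    }, character(1))
    paste(c(r$response, vals,
            formatC(r$SEM, format = "g", digits = 3),
            formatC(round_half_even(r$p_value, 2), format = "f",
                    digits = 2)), collapse = "\t")
  }, character(1))
  c(header, lines)
}

#' Example treatment-mean performance inputs
#'
#' Pen-level treatment means of the kind produced by
#' [pen_performance()] for a three-treatment corn-coproduct replacement
#' trial, at reported precision.  Used by the worked examples and the
#' reproduction script.
#'
#' @return Data.frame with one row per treatment: `treatment`,
#'   `initial_shrunk_bw_kg`, `carcass_adjusted_final_bw_kg`, `adg_kg_d`,
#'   `dmi_kg_d`.
#' @export
example_treatment_means <- function() {
  data.frame(
    treatment = c("CON", "CBCDS", "WCGF"),
    initial_shrunk_bw_kg = c(386, 385, 385),
    carcass_adjusted_final_bw_kg = c(640, 637, 634),
    adg_kg_d = c(1.74, 1.73, 1.70),
    dmi_kg_d = c(10.69, 10.76, 10.67),
    stringsAsFactors = FALSE
  )
}

#' Worked example: observed diet NE and ingredient replacement values
#'
#' Runs the energetics chain on [example_treatment_means()] and the
#' replacement technique on the resulting (2-decimal) diet NE means —
#' the desk-scale reproduction of the package's core computation.
#'
#' @param config A [pipeline_config()].
#' @return List: `energetics` (per-treatment data.frame), `replacement`
#'   (ingredient NE data.frame).
#' @examples
#' worked_example()
#' @export
worked_example <- function(config = pipeline_config()) {
  tm <- example_treatment_means()
  en <- pen_energetics(tm$initial_shrunk_bw_kg,
                       tm$carcass_adjusted_final_bw_kg,
                       tm$adg_kg_d, tm$dmi_kg_d,
                       tabular_nem = config$tabular_nem[tm$treatment],
                       tabular_neg = config$tabular_neg[tm$treatment])
  en <- cbind(treatment = tm$treatment, en)
  nem <- stats::setNames(en$nem_mcal_kg, tm$treatment)
  neg <- stats::setNames(en$neg_mcal_kg, tm$treatment)
  list(energetics = en,
       replacement = replacement_summary(nem, neg, config))
}
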