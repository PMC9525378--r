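# Pen-level growth performance from per-steer weigh records, feed
# deliveries and carcass weights.  All masses kg; intakes on a DM basis.
#
# Conventions:
#  * `steers` is a long table with one row per weigh event:
#    steer_id, pen_id, block, treatment, day, bw_kg, disposition,
#    disposition_day (NA for finishers).
#  * `feed` has one row per delivery: pen_id, day, as_fed_kg, dm_fraction,
#    destination ("home"/"hospital"), steer_id (hospital rows only).
#  * `disposition_day` is the first study day on which a steer was no
#    longer fed in its home pen; a dead/removed steer accrues head-days
#    through `disposition_day - 1` (date-of-disposition accounting; the
#    convention is an assumption, stated in the vignette).

.steer_cols <- c("steer_id", "pen_id", "block", "treatment", "day", "bw_kg",
                 "disposition")
.feed_cols <- c("pen_id", "day", "as_fed_kg", "dm_fraction", "destination")

.check_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("`", what, "` is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  invisible(df)
}

#' Apply a fixed shrink to live body weight
#'
#' Shrunk BW discounts live weight by a fixed fraction (4% by default)
#' for gastrointestinal fill: `bw_kg * (1 - shrink_fraction)`.
#'
#' @param bw_kg Live body weight, kg.
#' @param shrink_fraction Fraction removed, in `[0, 1)`; default 0.04.
#' @return Shrunk body weight, kg.  Vectorised.
#' @examples
#' shrink_bw(401)       # 385.0 (approx.)
#' @export
shrink_bw <- function(bw_kg, shrink_fraction = 0.04) {
  stopifnot(is.numeric(bw_kg), is.numeric(shrink_fraction))
  if (any(bw_kg < 0)) stop("`bw_kg` must be non-negative")
  if (any(shrink_fraction < 0 | shrink_fraction >= 1)) {
    stop("`shrink_fraction` must be in [0, 1)")
  }
  bw_kg * (1 - shrink_fraction)
}

#' Carcass-adjusted final body weight
#'
#' Final BW standardised to carcass terms: hot carcass weight divided by
#' a common dressed yield, removing gut-fill and dressing variation from
#' the growth endpoint.
#'
#' @param hcw_kg Hot carcass weight, kg.
#' @param common_dressed_yield The study-wide average dressed yield
#'   (fraction in (0, 1)), e.g. the mean of per-steer HCW / shrunk final
#'   BW over all finishers.
#' @return Carcass-adjusted final BW, kg.  Vectorised.
#' @examples
#' carcass_adjusted_final_bw(411, 0.6433)
#' @export
carcass_adjusted_final_bw <- function(hcw_kg, common_dressed_yield) {
  stopifnot(is.numeric(hcw_kg), is.numeric(common_dressed_yield))
  if (any(hcw_kg <= 0)) stop("`hcw_kg` must be positive")
  if (any(common_dressed_yield <= 0 | common_dressed_yield >= 1)) {
    stop("`common_dressed_yield` must be in (0, 1)")
  }
  hcw_kg / common_dressed_yield
}

#' Cumulative average daily gain
#'
#' @param initial_shrunk_bw Initial shrunk BW, kg.
#' @param final_bw Final BW (typically carcass-adjusted), kg.
#' @param days Days on feed; must be positive (may be fractional when
#'   averaged over weigh groups).
#' @return ADG, kg/d.  Vectorised.
#' @examples
#' cumulative_adg(386, 640, 145.5)
#' @export
cumulative_adg <- function(initial_shrunk_bw, final_bw, days) {
  stopifnot(is.numeric(initial_shrunk_bw), is.numeric(final_bw),
            is.numeric(days))
  if (any(days <= 0)) stop("`days` must be positive")
  (final_bw - initial_shrunk_bw) / days
}

#' Restrict records to steers that finished the study
#'
#' Growth performance is computed on a deads-and-removals-excluded
#' basis: only rows whose `disposition` is `"finished"` are retained.
#'
#' @param records A data.frame with a `disposition` column.
#' @return The subset of `records` with `disposition == "finished"`.
#' @export
exclude_deads_removals <- function(records) {
  .check_cols(records, "disposition", "records")
  bad <- setdiff(unique(records$disposition),
                 c("finished", "died", "removed"))
  if (length(bad)) {
    stop("unknown disposition value(s): ", paste(bad, collapse = ", "))
  }
  records[records$disposition == "finished", , drop = FALSE]
}

#' Per-steer summary of a long weigh-event table
#'
#' Collapses the weigh-event rows to one row per steer with its initial
#' (earliest) and final (latest) weights and its days on feed.
#'
#' @param steers Long weigh-event table (see the module conventions).
#' @return One row per steer: `steer_id`, `pen_id`, `block`, `treatment`,
#'   `disposition`, `disposition_day`, `initial_bw_kg`, `final_bw_kg`,
#'   `first_day`, `last_day`.
#' @export
steer_summary <- function(steers) {
  .check_cols(steers, .steer_cols, "steers")
  if (!"disposition_day" %in% names(steers)) {
    steers$disposition_day <- NA_real_
  }
  o <- order(steers$steer_id, steers$day)
  s <- steers[o, ]
  if (anyDuplicated(s[, c("steer_id", "day")])) {
    stop("duplicate weigh event (steer_id, day) pairs in `steers`")
  }
  if (any(s$bw_kg <= 0)) stop("body weights must be positive")
  first <- s[!duplicated(s$steer_id), ]
  last <- s[!duplicated(s$steer_id, fromLast = TRUE), ]
  out <- data.frame(
    steer_id = first$steer_id, pen_id = first$pen_id, block = first$block,
    treatment = first$treatment, disposition = first$disposition,
    disposition_day = first$disposition_day,
    initial_bw_kg = first$bw_kg, final_bw_kg = last$bw_kg,
    first_day = first$day, last_day = last$day,
    stringsAsFactors = FALSE
  )
  fin <- out$disposition == "finished"
  if (any(fin & !is.na(out$disposition_day)) ||
      any(!fin & is.na(out$disposition_day))) {
    stop("`disposition_day` must be present iff disposition != finished")
  }
  out
}

#' Head-days per pen under date-of-disposition accounting
#'
#' A finisher contributes the pen's full days on feed; a dead or removed
#' steer contributes head-days through the day before its
#' `disposition_day` (its last day fed in the home pen).
#'
#' @param steer_tab Output of [steer_summary()] (all steers, not just
#'   finishers).
#' @param days_on_feed Named vector of days on feed per pen; if `NULL`,
#'   taken as the maximum `last_day` among each pen's finishers.
#' @return Named numeric vector of head-days per pen.
#' @export
pen_head_days <- function(steer_tab, days_on_feed = NULL) {
  if (is.null(days_on_feed)) {
    fin <- steer_tab[steer_tab$disposition == "finished", ]
    days_on_feed <- tapply(fin$last_day - fin$first_day, fin$pen_id, max)
  }
  dof <- days_on_feed[as.character(steer_tab$pen_id)]
  if (anyNA(dof)) stop("pen(s) without a days-on-feed value")
  hd <- ifelse(steer_tab$disposition == "finished",
               dof, pmin(steer_tab$disposition_day - 1, dof))
  out <- tapply(hd, steer_tab$pen_id, sum)
  stats::setNames(as.numeric(out), names(out))
}

#' Pen dry matter intake with hospital-pen feed crediting
#'
#' Sums delivered dry matter (`as_fed_kg * dm_fraction`) per pen and
#' divides by head-days.  Feed delivered to a hospital pen remains
#' credited to the steer's home pen if the steer later returned
#' (finished the study); if the steer never returned, all its hospital
#' deliveries are excluded, which deducts that feed back to the date of
#' hospitalisation.
#'
#' @param feed Delivery table (see the module conventions).
#' @param head_days Named vector of head-days per pen
#'   (see [pen_head_days()]).
#' @param returned Named logical vector, by steer id, saying whether each
#'   hospitalised steer returned to its home pen.  Every hospital-row
#'   `steer_id` must be named here.
#' @return Named numeric vector: kg DM per steer per day, by pen.
#' @examples
#' feed <- data.frame(pen_id = "P1", day = 1:10, as_fed_kg = 10,
#'                    dm_fraction = 0.8, destination = "home",
#'                    steer_id = NA)
#' pen_dmi(feed, c(P1 = 10), returned = logical(0))
#' @export
pen_dmi <- function(feed, head_days, returned) {
  .check_cols(feed, .feed_cols, "feed")
  if (any(feed$as_fed_kg < 0)) stop("`as_fed_kg` must be non-negative")
  if (any(feed$dm_fraction <= 0 | feed$dm_fraction > 1)) {
    stop("`dm_fraction` must be in (0, 1]")
  }
  bad_dest <- setdiff(unique(feed$destination), c("home", "hospital"))
  if (length(bad_dest)) {
    stop("unknown destination value(s): ", paste(bad_dest, collapse = ", "))
  }
  unknown_pen <- setdiff(unique(as.character(feed$pen_id)), names(head_days))
  if (length(unknown_pen)) {
    stop("feed delivered to unknown pen(s): ",
         paste(unknown_pen, collapse = ", "))
  }
  if (any(head_days <= 0)) stop("`head_days` must be positive")
  hosp <- feed$destination == "hospital"
  if (any(hosp)) {
    sid <- as.character(feed$steer_id[hosp])
    if (anyNA(feed$steer_id[hosp]) || !all(sid %in% names(returned))) {
      stop("hospital deliveries reference steer(s) with unknown return status")
    }
  }
  dm <- feed$as_fed_kg * feed$dm_fraction
  keep <- !hosp
  if (any(hosp)) {
    keep[hosp] <- returned[as.character(feed$steer_id[hosp])]
  }
  tot <- tapply(dm[keep], as.character(feed$pen_id)[keep], sum)
  out <- stats::setNames(rep(0, length(head_days)), names(head_days))
  out[names(tot)] <- as.numeric(tot)
  out / head_days
}

#' Pen-level cumulative, carcass-adjusted growth performance
#'
#' Cleans per-steer records into one performance row per pen: finishers
#' only for all weight aggregates, a fixed initial-BW shrink, final BW
#' carcass-adjusted through a common dressed yield, and DMI under the
#' hospital-pen crediting rule.
#'
#' @param steers Long weigh-event table (module conventions).
#' @param feed Feed-delivery table.
#' @param carcass Per-steer carcass table with at least `steer_id` and
#'   `hcw_kg`; every finisher must appear.
#' @param shrink Initial-BW shrink fraction (default 0.04).  The same
#'   shrink defines the final shrunk BW used in the dressing ratio.
#' @param common_dressed_yield If `NULL` (default), computed as the
#'   simple mean of per-steer HCW / shrunk final BW over all finishers,
#'   then applied uniformly.
#' @return A data.frame with one row per pen: `pen_id`, `block`,
#'   `treatment`, `n_head_final`, `days_on_feed`, `initial_shrunk_bw_kg`,
#'   `final_bw_kg` (live), `carcass_adjusted_final_bw_kg`, `adg_kg_d`,
#'   `dmi_kg_d`, `gf`.  The yield used is attached as attribute
#'   `common_dressed_yield`.
#' @export
pen_performance <- function(steers, feed, carcass, shrink = 0.04,
                            common_dressed_yield = NULL) {
  .check_cols(carcass, c("steer_id", "hcw_kg"), "carcass")
  ss <- steer_summary(steers)
  fin <- exclude_deads_removals(ss)
  if (!nrow(fin)) stop("no finishers in `steers`")
  idx <- match(fin$steer_id, carcass$steer_id)
  if (anyNA(idx)) {
    stop("finisher(s) missing from `carcass`: ",
         paste(utils::head(fin$steer_id[is.na(idx)], 5), collapse = ", "))
  }
  fin$hcw_kg <- carcass$hcw_kg[idx]
  fin$final_shrunk_bw_kg <- shrink_bw(fin$final_bw_kg, shrink)
  if (is.null(common_dressed_yield)) {
    common_dressed_yield <- mean(fin$hcw_kg / fin$final_shrunk_bw_kg)
  }
  fin$carc_adj_bw_kg <-
    carcass_adjusted_final_bw(fin$hcw_kg, common_dressed_yield)
  fin$initial_shrunk_bw_kg <- shrink_bw(fin$initial_bw_kg, shrink)

  pens <- unique(fin[, c("pen_id", "block", "treatment")])
  pens <- pens[order(pens$pen_id), ]
  key <- as.character(fin$pen_id)
  agg <- function(x) as.numeric(tapply(x, key, mean)[as.character(pens$pen_id)])
  dof <- as.numeric(tapply(fin$last_day - fin$first_day, key,
                           max)[as.character(pens$pen_id)])
  out <- data.frame(
    pen_id = pens$pen_id, block = pens$block, treatment = pens$treatment,
    n_head_final = as.numeric(table(key)[as.character(pens$pen_id)]),
    days_on_feed = dof,
    initial_shrunk_bw_kg = agg(fin$initial_shrunk_bw_kg),
    final_bw_kg = agg(fin$final_bw_kg),
    carcass_adjusted_final_bw_kg = agg(fin$carc_adj_bw_kg),
    stringsAsFactors = FALSE
  )
  out$adg_kg_d <- cumulative_adg(out$initial_shrunk_bw_kg,
                                 out$carcass_adjusted_final_bw_kg,
                                 out$days_on_feed)
  hd <- pen_head_days(ss, stats::setNames(dof, as.character(pens$pen_id)))
  ret <- stats::setNames(ss$disposition == "finished",
                         as.character(ss$steer_id))
  dmi <- pen_dmi(feed, hd, ret)
  out$dmi_kg_d <- as.numeric(dmi[as.character(out$pen_id)])
  out$gf <- out$adg_kg_d / out$dmi_kg_d
  attr(out, "common_dressed_yield") <- common_dressed_yield
  out
}
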