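# Synthetic finishing-study generator.  The forward model for gain is
# the package's own energy system (predict_adg), so the analysis stage
# is correctly specified on generated data and parameter-recovery tests
# are meaningful.  Steers are blocked by initial weight exactly as a
# weight-blocked RCBD allocates them: draws are sorted and sliced into
# blocks, then randomised to pens within block.

#' Configuration of a synthetic randomized-complete-block feeding study
#'
#' Defaults describe a 3-treatment x 10-block design with 8 steers per
#' pen, ~145.5 d on feed (146 d for the first weigh group, 145 d for
#' the second), initial BW 401 +/- 43.2 kg, treatment-level true diet
#' NE_m of 2.11/2.09/2.08 Mcal/kg and mean DMI near 10.7 kg/d, and a
#' study-average dressed yield of 0.6433.  Dispersion defaults are
#' chosen to give pen-level standard errors of the size seen in
#' well-run university feedlot trials (see the methods vignette).
#'
#' @param n_blocks Number of complete blocks (pens per treatment).
#' @param treatments Treatment labels; first is the control.
#' @param true_nem Named true dietary NE_m per treatment, Mcal/kg.
#' @param dmi_mean Named mean pen DMI per treatment at the reference
#'   weight, kg DM/steer/d.
#' @param steers_per_pen Steers allotted per pen.
#' @param days_on_feed Length-2 integer vector: days on feed for weigh
#'   group 1 (first half of blocks) and group 2.
#' @param weigh_days Interim weigh days (between day 0 and the final
#'   day).
#' @param initial_bw_mean,initial_bw_sd Unshrunk initial BW
#'   distribution, kg.
#' @param shrink Initial/final BW shrink fraction.
#' @param dmi_cv CV of pen-level DMI around its treatment mean.
#' @param adg_residual_sd SD (kg/d) of pen ADG around the
#'   energy-predicted value (pen-to-pen efficiency variation).
#' @param steer_adg_sd Within-pen SD (kg/d) of steer ADG around the pen
#'   mean.
#' @param weigh_noise_sd SD (kg) of interim weigh-day scale noise.
#' @param delivery_cv CV of daily as-fed delivery around target.
#' @param diet_dm Named diet DM fraction per treatment.
#' @param dm_fraction_sd Day-to-day SD of the batch DM fraction.
#' @param dressed_yield_mean,dressed_yield_sd Per-steer dressed-yield
#'   distribution.
#' @param rea,rf Named vectors `c(intercept, slope, sd)`: linear models
#'   of ribeye area (cm^2) and rib fat (cm) on final shrunk BW.
#' @param kph,marbling Named vectors `c(mean, sd)`.
#' @param removal_probability Per-steer probability of death/removal.
#' @param hospital_episode_prob Per-finisher probability of a temporary
#'   hospital-pen episode (feed credited back to the home pen).
#' @param hospital_days Length of a temporary hospital episode, days.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    n_blocks = 10,
    treatments = c("CON", "CBCDS", "WCGF"),
    true_nem = c(CON = 2.11, CBCDS = 2.09, WCGF = 2.08),
    dmi_mean = c(CON = 10.69, CBCDS = 10.76, WCGF = 10.67),
    steers_per_pen = 8,
    days_on_feed = c(146L, 145L),
    weigh_days = c(14, 42, 77, 105),
    initial_bw_mean = 401, initial_bw_sd = 43.2,
    shrink = 0.04,
    dmi_cv = 0.038,
    adg_residual_sd = 0.09,
    steer_adg_sd = 0.15,
    weigh_noise_sd = 2,
    delivery_cv = 0.02,
    diet_dm = c(CON = 0.81, CBCDS = 0.71, WCGF = 0.70),
    dm_fraction_sd = 0.01,
    dressed_yield_mean = 0.6433, dressed_yield_sd = 0.012,
    rea = c(intercept = 40, slope = 0.09, sd = 4.5),
    rf = c(intercept = -0.5, slope = 0.00275, sd = 0.22),
    kph = c(mean = 1.8, sd = 0.15),
    marbling = c(mean = 480, sd = 75),
    removal_probability = 4 / 240,
    hospital_episode_prob = 0.03,
    hospital_days = 3L) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(n_blocks >= 2, steers_per_pen >= 1,
              length(days_on_feed) == 2, all(days_on_feed > 0),
              length(treatments) >= 2)
    sds <- c(initial_bw_sd, dmi_cv, adg_residual_sd, steer_adg_sd,
             weigh_noise_sd, delivery_cv, dm_fraction_sd,
             dressed_yield_sd, rea[["sd"]], rf[["sd"]], kph[["sd"]],
             marbling[["sd"]])
    if (any(sds < 0)) stop("all dispersion parameters must be >= 0")
    if (removal_probability < 0 || removal_probability > 1 ||
        hospital_episode_prob < 0 || hospital_episode_prob > 1) {
      stop("probabilities must lie in [0, 1]")
    }
    for (nm in c("true_nem", "dmi_mean", "diet_dm")) {
      v <- cfg[[nm]]
      if (!all(treatments %in% names(v))) {
        stop("`", nm, "` must be named for every treatment")
      }
    }
    if (any(true_nem <= nem_lower_bound())) {
      stop("`true_nem` at or below the zero-gain bound")
    }
  })
  structure(cfg, class = "synthetic_config")
}

# Median-W / ADG fixed point for one pen: ADG comes from the energy
# system at the drawn pen DMI, and final BW feeds back into the median
# weight.
.pen_fixed_point <- function(nem, dmi, init_shrunk, days,
                             tol = 1e-8, max_iter = 200) {
  w <- init_shrunk
  for (i in seq_len(max_iter)) {
    adg <- predict_adg(nem, dmi, w)
    w_new <- init_shrunk + adg * days / 2
    if (abs(w_new - w) < tol) {
      return(list(w = w_new, dmi = dmi, adg = adg, iterations = i))
    }
    w <- w_new
  }
  stop("median-weight fixed point failed to converge")
}

#' Generate a complete synthetic feeding study
#'
#' Produces the three raw tables the analysis pipeline consumes: a long
#' per-steer weigh-event table, a feed-delivery table (home and
#' hospital destinations), and a per-steer carcass table for finishers.
#' Pen ADG is generated through the energy system at the configured
#' true diet NE_m, with the median-weight circularity resolved by
#' fixed-point iteration; hot carcass weight is final shrunk BW times a
#' per-steer dressed-yield draw; carcass traits are conditionally
#' Gaussian given final BW.  Fully reproducible for a given config and
#' seed.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer RNG seed.
#' @return List of class `synthetic_study`: `steers`, `feed`, `carcass`
#'   data.frames, plus `pens` (the design with per-pen truth) and the
#'   `config` and `seed` used.
#' @export
generate_study <- function(config = synthetic_config(), seed = 1) {
  stopifnot(inherits(config, "synthetic_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(seed)
  cf <- config
  n_trt <- length(cf$treatments)
  n_pens <- cf$n_blocks * n_trt
  n_steers <- n_pens * cf$steers_per_pen

  # weight-blocked allotment: sort draws, slice into blocks, randomise
  # to pens within block
  bw0 <- pmax(stats::rnorm(n_steers, cf$initial_bw_mean, cf$initial_bw_sd),
              0.5 * cf$initial_bw_mean)
  bw0 <- sort(bw0, decreasing = TRUE)
  per_block <- n_trt * cf$steers_per_pen

  steers_rows <- vector("list", n_pens)
  feed_rows <- vector("list", n_pens)
  carcass_rows <- vector("list", n_pens)
  pen_rows <- vector("list", n_pens)
  pen_i <- 0

  for (b in seq_len(cf$n_blocks)) {
    blk_bw <- bw0[((b - 1) * per_block + 1):(b * per_block)]
    blk_bw <- blk_bw[sample.int(per_block)]
    group <- if (b <= ceiling(cf$n_blocks / 2)) 1L else 2L
    days <- cf$days_on_feed[group]
    for (t in seq_len(n_trt)) {
      pen_i <- pen_i + 1
      trt <- cf$treatments[t]
      pen_id <- sprintf("P%02d", pen_i)
      sid <- sprintf("%s_S%d", pen_id, seq_len(cf$steers_per_pen))
      bw_init <- blk_bw[((t - 1) * cf$steers_per_pen + 1):
                        (t * cf$steers_per_pen)]
      init_shrunk_pen <- mean(bw_init) * (1 - cf$shrink)

      fp <- tryCatch(
        .pen_fixed_point(cf$true_nem[[trt]], cf$dmi_mean[[trt]] *
                           (1 + stats::rnorm(1, 0, cf$dmi_cv)),
                         init_shrunk_pen, days),
        error = function(e) {
          stop("generation failed for pen ", pen_id, " (", trt, "): ",
               conditionMessage(e))
        })
      adg_pen <- fp$adg + stats::rnorm(1, 0, cf$adg_residual_sd)
      if (adg_pen <= 0) {
        stop("generation failed for pen ", pen_id,
             ": non-positive pen ADG under the configured noise")
      }
      dmi_pen <- fp$dmi

      adg_steer <- adg_pen + stats::rnorm(cf$steers_per_pen, 0,
                                          cf$steer_adg_sd)
      init_shrunk <- bw_init * (1 - cf$shrink)
      final_shrunk <- init_shrunk + adg_steer * days
      final_live <- final_shrunk / (1 - cf$shrink)

      # dispositions: disposition_day is the first day not fed at home
      removed <- stats::runif(cf$steers_per_pen) < cf$removal_probability
      disp <- ifelse(removed,
                     sample(c("died", "removed"), cf$steers_per_pen,
                            replace = TRUE), "finished")
      disp_day <- ifelse(removed,
                         floor(stats::runif(cf$steers_per_pen, 15,
                                            days - 14)), NA_real_)

      # weigh events: day 0, interim days while present, final day for
      # finishers; endpoint weights exact, interim weights noisy around
      # the linear growth path
      sched <- sort(unique(c(0, cf$weigh_days[cf$weigh_days < days], days)))
      ev <- lapply(seq_len(cf$steers_per_pen), function(i) {
        d <- if (removed[i]) sched[sched < disp_day[i]] else sched
        bw <- bw_init[i] + (final_live[i] - bw_init[i]) * d / days
        mid <- d > 0 & d < days
        bw[mid] <- bw[mid] + stats::rnorm(sum(mid), 0, cf$weigh_noise_sd)
        data.frame(steer_id = sid[i], pen_id = pen_id,
                   block = sprintf("B%02d", b), treatment = trt,
                   day = d, bw_kg = bw, disposition = disp[i],
                   disposition_day = disp_day[i], stringsAsFactors = FALSE)
      })
      steers_rows[[pen_i]] <- do.call(rbind, ev)

      # hospital episodes for finishers (feed stays credited)
      episode <- !removed & stats::runif(cf$steers_per_pen) <
        cf$hospital_episode_prob
      ep_start <- ifelse(episode,
                         floor(stats::runif(cf$steers_per_pen, 2,
                                            days - cf$hospital_days)),
                         NA_real_)

      # presence-at-home matrix steers x feed days (1..days)
      present <- matrix(TRUE, cf$steers_per_pen, days)
      for (i in seq_len(cf$steers_per_pen)) {
        if (removed[i]) present[i, disp_day[i]:days] <- FALSE
        if (episode[i]) {
          present[i, ep_start[i]:(ep_start[i] + cf$hospital_days - 1)] <- FALSE
        }
      }
      heads_home <- colSums(present)
      dm_frac <- pmin(pmax(cf$diet_dm[[trt]] +
                             stats::rnorm(days, 0, cf$dm_fraction_sd),
                           0.2), 1)
      dm_target <- dmi_pen * heads_home *
        (1 + stats::rnorm(days, 0, cf$delivery_cv))
      home <- data.frame(pen_id = pen_id, day = as.numeric(seq_len(days)),
                         as_fed_kg = dm_target / dm_frac,
                         dm_fraction = dm_frac, destination = "home",
                         steer_id = NA_character_, stringsAsFactors = FALSE)
      hosp_list <- list()
      for (i in seq_len(cf$steers_per_pen)) {
        hd <- integer(0)
        if (removed[i]) {
          hd <- disp_day[i]:min(disp_day[i] + cf$hospital_days - 1, days)
        } else if (episode[i]) {
          hd <- ep_start[i]:(ep_start[i] + cf$hospital_days - 1)
        }
        if (length(hd)) {
          hf <- pmin(pmax(cf$diet_dm[[trt]] +
                            stats::rnorm(length(hd), 0, cf$dm_fraction_sd),
                          0.2), 1)
          hosp_list[[length(hosp_list) + 1]] <- data.frame(
            pen_id = pen_id, day = as.numeric(hd),
            as_fed_kg = dmi_pen * (1 + stats::rnorm(length(hd), 0,
                                                    cf$delivery_cv)) / hf,
            dm_fraction = hf, destination = "hospital", steer_id = sid[i],
            stringsAsFactors = FALSE)
        }
      }
      feed_rows[[pen_i]] <- rbind(home, do.call(rbind, hosp_list))

      # carcass traits for finishers
      fin <- !removed
      if (any(fin)) {
        fs <- final_shrunk[fin]
        yield <- stats::rnorm(sum(fin), cf$dressed_yield_mean,
                              cf$dressed_yield_sd)
        carcass_rows[[pen_i]] <- data.frame(
          steer_id = sid[fin],
          hcw_kg = fs * yield,
          rea_cm2 = cf$rea[["intercept"]] + cf$rea[["slope"]] * fs +
            stats::rnorm(sum(fin), 0, cf$rea[["sd"]]),
          rf_cm = pmax(cf$rf[["intercept"]] + cf$rf[["slope"]] * fs +
                         stats::rnorm(sum(fin), 0, cf$rf[["sd"]]), 0.1),
          kph_pct = pmax(stats::rnorm(sum(fin), cf$kph[["mean"]],
                                      cf$kph[["sd"]]), 0.5),
          marbling = round(pmin(pmax(
            stats::rnorm(sum(fin), cf$marbling[["mean"]],
                         cf$marbling[["sd"]]), 210), 1050)),
          stringsAsFactors = FALSE)
      }
      pen_rows[[pen_i]] <- data.frame(
        pen_id = pen_id, block = sprintf("B%02d", b), treatment = trt,
        days_on_feed = days, true_nem = cf$true_nem[[trt]],
        pen_dmi = dmi_pen, pen_adg = adg_pen,
        fixed_point_iterations = fp$iterations, stringsAsFactors = FALSE)
    }
  }
  structure(list(
    steers = do.call(rbind, steers_rows),
    feed = do.call(rbind, feed_rows),
    carcass = do.call(rbind, carcass_rows),
    pens = do.call(rbind, pen_rows),
    config = config, seed = seed
  ), class = "synthetic_study")
}

.write_exact_csv <- function(df, path) {
  out <- df
  for (cl in names(out)) {
    if (is.numeric(out[[cl]]) && !is.integer(out[[cl]])) {
      out[[cl]] <- sprintf("%.17g", out[[cl]])
      out[[cl]][is.na(df[[cl]])] <- NA
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
}

#' Write a synthetic study as the pipeline's CSV input set
#'
#' Writes `steers.csv`, `feed.csv` and `carcass.csv` with full numeric
#' precision, so that re-reading reproduces the generated tables
#' exactly; the byte content is deterministic for a given config and
#' seed.
#'
#' @param study A `synthetic_study` (or a bare list with `steers`,
#'   `feed`, `carcass`).
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("steers.csv", "feed.csv", "carcass.csv"))
  .write_exact_csv(study$steers, paths[1])
  .write_exact_csv(study$feed, paths[2])
  .write_exact_csv(study$carcass, paths[3])
  invisible(paths)
}

#' Read a study written by [write_study()]
#'
#' @param dir Directory containing `steers.csv`, `feed.csv`,
#'   `carcass.csv`.
#' @return List with `steers`, `feed`, `carcass` data.frames.
#' @export
read_study <- function(dir) {
  rd <- function(f, classes) {
    utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE,
                    colClasses = classes, na.strings = c("NA", ""))
  }
  list(
    steers = rd("steers.csv",
                c(steer_id = "character", pen_id = "character",
                  block = "character", treatment = "character",
                  day = "numeric", bw_kg = "numeric",
                  disposition = "character", disposition_day = "numeric")),
    feed = rd("feed.csv",
              c(pen_id = "character", day = "numeric",
                as_fed_kg = "numeric", dm_fraction = "numeric",
                destination = "character", steer_id = "character")),
    carcass = rd("carcass.csv",
                 c(steer_id = "character", hcw_kg = "numeric",
                   rea_cm2 = "numeric", rf_cm = "numeric",
                   kph_pct = "numeric", marbling = "numeric"))
  )
}
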