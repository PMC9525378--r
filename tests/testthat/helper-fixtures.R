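# Shared fixture builders.  All fixtures are constructed in code; the
# tiny pen is small enough to verify every aggregate by hand.

# One pen, two steers, 10 d on feed, flat known weights.  Steer S2 can
# be turned into a removal hospitalised on day 6.
tiny_pen <- function(s2_disposition = "finished", s2_day = NA) {
  mk <- function(id, bw0, bw1, disp, dday) {
    days <- c(0, 5, 10)
    if (disp != "finished") days <- days[days < dday]
    data.frame(steer_id = id, pen_id = "P1", block = "B1",
               treatment = "CON", day = days,
               bw_kg = bw0 + (bw1 - bw0) * days / 10,
               disposition = disp, disposition_day = dday,
               stringsAsFactors = FALSE)
  }
  rbind(mk("S1", 400, 500, "finished", NA),
        mk("S2", 420, 520, s2_disposition, s2_day))
}

# Home deliveries 10 kg as-fed at 0.80 DM on days 1..10 (8 kg DM/d).
tiny_feed <- function(days = 1:10, as_fed = 10, dm = 0.8) {
  data.frame(pen_id = "P1", day = days, as_fed_kg = as_fed,
             dm_fraction = dm, destination = "home",
             steer_id = NA_character_, stringsAsFactors = FALSE)
}

hospital_feed <- function(steer_id, days, dm_kg = 5, dm = 0.8) {
  data.frame(pen_id = "P1", day = days, as_fed_kg = dm_kg / dm,
             dm_fraction = dm, destination = "hospital",
             steer_id = steer_id, stringsAsFactors = FALSE)
}

# Fast-but-complete synthetic configuration for pipeline tests.
small_config <- function(...) {
  synthetic_config(n_blocks = 4, steers_per_pen = 4,
                   days_on_feed = c(60L, 59L), weigh_days = c(14, 42),
                   ...)
}

# Noise-free configuration: every dispersion zero, no removals.
noise_free_config <- function(...) {
  synthetic_config(initial_bw_sd = 0, dmi_cv = 0, adg_residual_sd = 0,
                   steer_adg_sd = 0, weigh_noise_sd = 0, delivery_cv = 0,
                   dm_fraction_sd = 0, dressed_yield_sd = 0,
                   rea = c(intercept = 40, slope = 0.09, sd = 0),
                   rf = c(intercept = -0.5, slope = 0.00275, sd = 0),
                   kph = c(mean = 1.8, sd = 0),
                   marbling = c(mean = 480, sd = 0),
                   removal_probability = 0, hospital_episode_prob = 0,
                   ...)
}

# Balanced RCBD response table with known structure.
rcbd_table <- function(trt_effects = c(A = 0, B = 0, C = 0),
                       block_sd = 1, resid_sd = 0.5, n_blocks = 10,
                       mu = 10) {
  trts <- names(trt_effects)
  d <- expand.grid(treatment = trts,
                   block = sprintf("B%02d", seq_len(n_blocks)),
                   stringsAsFactors = FALSE)
  blk <- stats::rnorm(n_blocks, 0, block_sd)
  names(blk) <- sprintf("B%02d", seq_len(n_blocks))
  d$y <- mu + trt_effects[d$treatment] + blk[d$block] +
    stats::rnorm(nrow(d), 0, resid_sd)
  d
}
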