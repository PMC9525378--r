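# Pen performance cleaning: shrink, carcass adjustment, ADG, DMI with
# hospital-pen crediting, and the deads/removals exclusion.

test_that("shrink is a fixed multiplicative discount", {
  expect_equal(shrink_bw(401, 0.04), 384.96)
  expect_equal(shrink_bw(100, 0), 100)
  expect_equal(shrink_bw(500, 0.04), 480)
  expect_error(shrink_bw(-1), "non-negative")
  expect_error(shrink_bw(100, 1), "\\[0, 1\\)")
})

test_that("carcass adjustment divides HCW by the common yield", {
  expect_equal(carcass_adjusted_final_bw(411, 0.6433), 638.9,
               tolerance = 1e-3)
  expect_equal(carcass_adjusted_final_bw(410, 0.6433), 637.3,
               tolerance = 1e-3)
  expect_equal(carcass_adjusted_final_bw(0.6433, 0.6433), 1)
  # round trip: adjusted BW times the yield restores HCW
  h <- c(350, 411, 470)
  expect_equal(carcass_adjusted_final_bw(h, 0.6433) * 0.6433, h)
  expect_error(carcass_adjusted_final_bw(411, 0), "\\(0, 1\\)")
})

test_that("cumulative ADG matches the fractional-days arithmetic", {
  expect_equal(cumulative_adg(386, 640, 145.5), 1.746, tolerance = 1e-3)
  expect_equal(cumulative_adg(386, 386, 100), 0)
  expect_equal(cumulative_adg(385, 637, 145.5), 1.732, tolerance = 1e-3)
  expect_error(cumulative_adg(386, 640, 0), "positive")
})

test_that("deads and removals are excluded and counts update", {
  d <- data.frame(steer_id = sprintf("S%02d", 1:80),
                  disposition = c(rep("finished", 78), "died", "removed"))
  expect_equal(nrow(exclude_deads_removals(d)), 78)
  expect_equal(nrow(exclude_deads_removals(d[0, , drop = FALSE])), 0)
  d$disposition[1] <- "vanished"
  expect_error(exclude_deads_removals(d), "unknown disposition")
})

test_that("pen DMI divides delivered DM by head-days", {
  # one steer, 10 d, 10 kg as-fed/d at 0.80 DM -> 8.0 kg DM/d
  expect_equal(pen_dmi(tiny_feed(), c(P1 = 10), logical(0)),
               c(P1 = 8))
})

test_that("hospital feed is credited when the steer returns", {
  # steer away days 6-10 but returns: hospital DM stays credited, full
  # head-days; (5 d * 8 DM + 5 d * 5 DM) / 10 head-days = 6.5
  feed <- rbind(tiny_feed(days = 1:5),
                hospital_feed("S2", 6:10, dm_kg = 5))
  dmi <- pen_dmi(feed, c(P1 = 10), c(S2 = TRUE))
  expect_equal(dmi, c(P1 = (5 * 8 + 5 * 5) / 10))
})

test_that("hospital feed is debited back to hospitalisation when not", {
  # steer hospitalised day 6, never returns: hospital feed excluded and
  # its head-days stop at day 5
  feed <- rbind(tiny_feed(days = 1:5),
                hospital_feed("S2", 6:10, dm_kg = 5))
  dmi <- pen_dmi(feed, c(P1 = 5), c(S2 = FALSE))
  expect_equal(dmi, c(P1 = 8))
})

test_that("pen DMI is invariant to splitting a delivery", {
  whole <- tiny_feed()
  halves <- rbind(transform(tiny_feed(), as_fed_kg = as_fed_kg * 0.25),
                  transform(tiny_feed(), as_fed_kg = as_fed_kg * 0.75))
  expect_equal(pen_dmi(whole, c(P1 = 10), logical(0)),
               pen_dmi(halves, c(P1 = 10), logical(0)))
})

test_that("pen DMI validates its references", {
  bad_pen <- transform(tiny_feed(), pen_id = "P9")
  expect_error(pen_dmi(bad_pen, c(P1 = 10), logical(0)), "unknown pen")
  hosp <- hospital_feed("S9", 3)
  expect_error(pen_dmi(hosp, c(P1 = 10), c(S2 = TRUE)),
               "unknown return status")
})

test_that("head-days use date-of-disposition accounting", {
  ss <- steer_summary(tiny_pen(s2_disposition = "removed", s2_day = 6))
  hd <- pen_head_days(ss, c(P1 = 10))
  # finisher 10 d + removed steer through day 5
  expect_equal(hd, c(P1 = 15))
})

test_that("pen_performance assembles consistent pen aggregates", {
  steers <- tiny_pen()
  feed <- tiny_feed()
  # choose HCW so that per-steer dressing is exactly 0.64
  carcass <- data.frame(steer_id = c("S1", "S2"),
                        hcw_kg = 0.64 * 0.96 * c(500, 520))
  perf <- pen_performance(steers, feed, carcass)
  expect_equal(attr(perf, "common_dressed_yield"), 0.64)
  expect_equal(perf$n_head_final, 2)
  expect_equal(perf$days_on_feed, 10)
  expect_equal(perf$initial_shrunk_bw_kg, 0.96 * 410)
  # both dressings equal the common yield, so carcass adjustment
  # restores the shrunk final weights exactly
  expect_equal(perf$carcass_adjusted_final_bw_kg, 0.96 * 510)
  expect_equal(perf$adg_kg_d, (0.96 * 510 - 0.96 * 410) / 10)
  expect_equal(perf$dmi_kg_d, 8 / 2)
  # stored G:F equals recomputed ADG/DMI exactly
  expect_identical(perf$gf, perf$adg_kg_d / perf$dmi_kg_d)
})

test_that("a removal leaves finisher aggregates alone and fixes intake", {
  steers <- tiny_pen(s2_disposition = "died", s2_day = 6)
  feed <- rbind(tiny_feed(), hospital_feed("S2", 6:8, dm_kg = 5))
  carcass <- data.frame(steer_id = "S1", hcw_kg = 0.64 * 0.96 * 500)
  perf <- pen_performance(steers, feed, carcass)
  expect_equal(perf$n_head_final, 1)
  expect_equal(perf$initial_shrunk_bw_kg, 0.96 * 400)
  # 10 d * 8 DM home feed over (10 + 5) head-days; hospital excluded
  expect_equal(perf$dmi_kg_d, 80 / 15)
})

test_that("missing carcass rows for finishers are an error", {
  steers <- tiny_pen()
  carcass <- data.frame(steer_id = "S1", hcw_kg = 300)
  expect_error(pen_performance(steers, tiny_feed(), carcass),
               "missing from `carcass`")
})
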