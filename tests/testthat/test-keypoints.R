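# brute-force cycle oracle: scan every sample triple for peaks, then
# search outward for the tone+tol crossings
oracle_uc_cycles <- function(uc, tone, tol, prom) {
  n <- length(uc)
  res <- list()
  for (p in 2:(n - 1)) {
    if (uc[p] > uc[p - 1] && uc[p] > uc[p + 1] && uc[p] >= tone + prom) {
      s <- p
      while (s > 1 && uc[s] > tone + tol) s <- s - 1
      e <- p
      while (e < n && uc[e] > tone + tol) e <- e + 1
      res[[length(res) + 1L]] <- c(s, p, e)
    }
  }
  res
}

bell <- function(tt, onset, dur, amp) {
  u <- tt - onset
  ifelse(u >= 0 & u <= dur, amp * 0.5 * (1 - cos(2 * pi * u / dur)), 0)
}

test_that("contraction cycles match a brute-force scan on synthetic bells", {
  rate <- 2
  tt <- (0:599) / rate

  # single bell of height 60 over tone 5
  uc <- 5 + bell(tt, 60, 100, 60)
  cyc <- detect_uc_cycles(uc, 5, rate)
  expect_length(cyc, 1)
  orc <- oracle_uc_cycles(uc, 5, 2, 10)[[1]]
  expect_equal(round(cyc[[1]]$ucs$t * rate) + 1, orc[1], tolerance = 1.01)
  expect_equal(round(cyc[[1]]$ucp$t * rate) + 1, orc[2], tolerance = 1.01)
  expect_equal(round(cyc[[1]]$uce$t * rate) + 1, orc[3], tolerance = 1.01)

  # constant channel has no cycles
  expect_length(detect_uc_cycles(rep(5, 600), 5, rate), 0)

  # two bells separated by a return to tone give two disjoint cycles
  uc2 <- 5 + bell(tt, 40, 80, 50) + bell(tt, 180, 80, 55)
  cyc2 <- detect_uc_cycles(uc2, 5, rate)
  expect_length(cyc2, 2)
  expect_lt(cyc2[[1]]$uce$t, cyc2[[2]]$ucs$t + 1e-9)
  orc2 <- oracle_uc_cycles(uc2, 5, 2, 10)
  expect_equal(
    vapply(cyc2, function(cy) cy$ucp$t, numeric(1)),
    vapply(orc2, function(o) tt[o[2]], numeric(1))
  )
})

test_that("overlapping bells are split at the valley between peaks", {
  rate <- 2
  tt <- (0:599) / rate
  uc <- 5 + bell(tt, 50, 100, 60) + bell(tt, 120, 100, 55)
  cyc <- detect_uc_cycles(uc, 5, rate)
  expect_length(cyc, 2)
  # shared boundary at the valley minimum: end of 1 == start of 2
  expect_equal(cyc[[1]]$uce$t, cyc[[2]]$ucs$t)
  valley_t <- tt[which.min(uc[(cyc[[1]]$ucp$t * rate + 1):(cyc[[2]]$ucp$t * rate + 1)]) +
    cyc[[1]]$ucp$t * rate]
  expect_equal(cyc[[1]]$uce$t, valley_t, tolerance = 0.5)
})

test_that("deceleration key points are recovered within tight tolerance", {
  spec <- synth_spec(
    duration_s = 300, uc = uc_bells(60, 100, 60),
    events = list(ev_early_decel(1, depth_bpm = 45, fall_s = 45, lag_s = 10)),
    seed = 5
  )
  sim <- generate_ctg(spec)
  tr <- ctg_clean(sim$trace)
  cfg <- ctg_config()
  fhr_s <- ctg_smooth(tr$fhr, tr$rate, cfg$smooth_window_s)
  uc_s <- ctg_smooth(tr$uc, tr$rate, cfg$smooth_window_s)
  cyc <- detect_uc_cycles(uc_s, 5, tr$rate, cfg)
  expect_length(cyc, 1)
  ep <- extract_decel(fhr_s, cyc[[1]], 140, tr$rate, cfg)
  truth <- sim$truth[[1]]
  expect_false(is.null(ep))
  expect_lt(abs(ep$hrs$t - truth$hrs$t), 1)
  expect_lt(abs(ep$hrp$t - truth$hrp$t), 1)
  expect_lt(abs(ep$hrp$v - truth$hrp$v), 2)
})

test_that("flat heart rate over a cycle yields no episode", {
  rate <- 2
  tt <- (0:599) / rate
  uc <- 5 + bell(tt, 60, 100, 60)
  cyc <- detect_uc_cycles(uc, 5, rate)[[1]]
  expect_null(extract_decel(rep(140, 600), cyc, 140, rate))
})

test_that("a dip entirely before the contraction start is ignored", {
  rate <- 2
  tt <- (0:599) / rate
  uc <- 5 + bell(tt, 150, 100, 60) # cycle starts ~155 s
  fhr <- 140 - 45 * bell(tt, 20, 60, 1) # dip at 20-80 s
  cyc <- detect_uc_cycles(uc, 5, rate)[[1]]
  ep <- extract_decel(fhr, cyc, 140, rate)
  expect_null(ep)
})

test_that("shoulder detection finds overshoots only inside its window", {
  rate <- 2
  spec <- synth_spec(
    duration_s = 300, uc = uc_bells(60, 100, 60),
    events = list(ev_var_decel(1,
      depth_bpm = 30, fall_s = 15, lag_s = 10,
      shoulder_height_bpm = 12, shoulder_duration_s = 15
    )),
    seed = 5
  )
  sim <- generate_ctg(spec)
  cfg <- ctg_config()
  fhr_s <- ctg_smooth(sim$trace$fhr, rate, cfg$smooth_window_s)
  uc_s <- ctg_smooth(sim$trace$uc, rate, cfg$smooth_window_s)
  cyc <- detect_uc_cycles(uc_s, 5, rate, cfg)[[1]]
  ep <- extract_decel(fhr_s, cyc, 140, rate, cfg)
  ep <- detect_shoulder(fhr_s, ep, 140, rate, cfg)
  expect_false(is.null(ep$shoulder))
  expect_equal(ep$shoulder$hsp$v - 140, 12, tolerance = 2)

  # no overshoot -> no shoulder
  spec2 <- synth_spec(
    duration_s = 300, uc = uc_bells(60, 100, 60),
    events = list(ev_var_decel(1, depth_bpm = 30, fall_s = 15, lag_s = 10)),
    seed = 5
  )
  sim2 <- generate_ctg(spec2)
  fhr2 <- ctg_smooth(sim2$trace$fhr, rate, cfg$smooth_window_s)
  ep2 <- extract_decel(fhr2, cyc, 140, rate, cfg)
  ep2 <- detect_shoulder(fhr2, ep2, 140, rate, cfg)
  expect_null(ep2$shoulder)

  # overshoot starting 90 s after recovery is outside the search window
  tt <- (0:599) / rate
  fhr3 <- 140 - 30 * bell(tt, 75, 30, 1)
  fhr3 <- fhr3 + 12 * bell(tt, 105 + 90, 15, 1)
  ep3 <- extract_decel(fhr3, cyc, 140, rate, cfg)
  ep3 <- detect_shoulder(fhr3, ep3, 140, rate, cfg)
  expect_null(ep3$shoulder)
})

test_that("sustained episodes follow the three-minute rule", {
  rate <- 2
  crit <- ctg_criteria()
  # 200 s at 165 bpm flanked by 140: one high episode
  fhr <- c(rep(140, 200), rep(165, 400), rep(140, 200))
  eps <- detect_sustained(fhr, rate, crit)
  expect_length(eps, 1)
  expect_equal(eps[[1]]$kind, "high")
  expect_equal(eps[[1]]$duration_s, 200)
  # 100 s at 165 bpm: too short
  fhr2 <- c(rep(140, 200), rep(165, 200), rep(140, 200))
  expect_length(detect_sustained(fhr2, rate, crit), 0)
  # a 155-bpm plateau is below the tachycardia threshold
  fhr3 <- c(rep(140, 200), rep(155, 500), rep(140, 200))
  expect_length(detect_sustained(fhr3, rate, crit), 0)
  # missing data breaks runs
  fhr4 <- c(rep(165, 300), NA, rep(165, 300))
  expect_length(detect_sustained(fhr4, rate, crit), 0)
})

test_that("sustained detection equals an exhaustive run-length scan", {
  rate <- 2
  crit <- ctg_criteria()
  set.seed(99)
  for (rep_i in 1:200) {
    fhr <- random_step_fhr(1200, rate)
    got <- detect_sustained(fhr, rate, crit)
    want <- oracle_sustained(fhr, rate)
    expect_equal(length(got), length(want))
    for (k in seq_along(got)) {
      expect_equal(got[[k]]$start, want[[k]]$start)
      expect_equal(got[[k]]$end, want[[k]]$end)
      expect_equal(got[[k]]$kind, want[[k]]$kind)
    }
  }
})

test_that("extraction is translation-equivariant", {
  rate <- 2
  tt <- (0:599) / rate
  uc <- 5 + bell(tt, 60, 100, 60)
  fhr <- 140 - 45 * bell(tt, 70, 90, 1)
  k <- 37 # shift by k samples
  uc_sh <- c(rep(5, k), uc)
  fhr_sh <- c(rep(140, k), fhr)

  cyc <- detect_uc_cycles(uc, 5, rate)[[1]]
  cyc_sh <- detect_uc_cycles(uc_sh, 5, rate)[[1]]
  expect_equal(cyc_sh$ucs$t - cyc$ucs$t, k / rate)
  expect_equal(cyc_sh$ucp$t - cyc$ucp$t, k / rate)
  expect_equal(cyc_sh$uce$t - cyc$uce$t, k / rate)

  ep <- extract_decel(fhr, cyc, 140, rate)
  ep_sh <- extract_decel(fhr_sh, cyc_sh, 140, rate)
  expect_equal(ep_sh$hrs$t - ep$hrs$t, k / rate, tolerance = 1e-6)
  expect_equal(ep_sh$hrp$t - ep$hrp$t, k / rate)
  expect_equal(ep_sh$hre$t - ep$hre$t, k / rate)
})

test_that("extracted episodes satisfy their structural invariants", {
  for (cl in c("early", "late", "vara", "varb")) {
    for (s in c(3, 14)) {
      sim <- generate_ctg(random_event_spec(cl, s))
      dx <- ctg_diagnose(sim$trace)
      for (d in dx$decels) {
        e <- d$episode
        expect_lte(e$hrs$t, e$hrp$t)
        expect_lte(e$hrp$t, e$hre$t)
        # nadir minimality: no smoothed sample in [hrs, hre] sits below
        cfg <- dx$config
        sm <- ctg_smooth(ctg_clean(sim$trace, cfg)$fhr, 2, cfg$smooth_window_s)
        idx <- (round(e$hrs$t * 2) + 1):(round(e$hre$t * 2) + 1)
        expect_gte(min(sm[idx], na.rm = TRUE), e$hrp$v - 1e-9)
        if (!is.null(e$shoulder)) {
          expect_gte(e$shoulder$hsp$t, e$hre$t)
          expect_gte(e$shoulder$hse$t, e$shoulder$hsp$t)
        }
        expect_lt(e$cycle$ucs$t, e$cycle$ucp$t)
        expect_lt(e$cycle$ucp$t, e$cycle$uce$t)
      }
    }
  }
})
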