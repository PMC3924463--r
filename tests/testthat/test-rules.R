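test_that("sample counts convert to seconds at the plotting rate", {
  expect_equal(samples_to_seconds(90, 2), 45)
  expect_equal(samples_to_seconds(0, 2), 0)
  expect_equal(samples_to_seconds(10, 2), 5)
  expect_equal(samples_to_seconds(7, 4), 1.75)
  expect_error(samples_to_seconds(10, 0), "rate")
  expect_error(samples_to_seconds(-1, 2), "n must")
})

test_that("the canonical early-deceleration geometry classifies as early only", {
  # nadir before contraction end, 45-s fall, 5-s lag, 45-bpm depth,
  # no shoulder
  ep <- make_episode(
    hrs_t = 105, hrp_t = 150, hre_t = 195, b = 140, hrp_v = 95,
    ucs_t = 100, uce_t = 200
  )
  labs <- classify_decel(ep, ctg_criteria())
  expect_equal(as.character(labs), "EarlyDeceleration")
  r <- attr(labs, "rules")
  # late fails because the nadir precedes the contraction end
  expect_false(r$passed[r$label == "LateDeceleration" &
    r$rule == "nadir_after_uce"])
  # variable A fails because the fall exceeds 30 s
  expect_false(r$passed[r$label == "VariableDecelerationA" &
    r$rule == "fall_time"])
  # variable B fails for want of a shoulder
  expect_false(any(r$passed[r$label == "VariableDecelerationB" &
    r$rule %in% c("shoulder_height", "shoulder_lag")]))
})

test_that("late and V-shaped variable geometries classify as stated", {
  # nadir after the contraction end, 45-s fall, depth 20
  late <- make_episode(
    hrs_t = 160, hrp_t = 205, hre_t = 240, b = 140, hrp_v = 120,
    ucs_t = 100, uce_t = 200
  )
  expect_true("LateDeceleration" %in% classify_decel(late))

  # 20-s fall, 6-s lag, depth 20, no shoulder: variable A exactly
  vara <- make_episode(
    hrs_t = 106, hrp_t = 126, hre_t = 146, b = 140, hrp_v = 120,
    ucs_t = 100, uce_t = 200
  )
  expect_equal(as.character(classify_decel(vara)), "VariableDecelerationA")
})

test_that("episodes without a linked cycle are rejected", {
  ep <- make_episode(105, 150, 195, 140, 95)
  ep$cycle <- NULL
  expect_error(classify_decel(ep), "cycle")
})

test_that("classification agrees with a truth-table oracle over a grid", {
  crit <- ctg_criteria()
  grid <- expand.grid(
    nadir_after = c(-20, 0, 20), # hrp.t - uce.t: before / at / after
    fall = c(20, 30, 45), # vs fall_time_s = 30, incl. boundary
    lag = c(2, 5, 10), # vs uc_lag_s = 5, incl. boundary
    depth = c(10, 15, 25), # vs depth_bpm = 15, incl. boundary
    shoulder = c("none", "low", "ok", "short"),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    ucs_t <- 100
    uce_t <- 200
    hrs_t <- ucs_t + g$lag
    hrp_t <- uce_t + g$nadir_after
    if (hrp_t <= hrs_t) next # unreachable geometry
    hre_t <- hrp_t + 20
    sh <- switch(g$shoulder,
      none = list(hsp_t = NULL, hsp_v = NULL, hse_t = NULL),
      low = list(hsp_t = hre_t + 6, hsp_v = 140 + 5, hse_t = hre_t + 12),
      ok = list(hsp_t = hre_t + 6, hsp_v = 140 + 12, hse_t = hre_t + 15),
      short = list(hsp_t = hre_t + 3, hsp_v = 140 + 12, hse_t = hre_t + 7)
    )
    ep <- make_episode(
      hrs_t = hrs_t, hrp_t = hrp_t, hre_t = hre_t, b = 140,
      hrp_v = 140 - g$depth, ucs_t = ucs_t, uce_t = uce_t,
      hsp_t = sh$hsp_t, hsp_v = sh$hsp_v, hse_t = sh$hse_t
    )
    got <- sort(as.character(classify_decel(ep, crit)))
    want <- sort(oracle_decel_labels(
      hrs_t, hrp_t, hre_t, 140, 140 - g$depth, ucs_t, uce_t,
      hsp_v = sh$hsp_v, hse_t = sh$hse_t, crit = crit
    ))
    expect_equal(got, want, info = paste(unlist(g), collapse = "/"))
  }
})

test_that("labels respond monotonically to threshold changes", {
  set.seed(7)
  for (i in 1:50) {
    fall <- runif(1, 5, 60)
    lag <- runif(1, 0, 15)
    depth <- runif(1, 5, 40)
    hrs_t <- 100 + lag
    hrp_t <- hrs_t + fall
    ep <- make_episode(
      hrs_t = hrs_t, hrp_t = hrp_t, hre_t = hrp_t + 25, b = 140,
      hrp_v = 140 - depth, ucs_t = 100, uce_t = 100 + runif(1, 30, 120)
    )
    base <- classify_decel(ep, ctg_criteria())
    # decreasing depth_bpm never removes a label
    eased <- classify_decel(ep, ctg_criteria(depth_bpm = 5))
    expect_true(all(as.character(base) %in% as.character(eased)))
    # increasing fall_time_s never adds early or late
    strict <- classify_decel(ep, ctg_criteria(fall_time_s = 50))
    added <- setdiff(as.character(strict), as.character(base))
    expect_false(any(added %in% c("EarlyDeceleration", "LateDeceleration")))
  }
})

test_that("early and late are mutually exclusive; determinism holds", {
  set.seed(8)
  for (i in 1:40) {
    ep <- make_episode(
      hrs_t = 100 + runif(1, 0, 20), hrp_t = 150 + runif(1, 0, 80),
      hre_t = 260, b = 140, hrp_v = 140 - runif(1, 5, 40),
      ucs_t = 100, uce_t = 200
    )
    labs <- as.character(classify_decel(ep))
    expect_false(all(c("EarlyDeceleration", "LateDeceleration") %in% labs))
    expect_identical(labs, as.character(classify_decel(ep)))
  }
})

test_that("sustained episodes map to their rate label", {
  hi <- structure(list(
    start = 10, end = 210, duration_s = 200.5, kind = "high",
    extreme_v = 172
  ), class = "sustained_episode")
  lo <- structure(list(
    start = 10, end = 195, duration_s = 185.5, kind = "low",
    extreme_v = 96
  ), class = "sustained_episode")
  expect_equal(as.character(classify_sustained(hi)), "Tachycardia")
  expect_equal(as.character(classify_sustained(lo)), "Bradycardia")
})
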