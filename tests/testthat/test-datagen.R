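# Synthetic-data generator: calibration, censoring, shapes, CSV round trip.

test_that("component calibration hits the design mean exactly", {
  e <- calibrate_component("exponential", target_mean = 0.9)
  expect_equal(e$params$rate, 1 / 0.9, tolerance = 1e-12)
  w <- calibrate_component("weibull", list(shape = 2), 0.9)
  expect_equal(w$params$rate, (gamma(1.5) / 0.9)^2, tolerance = 1e-12)
  expect_equal(mean(rtimes(w, 1e6, seed = 5)), 0.9,
               tolerance = 3 * 0.9 / sqrt(1e6) * 0.6)  # 3 SEs, cv ~ 0.52
  ln <- calibrate_component("lognormal", list(sdlog = 0.8), 0.9)
  expect_equal(ln$params$meanlog, log(0.9) - 0.8^2 / 2, tolerance = 1e-12)
  for (args in list(list("gamma", list(shape = 2)),
                    list("loglogistic", list(shape = 2)),
                    list("gompertz", list(shape = 0.5)),
                    list("gengamma", list(sigma = 0.8, Q = -0.5)))) {
    fp <- calibrate_component(args[[1]], args[[2]], 0.9)
    expect_equal(rmst(fp, Inf), 0.9, tolerance = 1e-6, info = args[[1]])
  }
  expect_error(calibrate_component("loglogistic", list(shape = 0.8), 0.9),
               class = "hazext_calibration_error")
})

test_that("make_dataset applies the administrative censoring design", {
  spec <- scenario_spec("flat", seed = 10)
  d <- make_dataset(spec)
  expect_s3_class(d, "survival_data")
  expect_equal(nrow(d), 400)
  expect_true(all(d$time <= 1))
  expect_true(all(d$time[d$event == 0] == 1))   # censoring only at 1 year
  expect_true(all(d$event %in% 0:1))
  expect_identical(make_dataset(spec)$time, d$time)   # seed-deterministic
  d2 <- make_dataset(scenario_spec("flat", seed = 11))
  expect_false(identical(d2$time, d$time))
  # mixture scenarios draw 200 + 200 from two families
  si <- scenario_spec("increasing", seed = 1)
  expect_equal(si$counts, c(200L, 200L))
  expect_equal(vapply(si$components, function(f) f$family, ""),
               c("weibull", "gamma"))
  su <- scenario_spec("unimodal", seed = 1)
  expect_equal(vapply(su$components, function(f) f$family, ""),
               c("loglogistic", "lognormal"))
})

test_that("latent times of the flat scenario have the design mean", {
  spec <- scenario_spec("flat", n = 200000, seed = 42)
  lat <- make_dataset(spec, censor = FALSE)
  expect_equal(mean(lat$time), 0.9, tolerance = 3 * 0.9 / sqrt(2e5) / 0.9)
  expect_true(all(lat$event == 1))
})

test_that("observed censoring matches the mixtures' analytic P(T > 1)", {
  for (kind in SCENARIO_KINDS) {
    spec1 <- scenario_spec(kind, seed = 1)
    p_cens <- mean(vapply(spec1$components, function(fp) surv(fp, 1),
                          numeric(1)))
    cens <- vapply(1:200, function(s)
      400L - n_events(make_dataset(scenario_spec(kind, seed = s))),
      integer(1))
    tot <- sum(cens); N <- 200 * 400
    z <- (tot - N * p_cens) / sqrt(N * p_cens * (1 - p_cens))
    expect_lt(abs(z), stats::qnorm(0.995), label = paste(kind, "censoring z"))
  }
})

test_that("each kind's components are recovered by their own family at n = 1e5", {
  for (kind in SCENARIO_KINDS) {
    spec <- scenario_spec(kind, n = if (kind == "flat") 1e5 else 2e5,
                          seed = 77)
    lat <- make_dataset(spec, censor = FALSE)
    off <- 0
    for (i in seq_along(spec$components)) {
      comp <- spec$components[[i]]
      idx <- off + seq_len(spec$counts[i]); off <- off + spec$counts[i]
      f <- fit_parametric(survival_data(lat$time[idx], lat$event[idx]),
                          comp$family)
      expect_equal(rmst(f$fp, Inf), 0.9, tolerance = 0.01,
                   info = paste(kind, comp$family))
    }
  }
})

test_that("scenario hazard shapes match their design (smoothed empirical)", {
  shape_stat <- function(kind, seed) {
    d <- make_dataset(scenario_spec(kind, seed = seed))
    sm <- smoothed_hazard(d, bandwidth = 0.125)
    early <- mean(sm$hazard[sm$time < 0.5], na.rm = TRUE)
    late <- mean(sm$hazard[sm$time >= 0.5], na.rm = TRUE)
    c(ratio = late / early,
      peak = sm$time[which.max(sm$hazard)] / max(sm$time))
  }
  seeds <- 1:25
  inc <- vapply(seeds, function(s) shape_stat("increasing", s)["ratio"], 1)
  dec <- vapply(seeds, function(s) shape_stat("decreasing", s)["ratio"], 1)
  flt <- vapply(seeds, function(s) shape_stat("flat", s)["ratio"], 1)
  uni <- vapply(seeds, function(s) shape_stat("unimodal", s)["peak"], 1)
  expect_gt(mean(inc > 1), 0.5)          # majority rule over seeds
  expect_gt(mean(dec < 1), 0.5)
  expect_gt(mean(flt > 0.6 & flt < 1.67), 0.5)
  expect_gt(mean(uni > 0.05 & uni < 0.95), 0.5)  # interior mode
})

test_that("CSV round trip and validation errors", {
  tf <- tempfile(fileext = ".csv")
  writeLines("time,event\n0.5,1\n1.0,0", tf)
  d <- load_dataset(tf)
  expect_equal(nrow(d), 2)
  expect_equal(n_events(d), 1)

  d0 <- make_dataset(scenario_spec("decreasing", seed = 8))
  tf2 <- tempfile(fileext = ".csv")
  write_dataset(d0, tf2)
  d1 <- load_dataset(tf2)
  expect_equal(d1$time, d0$time)
  expect_equal(d1$event, d0$event)

  tf3 <- tempfile(fileext = ".csv")
  writeLines("time,event\n-0.5,1", tf3)
  expect_error(load_dataset(tf3), "row", class = "hazext_validation_error")
  tf4 <- tempfile(fileext = ".csv")
  writeLines("time,event\n0.5,2", tf4)
  expect_error(load_dataset(tf4), class = "hazext_validation_error")
  expect_error(load_dataset(tempfile()), class = "hazext_validation_error")
})

test_that("mis-calibrated components are rejected", {
  bad <- family_params("exponential", rate = 2)   # mean 0.5, not 0.9
  expect_error(scenario_spec("flat", components = list(bad)),
               class = "hazext_calibration_error")
})
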