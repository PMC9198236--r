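test_that("percept_sample has scalar-timing moments", {
  set.seed(11)
  x200 <- percept_sample(200, 0.1, n = 10000)
  expect_lt(abs(mean(x200) - 200), 1)
  expect_lt(abs(sd(x200) - 20), 1)
  # scalar property: SD doubles when the duration doubles
  x400 <- percept_sample(400, 0.1, n = 10000)
  expect_lt(abs(sd(x400) - 40), 2)
  # zero-noise limit: percepts collapse onto the physical duration
  expect_equal(percept_sample(200, 1e-12, n = 5), rep(200, 5),
               tolerance = 1e-9)
  # draws are strictly positive even under absurd noise (truncation)
  set.seed(12)
  expect_true(all(percept_sample(10, 3, n = 2000) > 0))
})

test_that("percept_sample SD grows linearly with duration (slope test)", {
  set.seed(21)
  durs <- c(100, 200, 300, 400, 600)
  sds <- vapply(durs, function(d) sd(percept_sample(d, 0.15, n = 8000)),
                numeric(1))
  fit <- lm(sds ~ durs)
  expect_lt(abs(coef(fit)[["durs"]] - 0.15), 0.01)
  expect_lt(abs(coef(fit)[["(Intercept)"]]), 2)
})

test_that("percept_sample rejects invalid parameters", {
  expect_error(percept_sample(0, 0.1), "positive")
  expect_error(percept_sample(-5, 0.1), "positive")
  expect_error(percept_sample(200, 0), "positive")
  expect_error(percept_sample(200, -0.1), "positive")
})

test_that("respond_2ifc is symmetric on ties and exact in the noiseless limit", {
  obs <- stationary_observer(0.2)
  set.seed(31)
  choices <- replicate(4000, respond_2ifc(200, 200, obs, "empty_200")$choice)
  expect_lt(abs(mean(choices == 1) - 0.5), 0.03)
  # tie correctness is a fair coin
  corr <- replicate(4000, respond_2ifc(200, 200, obs, "empty_200")$correct)
  expect_lt(abs(mean(corr) - 0.5), 0.03)
  # (near-)noiseless lapse-free observer always picks the longer interval
  sharp <- stationary_observer(1e-9)
  for (i in 1:20) {
    expect_equal(respond_2ifc(200, 240, sharp, "empty_200")$choice, 2L)
    expect_true(respond_2ifc(200, 240, sharp, "empty_200")$correct)
    expect_equal(respond_2ifc(240, 200, sharp, "empty_200")$choice, 1L)
  }
  expect_error(respond_2ifc(200, 240, obs, "nope"), "condition")
  expect_error(respond_2ifc(-1, 240, obs, "empty_200"), "positive")
})

test_that("respond_2ifc accuracy matches the closed-form psychometric function", {
  w <- 0.15
  obs <- stationary_observer(w)
  set.seed(41)
  for (delta in c(20, 45, 90)) {
    p_theory <- psychometric_2ifc(delta, 200, w)
    hits <- replicate(4000, {
      # randomise comparison position as the task does
      if (runif(1) < 0.5) {
        respond_2ifc(200 + delta, 200, obs, "empty_200")$correct
      } else {
        respond_2ifc(200, 200 + delta, obs, "empty_200")$correct
      }
    })
    expect_lt(abs(mean(hits) - p_theory), 0.025)
  }
})

test_that("closed-form 2IFC probability agrees with a brute-force percept simulation", {
  set.seed(51)
  for (case in list(c(30, 200, 0.1), c(60, 200, 0.2), c(80, 400, 0.15))) {
    p_mc <- oracle_p2ifc(case[1], case[2], case[3])
    expect_lt(abs(p_mc - psychometric_2ifc(case[1], case[2], case[3])), 0.01)
  }
  # equal-variance textbook case: d / (sigma * sqrt(2)) = 1 gives 0.841
  sigma <- 20
  x1 <- rnorm(50000, 0, sigma)
  x2 <- rnorm(50000, sigma * sqrt(2), sigma)
  expect_lt(abs(mean(x2 > x1) - pnorm(1)), 0.01)
})

test_that("lapses flatten the psychometric function towards chance", {
  w <- 0.1
  obs <- stationary_observer(w, lapse = 0.3)
  set.seed(61)
  # huge delta: a lapse-free observer is at ~1; lapses cap it at 1 - 0.15
  hits <- replicate(3000, respond_2ifc(200, 500, obs, "empty_200")$correct)
  expect_lt(abs(mean(hits) - (1 - 0.3 / 2)), 0.03)
  expect_equal(psychometric_2ifc(1e6, 200, w, lapse_rate = 0.3), 0.85,
               tolerance = 1e-6)
})

test_that("simulated psychometric function is monotone in delta", {
  obs <- stationary_observer(0.2)
  set.seed(71)
  deltas <- c(10, 30, 60, 100, 160)
  acc <- vapply(deltas, function(d) {
    mean(replicate(1500, respond_2ifc(200, 200 + d, obs, "empty_200")$correct))
  }, numeric(1))
  expect_true(all(diff(acc) > -0.03))  # monotone up to Monte-Carlo jitter
  expect_true(all(diff(psychometric_2ifc(deltas, 200, 0.2)) > 0))
})

test_that("wf_trajectory follows the exponential learning law", {
  obs <- default_observer("EI")
  # session 0 returns the starting coefficient exactly
  expect_equal(wf_trajectory(obs, 0, "empty_200"), 0.20)
  # direct evaluation: 0.13 + 0.07 * exp(-2 / 1.5)
  expect_equal(wf_trajectory(obs, 2, "empty_200"),
               0.13 + 0.07 * exp(-2 / 1.5), tolerance = 1e-12)
  # hand-set parameters from the documented formula
  o2 <- observer_params("EI", conditions = list(
    empty_200 = list(wf_start = 0.2, wf_asymptote = 0.1, tau_sessions = 2)))
  expect_equal(wf_trajectory(o2, 2, "empty_200"), 0.1 + 0.1 * exp(-1),
               tolerance = 1e-12)
  # tau -> 0 jumps to the asymptote from session 1 on
  o3 <- observer_params("EI", conditions = list(
    empty_200 = list(wf_start = 0.2, wf_asymptote = 0.1, tau_sessions = 0)))
  expect_equal(wf_trajectory(o3, 0, "empty_200"), 0.2)
  expect_equal(wf_trajectory(o3, 1, "empty_200"), 0.1)
  expect_equal(wf_trajectory(o3, 4, "empty_200"), 0.1)
  # flat conditions stay at wf_start
  expect_equal(wf_trajectory(obs, 5, "empty_400"), 0.20)
  expect_error(wf_trajectory(obs, -1, "empty_200"), ">= 0")
  expect_error(wf_trajectory(obs, 1, "unknown"), "condition")
})

test_that("wf_trajectory is non-increasing over sessions for every condition", {
  for (grp in c("EI", "FI")) {
    obs <- default_observer(grp)
    for (cond in names(obs$conditions)) {
      traj <- vapply(0:5, wf_trajectory, numeric(1),
                     observer = obs, condition = cond)
      expect_true(all(diff(traj) <= 1e-12))
    }
  }
})

test_that("observer_params validates its inputs", {
  good <- list(empty_200 = list(wf_start = 0.2, wf_asymptote = 0.15,
                                tau_sessions = 1))
  expect_s3_class(observer_params("EI", conditions = good),
                  "observer_params")
  expect_error(observer_params("EI", lapse_rate = 0.6, conditions = good),
               "lapse_rate")
  expect_error(observer_params("EI", lapse_rate = -0.1, conditions = good),
               "lapse_rate")
  bad_neg <- list(empty_200 = list(wf_start = -0.2, wf_asymptote = 0.1,
                                   tau_sessions = 1))
  expect_error(observer_params("EI", conditions = bad_neg), "> 0")
  bad_up <- list(empty_200 = list(wf_start = 0.1, wf_asymptote = 0.2,
                                  tau_sessions = 1))
  expect_error(observer_params("EI", conditions = bad_up), "exceed")
  bad_tau <- list(empty_200 = list(wf_start = 0.2, wf_asymptote = 0.1,
                                   tau_sessions = -1))
  expect_error(observer_params("EI", conditions = bad_tau), "tau")
})

test_that("make_cohort is reproducible and structured as configured", {
  c1 <- make_cohort(5, "EI", seed = 7)
  c2 <- make_cohort(5, "EI", seed = 7)
  expect_equal(c1, c2)
  expect_length(c1, 5)
  expect_true(all(vapply(c1, function(o) o$group == "EI", logical(1))))
  # jitter moves wf_start around but keeps the asymptote ratio in
  # improving conditions
  starts <- vapply(c1, function(o) o$conditions$empty_200$wf_start,
                   numeric(1))
  expect_gt(sd(starts), 0)
  ratios <- vapply(c1, function(o) {
    o$conditions$empty_200$wf_asymptote / o$conditions$empty_200$wf_start
  }, numeric(1))
  expect_equal(ratios, rep(0.13 / 0.20, 5), tolerance = 1e-12)
  # FI observers are flat everywhere
  fi <- make_cohort(3, "FI", seed = 8)
  for (o in fi) {
    flat <- vapply(o$conditions,
                   function(cc) cc$wf_asymptote == cc$wf_start, logical(1))
    expect_true(all(flat))
  }
})

test_that("invert_psychometric is the inverse of the psychometric function", {
  for (w in c(0.1, 0.2, 0.3)) {
    d <- invert_psychometric(0.5^(1 / 3), 200, w)
    expect_equal(psychometric_2ifc(d, 200, w), 0.5^(1 / 3),
                 tolerance = 1e-8)
  }
  expect_error(invert_psychometric(0.4, 200, 0.1), "p_target")
  expect_error(invert_psychometric(0.9, 200, 0.1, lapse_rate = 0.5),
               "p_target")
})
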