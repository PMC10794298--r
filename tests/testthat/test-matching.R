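test_that("the x-double-weighted distance evaluates as defined", {
  expect_equal(weighted_distance(3, 4, 3, 4), 0)
  expect_equal(weighted_distance(1, 0, 0, 0), 2)
  expect_equal(weighted_distance(0, 3, 0, 0), 3)
  expect_equal(weighted_distance(1, 2, 0, 0), sqrt(8))
  expect_equal(weighted_distance(1, 0, 0, 0, x_weight = 3), 3)
})

test_that("identical series match each extremum to itself at distance zero", {
  set.seed(81)
  y <- 100 * sin(seq(0, 4 * pi, length.out = 300)) + cumsum(rnorm(300))
  trial <- toy_trial(y)
  ext <- find_local_extrema(y)
  m <- match_extrema(ext, ext, trial$cursor_x, trial$target_x)
  expect_equal(m$cursor_index, ext$index)
  expect_equal(m$target_index, ext$index)
  expect_equal(m$weighted_distance, rep(0, nrow(ext)))
  expect_true(all(m$label == "adaptive"))  # ties are adaptive
  expect_false(any(m$crossed))
})

test_that("matching agrees with exhaustive same-kind nearest neighbor", {
  set.seed(82)
  for (rep in 1:200) {
    n <- sample(60:200, 1)
    ty <- cumsum(rnorm(n, 0, 10))
    cy <- cumsum(rnorm(n, 0, 10))
    tar <- find_local_extrema(ty)
    cur <- find_local_extrema(cy)
    if (!nrow(cur) || !all(unique(cur$kind) %in% tar$kind)) next
    trial <- toy_trial(ty, cy)
    got <- match_extrema(cur, tar, trial$cursor_x, trial$target_x)
    want <- oracle_match(cur, tar, trial$cursor_x, trial$target_x)
    expect_equal(got$target_index, unname(want[, "target"]))
    expect_equal(got$weighted_distance, unname(want[, "dist"]))
    expect_true(all(got$kind == tar$kind[match(got$target_index, tar$index)]))
  }
})

test_that("a cursor extremum without a same-kind target partner is an error", {
  ty <- seq(0, 70, by = 10)                 # monotone target: no extrema
  cy <- c(0, 10, 50, 10, 0, 10, 50, 10)     # prominent cursor peaks
  trial <- toy_trial(ty, cy)
  expect_error(track(trial), "no target")
})

test_that("pure delay and lead are matched to the true counterpart extremum", {
  for (L in c(4, 9)) {
    tr <- seeded_trajectory(83)
    del <- simulate_pursuit(tr, pursuit_model(lag = L, noise_sd = 0))
    fit <- track(del)
    gaps <- fit$matches$cursor_index - fit$matches$target_index
    expect_equal(median(gaps), L)
    expect_true(all(fit$matches$label == "adaptive"))
    lead <- simulate_pursuit(tr, pursuit_model(lag = -L, noise_sd = 0))
    fitl <- track(lead)
    expect_equal(median(fitl$matches$cursor_index - fitl$matches$target_index), -L)
    expect_true(mean(fitl$matches$label == "anticipatory") > 0.9)
  }
})

test_that("every pursuit sample receives an in-window intended sample", {
  set.seed(84)
  for (rep in 1:20) {
    tr <- seeded_trajectory(900 + rep, velocity = sample(1:3, 1))
    trial <- simulate_pursuit(tr, pursuit_model(lag = 6, noise_sd = 4), seed = rep)
    fit <- track(trial)
    a <- fit$assignments
    expect_equal(nrow(a), nrow(trial))             # totality
    expect_true(all(a$intended >= a$window_lo & a$intended <= a$window_hi))
    expect_true(all(a$distance >= 0))
  }
})

test_that("intended-sample assignment agrees with exhaustive minimization", {
  set.seed(85)
  for (rep in 1:100) {
    n <- sample(50:200, 1)
    ty <- 60 * sin(seq(0, runif(1, 2, 5) * pi, length.out = n)) + cumsum(rnorm(n, 0, 3))
    cy <- c(ty[1:3], ty[1:(n - 3)]) + rnorm(n, 0, 2)
    trial <- toy_trial(ty, cy)
    fit <- track(trial, min_prominence = 10)
    a <- fit$assignments
    for (t in sample(n, 12)) {
      want <- oracle_assign_one(trial, t, c(a$window_lo[t], a$window_hi[t]))
      expect_equal(a$intended[t], unname(want["intended"]))
      expect_equal(a$distance[t], unname(want["distance"]))
    }
  }
})

test_that("perfect tracking assigns each sample to itself at distance zero", {
  tr <- seeded_trajectory(86)
  trial <- simulate_pursuit(tr, pursuit_model(lag = 0, noise_sd = 0))
  fit <- track(trial)
  a <- fit$assignments
  expect_equal(a$intended, a$sample)
  expect_equal(a$distance, rep(0, nrow(a)))
  expect_false(any(a$anticipated))               # ties are not anticipated
})

test_that("analysis is invariant under left/right mirroring", {
  cfg <- trajectory_config()
  set.seed(87)
  cf <- list(sample_coefficients(40), NULL, sample_coefficients(40))
  right <- build_trajectory(cfg, velocity = 2, side = "right", coefficients = cf)
  left <- build_trajectory(cfg, velocity = 2, side = "left", coefficients = cf)
  mr <- pursuit_model(lag = 6, noise_sd = 3)
  tr_r <- simulate_pursuit(right, mr, seed = 5)
  tr_l <- simulate_pursuit(left, mr, seed = 5)
  fr <- track(tr_r)
  fl <- track(tr_l)
  expect_equal(fl$spatial, fr$spatial)
  expect_equal(fl$temporal, fr$temporal)
  expect_equal(fl$assignments$anticipated, fr$assignments$anticipated)
  expect_equal(fl$matches$target_index, fr$matches$target_index)
})

test_that("an offset pursuit keeps spatial error within the offset", {
  c0 <- 30
  tr <- seeded_trajectory(88)
  trial <- simulate_pursuit(tr, pursuit_model(lag = 0, noise_sd = 0, offset = c0))
  fit <- track(trial)
  expect_equal(fit$temporal, rep(c0, nrow(trial)))
  expect_true(all(fit$spatial <= c0 + 1e-9))
})
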