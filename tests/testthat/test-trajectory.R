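test_that("waveform evaluation matches hand-computed cases", {
  expect_equal(eval_waveform(c(0, 0, 0), c(0, 0, 0), c(-1, 0, 2.5)), c(0, 0, 0))
  expect_equal(eval_waveform(c(1, 0, 0), c(0, 0, 0), pi / 2), 1)
  # fixed middle-segment amplitudes at phase 0: only the cosines survive
  expect_equal(eval_waveform(c(37, -3, 26), c(23, -15, -9), 0), -1)
  # amplitude bound
  a <- c(12, -30, 5); b <- c(-8, 40, -22)
  ph <- seq(-10, 10, length.out = 2001)
  expect_true(all(abs(eval_waveform(a, b, ph)) <= sum(abs(a)) + sum(abs(b))))
  expect_error(eval_waveform(a, b, c(1, NA)), "finite")
})

test_that("random amplitudes are uniform on [-range, range] and seeded", {
  set.seed(11)
  draws <- replicate(2000, unlist(sample_coefficients(40)))
  expect_true(all(draws >= -40 & draws <= 40))
  expect_gt(min(draws), -40.0001)
  # uniformity: Kolmogorov-Smirnov against U(-40, 40) on a large sample
  set.seed(12)
  big <- unlist(replicate(4000, sample_coefficients(40)))
  expect_gt(suppressWarnings(ks.test(big, "punif", -40, 40)$p.value), 0.01)
  expect_gt(max(big), 39.5)
  expect_lt(min(big), -39.5)
  set.seed(5); c1 <- sample_coefficients(40)
  set.seed(5); c2 <- sample_coefficients(40)
  expect_identical(c1, c2)
})

test_that("constant-speed resampling has uniform spacing and lies on the polyline", {
  # straight horizontal line: closed form
  r <- resample_constant_speed(seq(0, 100, by = 1), rep(0, 101), 10)
  expect_equal(nrow(r), 11)
  expect_equal(diff(r$x), rep(10, 10))
  expect_equal(r$y, rep(0, 11))
  # doubling the speed halves the point count (within a couple of points)
  x <- seq(0, 400, by = 0.5); y <- 30 * sin(x / 25)
  n1 <- nrow(resample_constant_speed(x, y, 2))
  n2 <- nrow(resample_constant_speed(x, y, 4))
  expect_lte(abs(n1 - 2 * n2), 3)
  # spacing uniform within 0.5% across seeded trials
  for (seed in 1:10) {
    tr <- seeded_trajectory(seed, velocity = sample(1:3, 1))
    d <- sqrt(diff(tr$x)^2 + diff(tr$y)^2)
    expect_lt(sd(d) / mean(d), 0.005)
  }
  # degenerate: speed beyond the total arc length
  expect_warning(r <- resample_constant_speed(c(0, 1), c(0, 0), 10), "degenerate")
  expect_equal(nrow(r), 2)
})

test_that("trial trajectories satisfy the generator contract", {
  cfg <- trajectory_config()
  for (seed in 1:5) {
    set.seed(seed)
    tr <- build_trajectory(cfg, velocity = 2)
    expect_true(all(diff(tr$x) > 0))                       # strictly rightward
    expect_equal(tr$x[1], 0)                               # starts at center x
    expect_equal(tr$y[1], 0, tolerance = 1e-6)             # and at center y
    expect_true(all(abs(tr$y) <= 240 + 1e-9))              # amplitude bound
    expect_true(all(abs(tr$y) <= cfg$screen_size[2] / 2))  # on screen
    expect_setequal(unique(tr$segment),
                    c("random1", "gap", "constant", "random2"))
  }
})

test_that("the middle segment is identical across trials of one velocity level", {
  cfg <- trajectory_config()
  set.seed(21); t1 <- build_trajectory(cfg, velocity = 3)
  set.seed(22); t2 <- build_trajectory(cfg, velocity = 3)
  set.seed(23); t3 <- build_trajectory(cfg, velocity = 3, side = "left")
  c1 <- t1[t1$segment == "constant", c("x", "y")]
  c2 <- t2[t2$segment == "constant", c("x", "y")]
  c3 <- t3[t3$segment == "constant", c("x", "y")]
  expect_identical(c1$y, c2$y)
  expect_identical(c1$x, c2$x)
  expect_identical(c1$y, c3$y)
  expect_identical(c1$x, -c3$x)          # mirrored x
  # random segments do differ
  expect_false(identical(t1$y[t1$segment == "random1"],
                         t2$y[t2$segment == "random1"]))
})

test_that("spline bridges are continuous and gapless concatenation works", {
  cfg <- trajectory_config()
  worst_ratio <- 0
  for (seed in 1:100) {
    set.seed(seed)
    cf <- list(sample_coefficients(40), NULL, sample_coefficients(40))
    dense <- pursuittrack:::dense_trajectory(cfg, {
      cf[[2]] <- cfg$fixed_middle; cf
    })
    d <- abs(diff(dense$y))
    seg_steps <- d[dense$segment[-1] != "gap" & dense$segment[-nrow(dense)] != "gap"]
    bridge_steps <- d[dense$segment[-1] == "gap" | dense$segment[-nrow(dense)] == "gap"]
    worst_ratio <- max(worst_ratio, max(bridge_steps) / max(seg_steps))
  }
  # bridges are on the scale of the waveform's own steps: no jumps. A bridge
  # connecting segment endpoints that happen to lie far apart is necessarily
  # somewhat steeper than the waveform, but never by half again as much.
  expect_lt(worst_ratio, 1.5)
  # gap_length 0: three segments joined directly at full dense length
  cfg0 <- trajectory_config(gap_length = 0)
  set.seed(2)
  cf <- list(sample_coefficients(40), cfg0$fixed_middle, sample_coefficients(40))
  dense0 <- pursuittrack:::dense_trajectory(cfg0, cf)
  expect_equal(nrow(dense0), 3 * cfg0$samples_per_segment)
  expect_false("gap" %in% dense0$segment)
})

test_that("mirroring is an involution and flips direction", {
  tr <- seeded_trajectory(31, side = "left")
  expect_true(all(diff(tr$x) < 0))
  back <- mirror_trajectory(mirror_trajectory(tr))
  expect_identical(back$x, tr$x)
  expect_identical(attr(back, "side"), "left")
})

test_that("sessions are counterbalanced, seeded and sized as configured", {
  cfg <- trajectory_config(seed = 4)
  s1 <- generate_session(cfg)
  expect_length(s1, 72)
  cond <- attr(s1, "conditions")
  expect_equal(unname(table(cond$velocity, cond$side)),
               matrix(12L, 3, 2), ignore_attr = TRUE)
  s2 <- generate_session(cfg)
  expect_identical(lapply(s1, function(t) t$y), lapply(s2, function(t) t$y))
  expect_identical(attr(s1, "conditions"), attr(s2, "conditions"))
  # minimal grid
  s3 <- generate_session(trajectory_config(n_repeats_per_condition = 1, seed = 1))
  expect_length(s3, 6)
  cond3 <- attr(s3, "conditions")
  expect_equal(nrow(unique(cond3[c("velocity", "side")])), 6)
  # every trial starts at the screen center
  expect_true(all(vapply(s3, function(t) abs(t$y[1]) < 1e-6 && t$x[1] == 0,
                         logical(1))))
})
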