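test_that("lag-1 MSD averages single-frame squared displacements", {
  # five localizations stepping +0.2 um in x per frame
  x <- seq(0, by = 0.2, length.out = 5)
  expect_equal(one_step_msd(x, rep(0, 5), 1:5), 0.04)
  # stationary track
  expect_equal(one_step_msd(rep(1, 4), rep(2, 4), 1:4), 0)
  # gap-spanning steps are excluded
  x2 <- c(0, 0.2, 0.6, 0.8)      # frames 1,2,4,5; the 2->4 jump is 0.4
  expect_equal(one_step_msd(x2, rep(0, 4), c(1, 2, 4, 5)), 0.04)
  expect_error(one_step_msd(c(0, 1), c(0, 0), c(1, 3)),
               "no single-frame steps")
})

test_that("D = MSD/(4 dt) and the bound threshold is inclusive", {
  expect_equal(apparent_d(0.04, 0.02), 0.5)
  expect_equal(apparent_d(0, 0.02), 0)
  expect_equal(apparent_d(0.024, 0.02), 0.3)
  expect_error(apparent_d(0.04, 0))

  expect_identical(classify_track(0.3), "bound")
  expect_identical(classify_track(0.3000001), "mobile")
  expect_identical(classify_track(0), "bound")
  expect_error(classify_track(-0.1))

  expect_equal(bound_fraction(c("bound", "bound", "mobile", "mobile",
                                "mobile")), 0.4)
  expect_equal(bound_fraction(rep("bound", 3)), 1.0)
  expect_error(bound_fraction(character(0)))
})

test_that("diffusion histogram is normalized with an overflow bin", {
  h1 <- d_histogram(0.37)
  expect_equal(sum(h1$mass), 1)
  expect_equal(h1$mass[h1$lower <= 0.37 & h1$upper > 0.37], 1)

  h2 <- d_histogram(runif(100, 0.52, 0.549), seq(0, 2, 0.05))
  expect_equal(h2$mass[h2$lower == 0.5], 1)

  h3 <- d_histogram(c(0.1, 5), seq(0, 2, 0.05))
  expect_equal(h3$mass[is.infinite(h3$upper)], 0.5)
  expect_error(d_histogram(numeric(0)))
  expect_error(d_histogram(0.5, c(0, 0, 1)))
})

test_that("ground-truth Brownian tracks calibrate the estimator", {
  # 10,000 noise-free tracks: mean msd = 4 d dt; msd*2n/(4 d dt) ~ chi2_2n
  n_tracks <- 10000L; n_steps <- 10; d <- 0.5; dt <- 0.02
  cfg <- spt_sim_config(n_frames = n_steps + 1, image_size = 256,
                        n_molecules = n_tracks, f_bound = 0,
                        d_mobile = d, frame_interval = dt,
                        k_off_frame = 0, k_on_frame = 1, seed = 101)
  traj <- simulate_trajectories(cfg)
  tracks <- truth_to_tracks(traj, loc_sigma = 0)
  res <- spt_diffusion(tracks, frame_interval = dt)
  expect_identical(res$n_tracks, n_tracks)
  expect_true(all(res$per_track$n_steps == n_steps))
  # per-track msd ~ (4 d dt/2n) chi2_2n: mean 4 d dt, var (4 d dt)^2/n
  m <- mean(res$per_track$msd_um2)
  se <- (4 * d * dt) / sqrt(n_steps * n_tracks)
  expect_lt(abs(m - 4 * d * dt), 3 * se)
  # distributional check at the track level
  z <- res$per_track$msd_um2 * 2 * n_steps / (4 * d * dt)
  ks <- suppressWarnings(ks.test(z, "pchisq", df = 2 * n_steps))
  expect_gt(ks$p.value, 0.01)
})

test_that("localization error inflates apparent D by sigma^2/dt", {
  n_tracks <- 8000; n_steps <- 15; d <- 0.3; dt <- 0.02; sig <- 0.04
  cfg <- spt_sim_config(n_frames = n_steps + 1, image_size = 256,
                        n_molecules = n_tracks, f_bound = 0,
                        d_mobile = d, frame_interval = dt,
                        k_off_frame = 0, k_on_frame = 1, seed = 202)
  tracks <- truth_to_tracks(simulate_trajectories(cfg), loc_sigma = sig,
                            seed = 203)
  res <- spt_diffusion(tracks, frame_interval = dt)
  d_eff <- d + sig^2 / dt
  se <- d_eff / sqrt(n_steps * n_tracks)
  expect_lt(abs(mean(res$per_track$d_app) - d_eff), 4 * se)
})

test_that("bound fraction is invariant to relabeling and unit round-trips", {
  cfg <- spt_sim_config(n_frames = 12, image_size = 64,
                        n_molecules = 400, f_bound = 0.4,
                        k_off_frame = 0, k_on_frame = 1, seed = 55)
  tracks <- truth_to_tracks(simulate_trajectories(cfg))
  res <- spt_diffusion(tracks, 0.02)

  perm <- tracks
  relab <- sample(max(tracks$track_id))
  perm$track_id <- relab[perm$track_id]
  perm <- perm[order(perm$track_id, perm$frame), ]
  expect_equal(spt_diffusion(perm, 0.02)$bound_fraction,
               res$bound_fraction)

  px <- 0.096
  rt <- tracks
  rt$x_um <- (rt$x_um / px) * px
  rt$y_um <- (rt$y_um / px) * px
  expect_equal(spt_diffusion(rt, 0.02)$bound_fraction,
               res$bound_fraction)
})

test_that("mixture classification matches the chi-square closed form", {
  n_tracks <- 6000; n_steps <- 8; dt <- 0.02
  cfg <- spt_sim_config(n_frames = n_steps + 1, image_size = 256,
                        n_molecules = n_tracks, f_bound = 0.4,
                        d_bound = 0.02, d_mobile = 0.5,
                        frame_interval = dt, k_off_frame = 0,
                        k_on_frame = 1, seed = 77)
  tracks <- truth_to_tracks(simulate_trajectories(cfg), loc_sigma = 0.03,
                            seed = 78)
  res <- spt_diffusion(tracks, dt)
  expected <- expected_bound_fraction(0.4, 0.02, 0.5, n_steps, dt,
                                      loc_sigma = 0.03)
  se <- sqrt(expected * (1 - expected) / n_tracks)
  expect_lt(abs(res$bound_fraction - expected), 4 * se)
})

test_that("one-way ANOVA on per-cell fractions matches the textbook formula", {
  # identical values in every cell: no variance at all
  r0 <- compare_conditions(list(a = c(0.3, 0.3), b = c(0.3, 0.3)))
  expect_equal(r0$F, 0)
  expect_equal(r0$p_value, 1)

  # perfectly separated conditions
  r1 <- compare_conditions(list(a = c(0.2, 0.2, 0.2),
                                b = c(0.5, 0.5, 0.5)))
  expect_lt(r1$p_value, 1e-6)

  # hand-computed F for jittered groups
  a <- c(0.18, 0.22, 0.20); b <- c(0.48, 0.55, 0.47)
  gm <- mean(c(a, b))
  ssb <- 3 * (mean(a) - gm)^2 + 3 * (mean(b) - gm)^2
  ssw <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
  f_hand <- (ssb / 1) / (ssw / 4)
  r2 <- compare_conditions(list(a = a, b = b))
  expect_equal(r2$F, f_hand, tolerance = 1e-12)
  expect_equal(r2$p_value, pf(f_hand, 1, 4, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(r2$per_condition$mean, c(mean(a), mean(b)))
  expect_equal(r2$per_condition$sd, c(sd(a), sd(b)))

  expect_error(compare_conditions(list(a = c(0.1, 0.2))))
  expect_error(compare_conditions(list(a = c(0.1, 0.2), b = 0.3)),
               "fewer than 2 cells")
})

test_that("ANOVA type-I error rate is nominal under the null", {
  set.seed(909)
  n_rej <- 0; B <- 1000
  for (i in seq_len(B)) {
    g <- list(a = rnorm(3, 0.3, 0.05), b = rnorm(3, 0.3, 0.05),
              c = rnorm(3, 0.3, 0.05))
    if (compare_conditions(g)$p_value <= 0.05) n_rej <- n_rej + 1
  }
  ci <- qbinom(c(0.0005, 0.9995), B, 0.05)
  expect_gte(n_rej, ci[1])
  expect_lte(n_rej, ci[2])
})
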