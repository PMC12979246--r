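test_that("config validation enforces the motion-model invariants", {
  expect_s3_class(spt_sim_config(n_frames = 10, image_size = 32,
                                 n_molecules = 2), "spt_sim_config")
  expect_error(spt_sim_config(d_mobile = 0.1, d_bound = 0.2))
  expect_error(spt_sim_config(f_bound = 1.2))
  expect_error(spt_sim_config(k_off_frame = -0.1))
  expect_error(spt_sim_config(image_size = 16,
                              nucleus_mask = matrix(FALSE, 16, 16)),
               "nucleus_mask")
  expect_error(spt_sim_config(image_size = 16,
                              nucleus_mask = matrix(TRUE, 8, 8)))
})

test_that("per-axis steps of mobile molecules have sd sqrt(2 D dt)", {
  cfg <- spt_sim_config(n_frames = 2000, image_size = 256,
                        n_molecules = 40, f_bound = 0, d_mobile = 0.5,
                        frame_interval = 0.02, seed = 11)
  traj <- simulate_trajectories(cfg)
  expect_true(all(traj$state == "mobile"))
  dx <- unlist(tapply(traj$x_um, traj$molecule_id, diff))
  # reflections at the disk boundary are rare at this density
  expect_equal(sd(dx), sqrt(2 * 0.5 * 0.02), tolerance = 0.02)
  # ensemble one-frame MSD = 4 D dt within a chi-square-scale CI
  dy <- unlist(tapply(traj$y_um, traj$molecule_id, diff))
  msd1 <- mean(dx^2 + dy^2)
  se <- sqrt(2 / length(dx)) * 4 * 0.5 * 0.02  # var(chi2_2)/2n scale
  expect_lt(abs(msd1 - 4 * 0.5 * 0.02), 3 * se)
})

test_that("bound-state assignment is binomial in f_bound", {
  cfg <- spt_sim_config(n_frames = 2, image_size = 64,
                        n_molecules = 10000, f_bound = 0.4, seed = 3)
  traj <- simulate_trajectories(cfg)
  lab <- tapply(traj$state, traj$molecule_id, `[`, 1)
  frac <- mean(lab == "bound")
  se <- sqrt(0.4 * 0.6 / 10000)
  expect_lt(abs(frac - 0.4), 3 * se)
  cfg1 <- spt_sim_config(n_frames = 2, image_size = 64,
                         n_molecules = 50, f_bound = 1, seed = 4)
  expect_true(all(simulate_trajectories(cfg1)$state == "bound"))
})

test_that("trajectories stay inside the nucleus mask", {
  cfg <- spt_sim_config(n_frames = 300, image_size = 48, n_molecules = 25,
                        f_bound = 0.2, d_mobile = 2, seed = 5)
  traj <- simulate_trajectories(cfg)
  inside <- sptrack:::inside_mask(traj$x_um, traj$y_um,
                                  cfg$nucleus_mask, cfg$pixel_size)
  expect_true(all(inside))
})

test_that("blinking duty cycle approaches k_on/(k_on + k_off)", {
  cfg <- spt_sim_config(n_frames = 4000, image_size = 32,
                        n_molecules = 60, f_bound = 1,
                        k_off_frame = 0.1, k_on_frame = 0.3, seed = 8)
  traj <- simulate_trajectories(cfg)
  duty <- mean(traj$emitting)
  # conservative MC bound (frames are serially correlated)
  expect_lt(abs(duty - 0.3 / 0.4), 0.02)
})

test_that("rendering follows the Poisson photon model", {
  cfg0 <- spt_sim_config(n_frames = 5, image_size = 32, n_molecules = 0,
                         background = 0, seed = 1)
  mv0 <- render_movie(simulate_trajectories(cfg0), cfg0)
  expect_true(all(vapply(mv0$frames, max, numeric(1)) == 0))

  # one static emitter: frame sums ~ Poisson(photons_per_spot)
  n_fr <- 200
  expect_error(spt_sim_config(d_bound = 0, d_mobile = 0))
  cfg1 <- spt_sim_config(n_frames = n_fr, image_size = 32,
                         n_molecules = 1, f_bound = 1, d_bound = 1e-6,
                         photons_per_spot = 5000, background = 0,
                         k_off_frame = 0, k_on_frame = 1, seed = 2)
  mv1 <- render_movie(simulate_trajectories(cfg1), cfg1)
  sums <- vapply(mv1$frames, sum, numeric(1))
  expect_lt(abs(mean(sums) - 5000), 3 * sqrt(5000 / n_fr))
  expect_lt(abs(var(sums) - 5000), 0.2 * 5000)

  # emitter with its center off the image edge: truncated tail only
  cfg2 <- spt_sim_config(n_frames = 1, image_size = 16, n_molecules = 1,
                         photons_per_spot = 1000, background = 0,
                         k_off_frame = 0, k_on_frame = 1, seed = 3)
  traj2 <- simulate_trajectories(cfg2)
  traj2$x_um <- -0.05  # just off the left edge
  mv2 <- render_movie(traj2, cfg2)
  s <- sum(mv2$frames[[1]])
  expect_true(s > 0 && s < 1000)
  expect_true(all(mv2$frames[[1]] >= 0))
})

test_that("identical seeds give bit-identical movies, different seeds differ", {
  cfg <- spt_sim_config(n_frames = 10, image_size = 32, n_molecules = 5,
                        seed = 42)
  m1 <- render_movie(simulate_trajectories(cfg), cfg)
  m2 <- render_movie(simulate_trajectories(cfg), cfg)
  expect_identical(m1$frames, m2$frames)
  cfg2 <- spt_sim_config(n_frames = 10, image_size = 32, n_molecules = 5,
                         seed = 43)
  m3 <- render_movie(simulate_trajectories(cfg2), cfg2)
  expect_false(identical(m1$frames, m3$frames))
})

test_that("truth_to_tracks drops dark frames and flags 1-frame gaps", {
  cfg <- spt_sim_config(n_frames = 50, image_size = 32, n_molecules = 10,
                        k_off_frame = 0.2, k_on_frame = 0.5, seed = 9)
  traj <- simulate_trajectories(cfg)
  tr <- truth_to_tracks(traj, loc_sigma = 0, seed = 1)
  expect_identical(nrow(tr), sum(traj$emitting))
  expect_true(all(tr$gap_flag == (c(NA, diff(tr$frame)) == 2 &
                                    c(NA, diff(tr$track_id)) == 0),
                  na.rm = TRUE))
  expect_false(tr$gap_flag[1])
})

test_that("stripe simulator matches its closed-form recruitment curve", {
  cfg <- stripe_sim_config(n_timepoints = 8, image_size = 64,
                           recruitment_amplitude = 0, seed = 1)
  sim <- simulate_stripe_series(cfg)
  expect_equal(sim$truth$sx_true, rep(1, 8))

  cfg2 <- stripe_sim_config(n_timepoints = 500, image_size = 64,
                            recruitment_amplitude = 1,
                            recruitment_rate = 1, nucleus_baseline = 1,
                            background_level = 0, noise_sd = 0, seed = 1)
  sim2 <- simulate_stripe_series(cfg2)
  # t -> Inf: stripe mean -> baseline + amplitude
  expect_equal(sim2$truth$stripe_mean[500], 1 + 1, tolerance = 1e-6)
  # first post-irradiation timepoint: Sx = (1 + (1 - e^-1))/1
  expect_equal(sim2$truth$sx_true[2], 1 + (1 - exp(-1)),
               tolerance = 1e-12)
})

test_that("stripe config rejects inconsistent masks and timing", {
  expect_error(stripe_sim_config(n_timepoints = 5, image_size = 32,
                                 pre_irradiation_timepoints = 5),
               "pre_irradiation")
  nuc <- disk_mask(32)
  bad_stripe <- matrix(TRUE, 32, 32)
  expect_error(stripe_sim_config(image_size = 32, nucleus_region = nuc,
                                 stripe_region = bad_stripe),
               "inside nucleus")
  expect_error(stripe_sim_config(image_size = 32,
                                 background_region = nuc,
                                 nucleus_region = nuc),
               "overlap")
})
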