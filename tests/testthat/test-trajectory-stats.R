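test_that("MSD matches hand values and the all-pairs oracle", {
  trk <- tibble::tibble(track_id = "h", time_min = 0:2,
                        x_um = c(0, 1, 1), y_um = c(0, 0, 1))
  m <- msd(trk, max_lag = 2)
  expect_equal(m$msd, c(1, 2))
  expect_equal(m$n_pairs, c(2, 1))

  set.seed(21)
  x <- cumsum(rnorm(80)); y <- cumsum(rnorm(80))
  trk2 <- tibble::tibble(track_id = "r", time_min = 0:79, x_um = x, y_um = y)
  m2 <- msd(trk2, max_lag = 40)
  expect_equal(m2$msd, oracle_msd(x, y, 40))

  # stationary -> all zeros
  expect_true(all(msd(fixture_track("stationary", duration = 30),
                      max_lag = 10)$msd == 0))
  expect_error(msd(trk, max_lag = 5), class = "modewalk_range_error")
})

test_that("fit_alpha recovers exact power laws and the ballistic limit", {
  synth <- tibble::tibble(track_id = "p", lag_min = 1:30,
                          msd = 4 * (1:30)^1.5, n_pairs = 30:1)
  class(synth) <- c("msd_tbl", class(synth))
  expect_equal(fit_alpha(synth, c(1, 30))$alpha, 1.5, tolerance = 1e-9)

  ball <- fixture_track("ballistic", speed = 2, duration = 60)
  expect_equal(fit_alpha(msd(ball, max_lag = 30), c(1, 30))$alpha, 2,
               tolerance = 1e-9)
})

test_that("ensemble Brownian MSD has unit slope", {
  pool <- purrr::map(1:200, function(k) {
    fixture_track("brownian", sigma = 1, duration = 300, seed = k,
                  track_id = paste0("bm", k))
  }) |> purrr::list_rbind()
  alpha <- fit_alpha(ensemble_msd(msd(pool, max_lag = 30)),
                     fit_lags = c(2, 30))$alpha
  expect_equal(alpha, 1, tolerance = 0.1)
})

test_that("per-segment alpha distribution reflects pool composition", {
  balls <- purrr::map(1:5, function(k) {
    fixture_track("ballistic", speed = k, duration = 60,
                  track_id = paste0("b", k))
  }) |> purrr::list_rbind()
  ad <- alpha_distribution(balls, fit_lags = c(1, 30))
  expect_equal(ad$alpha, rep(2, 5), tolerance = 1e-9)
  expect_equal(unname(attr(ad, "summary")[["50%"]]), 2, tolerance = 1e-9)

  one <- alpha_distribution(dplyr::filter(balls, track_id == "b1"),
                            fit_lags = c(1, 30))
  expect_equal(nrow(one), 1)
})

test_that("displacement PDF normalizes and matches known shapes", {
  pool <- purrr::map(1:50, function(k) {
    fixture_track("brownian", sigma = 1, duration = 100, seed = 100 + k,
                  track_id = paste0("bm", k))
  }) |> purrr::list_rbind()
  pdf <- displacement_pdf(pool, lag = 4)
  widths <- pdf$bin_hi - pdf$bin_lo
  expect_equal(sum(pdf$density * widths), 1, tolerance = 1e-6)
  # Brownian displacements are Gaussian: excess kurtosis ~ 0
  dx <- with(dplyr::group_by(pool, track_id), NULL)
  disp <- pool |>
    dplyr::group_by(track_id) |>
    dplyr::reframe(dx = tail(x_um, -4) - head(x_um, -4))
  kurt <- mean((disp$dx - mean(disp$dx))^4) / var(disp$dx)^2 - 3
  expect_equal(kurt, 0, tolerance = 0.3)

  # ballistic track along a heading: all x-displacements equal v dt cos(h)
  ball <- fixture_track("ballistic", speed = 2, heading = pi / 3,
                        duration = 60)
  pb <- displacement_pdf(ball, lag = 5, breaks = 5)
  expect_equal(sum(pb$count > 0), 1)
})

test_that("turning-angle heatmap columns are normalized with modes at the expected angles", {
  fp_pool <- purrr::map(1:50, function(k) {
    simulate_mode_segment(default_mode_params()$FP, 60, seed = k,
                          track_id = paste0("fp", k))
  }) |> purrr::list_rbind()
  sd_pool <- purrr::map(1:50, function(k) {
    simulate_mode_segment(default_mode_params()$SD, 60, seed = k,
                          track_id = paste0("sd", k))
  }) |> purrr::list_rbind()
  hm_fp <- turning_angle_heatmap(fp_pool, lags = c(1, 3, 5))
  sums <- dplyr::summarise(dplyr::group_by(hm_fp, lag_min),
                           s = sum(prob))$s
  expect_equal(sums, rep(1, 3))
  # persistent pool: modal angle at 0 for all lags
  modal <- hm_fp |>
    dplyr::group_by(lag_min) |>
    dplyr::slice_max(prob, n = 1)
  expect_true(all(abs(modal$theta_mid) < 0.35))
  # anti-persistent pool: modal angle near +-pi for lags > 3 min
  hm_sd <- turning_angle_heatmap(sd_pool, lags = c(5, 7))
  modal_sd <- hm_sd |>
    dplyr::group_by(lag_min) |>
    dplyr::slice_max(prob, n = 1)
  expect_true(all(abs(modal_sd$theta_mid) > pi - 0.6))
})

test_that("phase space series follow hand constructions", {
  # constant speed track -> all radial rates 0
  ball <- fixture_track("ballistic", speed = 2, duration = 30)
  ps <- phase_space(ball, lag = 3)
  expect_true(all(ps$v_radial == 0))
  expect_true(all(ps$delta_theta == 0))

  # constant-turn circular track: theta_n constant -> delta_theta 0
  circ <- fixture_track("circle", radius = 10, n_points = 60)
  psc <- phase_space(circ, lag = 1)
  expect_equal(psc$delta_theta, rep(0, nrow(psc)), tolerance = 1e-9)

  # alternating +-pi/2 zigzag at lag 1: delta_theta alternates +-pi
  zz <- fixture_track("zigzag", turn = pi / 2, duration = 20)
  psz <- phase_space(zz, lag = 1)
  expect_true(all(abs(abs(psz$delta_theta) - pi) < 1e-9))
  # and successive angles sit on the opposite-sign diagonal
  sa <- successive_angles(zz, lag = 1)
  expect_true(all(sign(sa$theta) == -sign(sa$theta_next)))
  q <- attr(sa, "quadrant_counts")
  expect_equal(unname(q[["pp"]] + q[["nn"]]), 0)
})

test_that("pair counts and angle counts are conserved", {
  trk <- fixture_track("brownian", sigma = 2, duration = 59, seed = 3)
  th <- turning_angles(trk$x_um, trk$y_um, lag = 1)
  sa <- successive_angles(trk, lag = 1)
  expect_equal(nrow(sa), length(th) - 1)
})

test_that("zigzag fraction separates turning styles", {
  # constant-sign turner (circle) -> 0
  circ <- fixture_track("circle", radius = 10, n_points = 60)
  expect_equal(zigzag_fraction(circ, lag = 1)$zigzag_fraction, 0)
  # perfect alternator -> no same-sign pairs -> Inf
  zz <- fixture_track("zigzag", turn = pi / 2, duration = 30)
  expect_equal(zigzag_fraction(zz, lag = 1)$zigzag_fraction, Inf)
  # rotation invariance; reflection preserves the ratio
  trk <- simulate_mode_segment(default_mode_params()$SP, 60, seed = 2)
  z0 <- zigzag_fraction(trk, lag = 3)$zigzag_fraction
  expect_equal(zigzag_fraction(rotate_track(trk, 1.1),
                               lag = 3)$zigzag_fraction, z0)
  refl <- dplyr::mutate(trk, x_um = -x_um)
  expect_equal(zigzag_fraction(refl, lag = 3)$zigzag_fraction, z0)
})

test_that("angle statistics are invariant under global rotation", {
  trk <- simulate_mode_segment(default_mode_params()$SD, 60, seed = 8)
  rot <- rotate_track(trk, 0.7)
  expect_equal(turning_angles(rot$x_um, rot$y_um),
               turning_angles(trk$x_um, trk$y_um), tolerance = 1e-9)
  hm0 <- turning_angle_heatmap(trk, lags = c(2, 4))
  hm1 <- turning_angle_heatmap(rot, lags = c(2, 4))
  expect_equal(hm1$count, hm0$count)
})
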