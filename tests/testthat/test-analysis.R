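# Population analyses: plane fits, metrics, main-sequence and relations.

test_that("plane fit: exact plane, width conversion, degenerate input", {
  R0 <- cbind(rx = numeric(50), ry = runif(50, -0.3, 0.3),
              rz = runif(50, -0.3, 0.3))
  pf <- fit_listing_plane(R0)
  expect_equal(pf$normal, c(1, 0, 0))
  expect_equal(pf$width_deg, 0)
  expect_equal(pf$angle_deg, 0)
  # a 0.043 half-radian scatter reads as about 4.9 degrees
  expect_equal(2 * 0.043 * 180 / pi, 4.93, tolerance = 0.01)
  expect_error(fit_listing_plane(cbind(1, 0 * 1:5, 0 * 1:5)), "degenerate")
})

test_that("plane width recovers injected torsional scatter", {
  # anchored generator case: SD 0.015 half-radians is 1.72 degrees
  cl <- make_rotvec_cloud(4000, sd_torsion = 0.015, seed = 2)
  expect_equal(fit_listing_plane(cl)$width_deg, 2 * 0.015 * 180 / pi,
               tolerance = 0.05)
  # across the physiological-to-model range 0.3 to 6 degrees
  for (wdeg in c(0.3, 1, 3, 6)) {
    cl <- make_rotvec_cloud(4000, sd_torsion = wdeg * pi / 360,
                            normal = c(0.95, -0.2, -0.1), seed = 7)
    expect_lt(abs(fit_listing_plane(cl)$width_deg - wdeg) / wdeg, 0.05)
  }
})

test_that("listing transform aligns the fitted normal with primary", {
  cl <- make_rotvec_cloud(3000, normal = c(0.94, -0.25, -0.18),
                          sd_torsion = 0.01, seed = 3)
  fit <- fit_listing_plane(cl)
  expect_gt(fit$angle_deg, 10)
  clL <- listing_transform(cl, fit)
  refit <- fit_listing_plane(clL)
  expect_lt(refit$angle_deg, 0.5)
  # second application is (nearly) the identity
  # second application is (nearly) the identity: the refitted normal is
  # within the fit noise of the primary direction
  clL2 <- listing_transform(clL, refit)
  expect_lt(max(abs(clL2 - listing_transform(clL,
                                             fit_listing_plane(clL2)))),
            1e-3)
  # rotations preserve pairwise inner products
  expect_equal(tcrossprod(clL[1:20, ]), tcrossprod(cl[1:20, ]),
               tolerance = 1e-9)
  # already-aligned data is left (essentially) unchanged
  aligned <- make_rotvec_cloud(1000, sd_torsion = 0.002, seed = 4)
  expect_lt(max(abs(listing_transform(aligned) - aligned)), 5e-3)
})

test_that("saccade metrics on analytic triangular saccades", {
  # amplitudes whose triangle base is an even number of ticks, so that the
  # sampled profile is exactly triangular (vertex on a sample point)
  amps_in <- c(4, 8, 12, 16, 20, 24, 28, 32, 36, 40)
  trs <- make_triangular_saccades(amps_in, vpk_deg_s = 400,
                                  direction = c(0, 1, 1) / sqrt(2))
  mets <- lapply(trs, function(tr)
    saccade_metrics(tr, round(attr(tr, "D_ms") / 10)))
  amp <- vapply(mets, `[[`, numeric(1), "amplitude_deg")
  vpk <- vapply(mets, `[[`, numeric(1), "vpk_deg_s")
  D <- vapply(mets, `[[`, numeric(1), "D_ms")
  expect_equal(amp, amps_in, tolerance = 0.02)
  # straight oblique movement: profile correlation is one
  for (mt in mets) expect_gt(mt$straightness, 1 - 1e-6)
  # triangular profiles: Vpk * D = 2 * amplitude, hence slope 1/2, r2 = 1
  rel <- vpk_duration_relation(data.frame(amplitude_deg = amp,
                                          vpk_deg_s = vpk, D_ms = D),
                               min_amplitude = 0)
  expect_equal(rel$slope, 0.5, tolerance = 0.05)
  expect_gt(rel$r2, 0.999)
  # duplicated points leave the fit unchanged
  rel2 <- vpk_duration_relation(data.frame(amplitude_deg = rep(amp, 2),
                                           vpk_deg_s = rep(vpk, 2),
                                           D_ms = rep(D, 2)),
                                min_amplitude = 0)
  expect_equal(rel2$slope, rel$slope, tolerance = 1e-12)
  # a zero-displacement "saccade" is flagged as fixation
  flat <- trs[[1]]
  flat[, c("rx", "ry", "rz", "wx", "wy", "wz")] <- 0
  attr(flat, "q") <- NULL
  expect_true(saccade_metrics(flat, 2)$fixation)
  expect_error(saccade_metrics(trs[[1]][1:2, ], 10), "shorter")
})

test_that("main-sequence fit recovers known parameters", {
  set.seed(61)
  # anchored case: V0 = 600, alpha = 20, 2% multiplicative noise
  A <- runif(200, 1, 45)
  V <- 600 * (1 - exp(-A / 20)) * (1 + rnorm(200, sd = 0.02))
  ms <- fit_main_sequence(data.frame(amplitude_deg = A, vpk_deg_s = V,
                                     D_ms = 2 * A + 40))
  expect_lt(abs(ms$V0 - 600) / 600, 0.05)
  expect_lt(abs(ms$alpha - 20) / 20, 0.05)
  expect_equal(ms$duration_slope, 2, tolerance = 1e-6)
  expect_equal(ms$duration_intercept, 40, tolerance = 1e-4)
  # parameter recovery across 20 random draws
  for (i in 1:20) {
    v0 <- runif(1, 200, 900); al <- runif(1, 8, 35)
    A <- runif(150, 1, 45)
    V <- v0 * (1 - exp(-A / al)) * (1 + rnorm(150, sd = 0.02))
    ms <- fit_main_sequence(data.frame(amplitude_deg = A, vpk_deg_s = V,
                                       D_ms = 2 * A + 40))
    expect_lt(abs(ms$V0 - v0) / v0, 0.1)
    expect_lt(abs(ms$alpha - al) / al, 0.15)
  }
  # linear (non-saturating) data pushes alpha past the amplitude range
  Vlin <- 8 * A * (1 + rnorm(150, sd = 0.01))
  mslin <- fit_main_sequence(data.frame(amplitude_deg = A,
                                        vpk_deg_s = Vlin, D_ms = 100))
  expect_true(mslin$near_linear)
  expect_gt(mslin$alpha, max(A))
})

test_that("component-stretching correlation endpoints", {
  Phi <- c(0, 20, 40, 60, 80)
  base <- data.frame(Phi_deg = Phi, V_amp = tan(Phi * pi / 180) * 8,
                     D_ms = 100)
  exact <- transform(base, vpk_H = 300 * cos(Phi * pi / 180), vpk_V = 1)
  expect_equal(component_stretch_corr(exact), 1)
  flat <- transform(base, vpk_H = 300, vpk_V = 1)
  expect_equal(component_stretch_corr(flat), 0)
  rising <- transform(base, vpk_H = 300 + 3 * Phi, vpk_V = 1)
  expect_lt(component_stretch_corr(rising), -0.9)
})

test_that("summary report table is well-formed and deterministic", {
  empty <- table3_report(list())
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("functional", "width_deg", "V0", "r_CS") %in%
                    names(empty)))
  b <- test_batch("AED", n = 300)
  st <- test_stretch("AED")
  path <- withr::local_tempfile(fileext = ".csv")
  r1 <- table3_report(list(AED = b), stretches = list(AED = st),
                      path = path)
  expect_equal(nrow(r1), 1L)
  expect_equal(r1$r_CS, component_stretch_corr(st))
  r2 <- table3_report(list(AED = b), stretches = list(AED = st))
  expect_identical(r1, r2)
  expect_true(file.exists(path))
})
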