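test_that("self-normalisation gives a unit spectrum and an impulse", {
  set.seed(1)
  x <- rnorm(1024)
  X <- stats::fft(x)
  n2 <- normalise_spectra(X, X, "N2", epsilon = 0)
  expect_equal(Mod(n2), rep(1, 1024), tolerance = 1e-12)
  rec <- recording("P", "EO", 256, "c1", matrix(x, 1))
  rec_ec <- recording("P", "EC", 256, "c1", matrix(x, 1))
  out <- normalise_recording(rec, rec_ec, norm_config("N2", epsilon = 1e-12))
  expect_equal(unname(out$data[1, 1]), 1, tolerance = 1e-8)
  expect_lt(max(abs(out$data[1, -1])), 1e-8)
})

test_that("N3 amplitude equals squared N2 amplitude when epsilon is zero", {
  set.seed(2)
  x_eo <- stats::fft(rnorm(512))
  x_ec <- stats::fft(rnorm(512))
  n2 <- normalise_spectra(x_eo, x_ec, "N2", 0)
  n3 <- normalise_spectra(x_eo, x_ec, "N3", 0)
  expect_equal(Mod(n3), Mod(n2)^2, tolerance = 1e-10)
})

test_that("N1 preserves the EO phase; N2/N3 discard all phase", {
  set.seed(3)
  x_eo <- stats::fft(rnorm(512))
  x_ec <- stats::fft(rnorm(512))
  n1 <- normalise_spectra(x_eo, x_ec, "N1", 1e-12)
  expect_equal(Arg(n1), Arg(x_eo), tolerance = 1e-9)
  # phase randomisation of either input leaves N2/N3 untouched
  spin <- exp(1i * stats::runif(512, -pi, pi))
  for (v in c("N2", "N3")) {
    a <- normalise_spectra(x_eo, x_ec, v, 0)
    b <- normalise_spectra(x_eo * spin, x_ec * rev(spin), v, 0)
    expect_equal(a, b, tolerance = 1e-10)
  }
})

test_that("a two-tone amplitude ratio maps to r (N2) and r^2 (N3)", {
  fs <- 256; n <- fs * 4; r <- 0.4
  t <- seq_len(n) / fs
  ec <- 2 * sin(2 * pi * 10 * t) + sin(2 * pi * 20 * t)
  eo <- 2 * r * sin(2 * pi * 10 * t) + sin(2 * pi * 20 * t)
  X_eo <- stats::fft(eo); X_ec <- stats::fft(ec)
  bin10 <- 10 * 4 + 1; bin20 <- 20 * 4 + 1   # resolution 1/4 Hz
  n2 <- normalise_spectra(X_eo, X_ec, "N2", 0)
  n3 <- normalise_spectra(X_eo, X_ec, "N3", 0)
  expect_equal(Mod(n2)[bin10], r, tolerance = 1e-6)
  expect_equal(Mod(n2)[bin20], 1, tolerance = 1e-6)
  expect_equal(Mod(n3)[bin10], r^2, tolerance = 1e-6)
  expect_equal(Mod(n3)[bin20], 1, tolerance = 1e-6)
})

test_that("normalisation cancels a common gain on both conditions", {
  set.seed(4)
  eo <- recording("P", "EO", 256, c("a", "b"), matrix(rnorm(2 * 1024), 2))
  ec <- recording("P", "EC", 256, c("a", "b"), matrix(rnorm(2 * 1024), 2))
  for (v in c("N1", "N2", "N3")) {
    base <- normalise_recording(eo, ec, norm_config(v))
    eo2 <- eo; ec2 <- ec
    eo2$data <- 7 * eo2$data; ec2$data <- 7 * ec2$data
    scaled <- normalise_recording(eo2, ec2, norm_config(v))
    expect_equal(scaled$data, base$data, tolerance = 1e-9)
  }
})

test_that("EC amplitude dominance bounds N1/N2 amplitudes by one", {
  set.seed(5)
  x <- rnorm(512)
  X_eo <- stats::fft(x)
  X_ec <- stats::fft(1.5 * x)
  for (v in c("N1", "N2")) {
    expect_true(all(Mod(normalise_spectra(X_eo, X_ec, v, 0)) <= 1 + 1e-12))
  }
})

test_that("epsilon keeps vanishing EC amplitudes finite and continuous", {
  x_eo <- as.complex(c(4, 2, 0, 2))
  x_ec <- as.complex(c(2, 0, 0, 0))
  out <- normalise_spectra(x_eo, x_ec, "N2", 1e-3)
  expect_true(all(is.finite(Mod(out))))
  out2 <- normalise_spectra(x_eo, x_ec, "N2", 1e-3 + 1e-9)
  expect_equal(Mod(out), Mod(out2), tolerance = 1e-4)
  expect_error(normalise_spectra(x_eo, x_ec, "N2", -1), "epsilon")
  expect_error(normalise_spectra(x_eo, x_ec[1:3], "N2", 0), "grids")
})

test_that("normalised HFD extraction is deterministic and validates inputs", {
  co <- tiny_cohort()
  a <- suppressWarnings(extract_normalised_hfd(co, norm_config("N2")))
  b <- suppressWarnings(extract_normalised_hfd(co, norm_config("N2")))
  expect_identical(a, b)
  expect_equal(nrow(a), 4 * 50 * 4)
  expect_identical(attr(a, "variant"), "N2")
  co2 <- co
  co2$recordings[["A_PDP_01_EC"]] <- NULL
  expect_error(suppressWarnings(extract_normalised_hfd(co2, norm_config("N2"))),
               "A_PDP_01")
  # matched-index pairing also produces the full table
  m <- suppressWarnings(
    extract_normalised_hfd(co, norm_config("N2", pairing = "matched-index"))
  )
  expect_equal(nrow(m), 4 * 50 * 4)
})

test_that("reduced reactivity moves the normalised alpha amplitude toward 1", {
  # the group contrast the normalisation is designed to expose: a PDP
  # participant's EC/EO alpha ratio is smaller, so their normalised alpha
  # amplitude sits closer to 1 than a PNP participant's
  spec <- cohort_spec(n_pdp = 8, n_pnp = 8, n_channels = 6,
                      duration_s = 100, theta_effect = 1, alpha_shift_hz = 0,
                      reactivity_pnp = 1.6, reactivity_pdp = 1.05, seed = 31)
  co <- preprocess_cohort(generate_cohort(spec, sites = "A"))
  amp <- vapply(co$manifest$participant_id, function(pid) {
    eo <- co$recordings[[paste0(pid, "_EO")]]$data[6, ]
    ec <- co$recordings[[paste0(pid, "_EC")]]$data[6, ]   # posterior channel
    y <- normalise_spectra(stats::fft(eo), stats::fft(ec), "N2", 1e-8)
    f <- seq(0, 256, length.out = length(eo) + 1)[seq_along(eo)]
    mean(Mod(y)[f >= 8 & f <= 12])
  }, numeric(1))
  grp <- co$manifest$group
  tt <- stats::t.test(amp[grp == "PDP"], amp[grp == "PNP"],
                      alternative = "greater")
  expect_lt(tt$p.value, 1e-6)
  # a null cohort (equal reactivity, no spectral effects) shows no contrast
  spec0 <- cohort_spec(n_pdp = 8, n_pnp = 8, n_channels = 6,
                       duration_s = 100, theta_effect = 1,
                       alpha_shift_hz = 0, reactivity_pnp = 1.3,
                       reactivity_pdp = 1.3, seed = 31)
  co0 <- preprocess_cohort(generate_cohort(spec0, sites = "A"))
  amp0 <- vapply(co0$manifest$participant_id, function(pid) {
    eo <- co0$recordings[[paste0(pid, "_EO")]]$data[6, ]
    ec <- co0$recordings[[paste0(pid, "_EC")]]$data[6, ]
    y <- normalise_spectra(stats::fft(eo), stats::fft(ec), "N2", 1e-8)
    f <- seq(0, 256, length.out = length(eo) + 1)[seq_along(eo)]
    mean(Mod(y)[f >= 8 & f <= 12])
  }, numeric(1))
  g0 <- co0$manifest$group
  expect_gt(stats::t.test(amp0[g0 == "PDP"], amp0[g0 == "PNP"])$p.value,
            0.01)
})
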