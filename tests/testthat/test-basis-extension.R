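test_that("mean_residual recovers a common orthogonal component exactly", {
  b <- load_cie_basis()
  set.seed(6)
  v <- stats::rnorm(471)
  v <- as.numeric(qr.resid(qr(b$components), v))
  v <- v / sqrt(sum(v^2))
  # spectra = basis combination + fixed orthogonal vector
  sp <- lapply(1:4, function(i) {
    base <- b$components %*% c(0.9, 0.1 * i, -0.05)
    spectrum(b$wavelength_nm, as.numeric(base) + 0.3 * v, "relative")
  })
  mr <- mean_residual(b, sp)
  # same component up to the per-spectrum normalisation (signs align)
  expect_gt(abs(sum(mr$component * v)), 0.999999)
  expect_equal(sqrt(sum(mr$component^2)), 1, tolerance = 1e-12)
  expect_equal(mr$n, 4)

  # spectra inside the basis span are degenerate
  inspan <- lapply(1:3, function(i)
    spectrum(b$wavelength_nm,
             as.numeric(b$components %*% c(1, 0.1 * i, 0)), "relative"))
  expect_error(mean_residual(b, inspan), "degenerate")
  # cancelling residuals are degenerate too
  plus <- spectrum(b$wavelength_nm,
                   as.numeric(b$components %*% c(1, 0, 0)) + 0.2 * v,
                   "relative")
  minus <- spectrum(b$wavelength_nm,
                    as.numeric(b$components %*% c(1, 0, 0)) - 0.2 * v,
                    "relative")
  expect_error(mean_residual(b, list(plus, minus)), "degenerate")
  expect_error(mean_residual(b, list()), "empty")
})

test_that("extend_cie grows two six-component location models", {
  sc <- small_calibrated()
  ext <- extend_cie(sc$sets$rural, sc$sets$city)
  expect_equal(ncol(ext$cie_plus_3R$components), 6)
  expect_equal(ncol(ext$cie_plus_3C$components), 6)
  expect_equal(ncol(ext$cie_plus_1$components), 4)
  expect_equal(ncol(ext$cie_plus_2$components), 5)
  expect_equal(unname(sqrt(colSums(ext$cie_plus_3R$components^2))),
               rep(1, 6), tolerance = 1e-10)
  expect_equal(ext$stages$n_records[1],
               sum(sc$sets$rural$theta_s >= 0) +
                 sum(sc$sets$city$theta_s >= 0))

  # the location-specific components recover the injected night features
  wl <- ext$cie_plus_3R$wavelength_nm
  r3 <- abs(ext$cie_plus_3R$components[, "CIE+3R"])
  expect_lte(abs(wl[which.max(r3)] - 558), 2)
  c3 <- abs(ext$cie_plus_3C$components[, "CIE+3C"])
  nir <- wl >= 750 & wl <= 840
  expect_lte(abs(wl[nir][which.max(c3[nir])] - 819), 2)
  vis_peak <- wl[which.max(c3)]
  expect_true((vis_peak >= 570 && vis_peak <= 615) ||
                abs(vis_peak - 819) <= 2)

  # an empty stage regime is reported by name
  day_only <- list(spectra = sc$sets$rural$spectra[sc$sets$rural$theta_s >= 0],
                   theta_s = sc$sets$rural$theta_s[sc$sets$rural$theta_s >= 0])
  expect_error(extend_cie(day_only, sc$sets$city), "astro_rural")
})

test_that("nested models never increase the residual sum of squares", {
  sc <- small_calibrated()
  ext <- extend_cie(sc$sets$rural, sc$sets$city)
  models <- list(load_cie_basis(), ext$cie_plus_1, ext$cie_plus_2,
                 ext$cie_plus_3R)
  sp <- sc$sets$rural$spectra
  idx <- seq(1, length(sp), by = 7)     # thinned for speed, all regimes hit
  for (i in idx) {
    sse <- vapply(models, function(m)
      sum(fit_spectrum(m, sp[[i]])$residual^2), 0)
    expect_true(all(diff(sse) <= 1e-10))
  }
})

test_that("compare_models profiles R^2 per bin with benchmarks", {
  b <- load_cie_basis()
  # a model containing the generating components scores R^2 = 1 in its bin
  sp <- lapply(c(5500, 6500, 7500), function(cct) cie_daylight_spectrum(cct))
  prof <- compare_models(list(cie = b), sp, c(1, 3, 5), bin_width_deg = 2)
  expect_true(all(prof$r2_mean > 0.999999))
  # the mean-spectrum benchmark on identical night spectra gives R^2 = 1
  night <- lapply(1:3, function(i) sp[[1]])
  prof2 <- compare_models(list(cie = b), night, rep(-20, 3),
                          bin_width_deg = 2, mean_night_benchmark = TRUE)
  bench <- prof2[prof2$model == "mean_night", ]
  expect_equal(bench$r2_mean, 1, tolerance = 1e-10)
})
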