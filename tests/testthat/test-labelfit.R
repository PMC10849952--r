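# Stable-isotope label incorporation fitting.

test_that("labeled species swap H for D with the right mass offset", {
  sp <- labeled_species("C28H55O8Cl", 2, 0, purity = 1)
  expect_identical(format(sp$formula), "C28H53D2ClO8")
  expect_equal(sp$mass_offset, 2.0126, tolerance = 1e-4)
  expect_equal(sp$mass_offset, 2 * 1.006277, tolerance = 1e-3)
  expect_equal(sp$nominal_shift, 2L)
  # losing every label returns the unlabeled parent
  sp0 <- labeled_species("C28H55O8Cl", 2, 2)
  expect_identical(format(sp0$formula), "C28H55ClO8")
  expect_equal(sp0$mass_offset, 0)
  expect_error(labeled_species("C28H55O8Cl", 1, 2), "n_lost")
})

test_that("noiseless mixtures are recovered essentially exactly", {
  unlab <- labeled_species("C28H55O8Cl", 2, 2)
  d2 <- labeled_species("C28H55O8Cl", 2, 0, purity = 1)
  # pure unlabeled
  fit0 <- fit_label_mixture(isotope_pattern("C28H55O8Cl"), list(unlab, d2))
  expect_equal(unname(fit0$fractions), c(1, 0), tolerance = 1e-6)
  # constructed 0.7/0.3 mixture
  obs <- simulate_feeding("C28H55O8Cl", 2, 0, 0.3, noise = 0, purity = 1)
  fit <- fit_label_mixture(obs$observed, list(unlab, d2))
  expect_equal(unname(fit$fractions), c(0.7, 0.3), tolerance = 1e-6)
  expect_lt(fit$residual, 1e-12)
  expect_equal(sum(fit$fractions), 1, tolerance = 1e-9)
  # pure labeled
  obs1 <- simulate_feeding("C28H55O8Cl", 2, 0, 1, noise = 0, purity = 1)
  fit1 <- fit_label_mixture(obs1$observed, list(unlab, d2))
  expect_equal(unname(fit1$fractions), c(0, 1), tolerance = 1e-6)
})

test_that("fractions are equivariant under species permutation", {
  unlab <- labeled_species("C28H55O8Cl", 2, 2)
  d1 <- labeled_species("C28H55O8Cl", 2, 1, purity = 1)
  d2 <- labeled_species("C28H55O8Cl", 2, 0, purity = 1)
  obs <- simulate_feeding("C28H55O8Cl", 2, 1, 0.4, noise = 0.01, seed = 13,
                          purity = 1)
  f123 <- fit_label_mixture(obs$observed, list(unlab, d1, d2))
  f321 <- fit_label_mixture(obs$observed, list(d2, d1, unlab))
  expect_equal(f123$fractions[c("unlabeled", "d1", "d2")],
               f321$fractions[c("unlabeled", "d1", "d2")], tolerance = 1e-9)
  expect_equal(f123$residual, f321$residual, tolerance = 1e-12)
})

test_that("adding the generating species never increases the residual", {
  unlab <- labeled_species("C28H55O8Cl", 2, 2)
  d1 <- labeled_species("C28H55O8Cl", 2, 1, purity = 1)
  d2 <- labeled_species("C28H55O8Cl", 2, 0, purity = 1)
  obs <- simulate_feeding("C28H55O8Cl", 2, 1, 0.35, noise = 0.02, seed = 14,
                          purity = 1)
  without <- fit_label_mixture(obs$observed, list(unlab, d2))
  with_d1 <- fit_label_mixture(obs$observed, list(unlab, d2, d1))
  expect_lte(with_d1$residual, without$residual + 1e-12)
})

test_that("identical species trigger the rank-deficiency warning", {
  unlab <- labeled_species("C28H55O8Cl", 2, 2)
  expect_warning(fit_label_mixture(isotope_pattern("C28H55O8Cl"),
                                   list(unlab, unlab)), "rank-deficient")
})

test_that("noisy mixtures are recovered within 0.05 over a fraction grid", {
  unlab <- labeled_species("C28H55O8Cl", 2, 2)
  d2 <- labeled_species("C28H55O8Cl", 2, 0, purity = 1)
  errs <- c()
  for (truef in c(0, 0.25, 0.5, 0.75, 1)) {
    for (rep in 1:20) {
      obs <- simulate_feeding("C28H55O8Cl", 2, 0, truef, noise = 0.02,
                              purity = 1, seed = 1000 * truef + rep)
      fit <- fit_label_mixture(obs$observed, list(unlab, d2))
      errs <- c(errs, abs(unname(fit$fractions[2]) - truef))
    }
  }
  expect_lte(mean(errs), 0.05)
  expect_lte(max(errs), 0.1)
})

test_that("retention hypothesis ranking identifies the true label loss", {
  # deuterium displaced by chlorination: one label lost, M+1 shift
  obs1 <- simulate_feeding("C28H55O8Cl", 2, 1, 0.3, noise = 0.02, seed = 15)
  rt1 <- retention_model_test(obs1$observed, "C28H55O8Cl", 2)
  expect_equal(attr(rt1, "best"), 1)
  expect_false(attr(rt1, "inconclusive"))
  # full retention
  obs0 <- simulate_feeding("C28H55O8Cl", 2, 0, 0.3, noise = 0.02, seed = 16)
  rt0 <- retention_model_test(obs0$observed, "C28H55O8Cl", 2)
  expect_equal(attr(rt0, "best"), 0)
  # pure unlabeled observation: inconclusive
  rtn <- retention_model_test(isotope_pattern("C28H55O8Cl"), "C28H55O8Cl", 2)
  expect_true(attr(rtn, "inconclusive"))
})
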