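# Isotope envelope simulation and chlorine detection.

test_that("single-element envelopes match closed-form isotope ratios", {
  cl <- isotope_pattern("Cl")
  expect_equal(cl$abundance[cl$offset == 2] / cl$abundance[cl$offset == 0],
               0.3200, tolerance = 5e-4)
  # binomial expansion oracle: q/p = 0.2424/0.7576 per chlorine
  qp <- 0.2424 / 0.7576
  cl2 <- isotope_pattern("Cl2")
  r0 <- cl2$abundance[cl2$offset == 0]
  expect_equal(cl2$abundance[cl2$offset == 2] / r0, 2 * qp, tolerance = 1e-9)
  expect_equal(cl2$abundance[cl2$offset == 4] / r0, qp^2, tolerance = 1e-9)
  expect_equal(2 * qp, 0.6399, tolerance = 1e-4)
  expect_equal(qp^2, 0.1024, tolerance = 5e-4)
  c1 <- isotope_pattern("C")
  expect_equal(c1$abundance[c1$offset == 1] / c1$abundance[c1$offset == 0],
               0.0107 / 0.9893, tolerance = 1e-9)
})

test_that("envelopes agree with the multinomial brute-force oracle (<= 6 atoms)", {
  set.seed(3)
  formulas <- c("H2O", "CH4", "Cl2", "SO2", "C2HCl", "NaCl", "C3S",
                "HDO", "C2N2", "OSCl")
  for (txt in formulas) {
    ora <- oracle_envelope(txt)
    pat <- isotope_pattern(txt, max_offsets = 30L, prune = 0)
    got <- stats::setNames(numeric(nrow(ora)), ora$offset)
    hit <- match(pat$offset, ora$offset)
    expect_false(anyNA(hit), label = txt)
    got[hit] <- pat$abundance
    expect_equal(got / sum(got), stats::setNames(ora$abundance, ora$offset) /
                   sum(ora$abundance), tolerance = 1e-9, label = txt)
  }
})

test_that("envelope of a union equals the convolution of envelopes", {
  conv <- function(a, b, kmax = 10L) {
    # offset-wise convolution of two normalized-to-sum patterns
    va <- stats::setNames(a$abundance / sum(a$abundance), a$offset)
    vb <- stats::setNames(b$abundance / sum(b$abundance), b$offset)
    out <- numeric(kmax + 1L)
    for (i in names(va)) for (j in names(vb)) {
      k <- as.integer(i) + as.integer(j)
      if (k <= kmax) out[k + 1L] <- out[k + 1L] + va[[i]] * vb[[j]]
    }
    out
  }
  pairs <- list(c("C10H16", "O5Cl"), c("C5Cl", "S2"), c("H10N2", "C4O2"))
  for (p in pairs) {
    a <- isotope_pattern(p[1], max_offsets = 10L, prune = 0)
    b <- isotope_pattern(p[2], max_offsets = 10L, prune = 0)
    ab <- isotope_pattern(formula_add(p[1], p[2]), max_offsets = 10L, prune = 0)
    v_ab <- numeric(11L)
    v_ab[ab$offset + 1L] <- ab$abundance / sum(ab$abundance)
    # truncation at kmax keeps > 1 - 1e-9 of the mass for these formulas
    expect_equal(v_ab, conv(a, b), tolerance = 1e-8,
                 label = paste(p, collapse = "+"))
  }
})

test_that("envelope structure invariants hold", {
  pat <- isotope_pattern("C28H55O8Cl")
  expect_equal(max(pat$abundance), 1.0)
  expect_true(all(diff(pat$mz) > 0))
  # successive peaks spaced by ~1.00336 Da per offset step
  d <- diff(pat$mz) / diff(pat$offset)
  expect_true(all(abs(d - 1.00336) < 0.01))
  expect_true(all(pat$abundance >= 1e-4))
  # pruning keeps the base peak even in pathological thresholds
  p2 <- isotope_pattern("C", prune = 0.5)
  expect_true(1.0 %in% p2$abundance)
})

test_that("chlorine scoring flags Cl envelopes and rejects Cl-free ones", {
  sc <- chlorine_score(isotope_pattern("C28H55O8Cl"))
  expect_true(sc$is_chlorinated)
  expect_equal(sc$ratio, 0.38, tolerance = 0.02)
  expect_equal(sc$n_cl_estimate, 1L)

  sc2 <- chlorine_score(isotope_pattern("C28H56O8"))
  expect_false(sc2$is_chlorinated)
  expect_gt(sc2$ratio, 0.04); expect_lt(sc2$ratio, 0.08)
  expect_equal(sc2$n_cl_estimate, 0L)

  sc3 <- chlorine_score(isotope_pattern("C20H38Cl2O4"))
  expect_true(sc3$is_chlorinated)
  expect_equal(sc3$n_cl_estimate, 2L)

  # pattern with no M+2 peak
  pat <- isotope_pattern("C2H6O")
  pat <- pat[pat$offset < 2, ]
  class(pat) <- c("isotope_pattern", "data.frame")
  sc4 <- chlorine_score(pat)
  expect_false(sc4$is_chlorinated)
  expect_equal(sc4$ratio, 0.0)
  expect_error(chlorine_score(structure(data.frame(),
                                        class = c("isotope_pattern",
                                                  "data.frame"))),
               "non-empty")
})

test_that("observed peak lists map onto integer isotopologue offsets", {
  mzs <- 555.3658 + c(0, 1.00336, 2.00671, 0.512)   # last one off-grid
  pat <- isotope_pattern_from_peaks(mzs, c(100, 34, 38, 40))
  expect_equal(pat$offset, c(0L, 1L, 2L))
  expect_equal(pat$abundance[1], 1.0)
})
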