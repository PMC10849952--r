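# MS/MS preprocessing, modified cosine and molecular networking.

test_that("precursor exclusion zone removes peaks within 17 Th", {
  s <- msms_spectrum("x", 500, data.frame(mz = c(480, 490, 499.5),
                                          intensity = c(10, 20, 30)))
  f <- filter_peaks(s)
  expect_equal(f$peaks$mz, 480)
})

test_that("rank filter keeps only the top 6 within any +-50 Th window", {
  # 8 equally spaced peaks inside one 100-Th span, distinct intensities
  mzs <- seq(100, 170, by = 10)
  ints <- c(5, 80, 15, 60, 25, 40, 95, 10)
  s <- msms_spectrum("x", 600, data.frame(mz = mzs, intensity = ints))
  f <- filter_peaks(s)
  # brute-force window check per peak
  expected <- vapply(seq_along(mzs), function(i) {
    win <- abs(mzs - mzs[i]) <= 50
    sum(ints[win] > ints[i]) < 6
  }, logical(1))
  expect_equal(f$peaks$mz, mzs[expected])
  expect_equal(nrow(filter_peaks(f)$peaks), nrow(f$peaks))  # idempotent
  # empty spectrum passes through
  e <- msms_spectrum("e", 500, data.frame(mz = numeric(0),
                                          intensity = numeric(0)))
  expect_equal(nrow(filter_peaks(e)$peaks), 0L)
})

test_that("modified cosine is 1 against itself and 0 with no matches", {
  set.seed(7)
  s <- rand_spectrum("s", 8)
  self <- modified_cosine(s, s)
  expect_equal(self$score, 1.0, tolerance = 1e-9)
  expect_equal(self$n_matched, 8L)
  a <- msms_spectrum("a", 500, data.frame(mz = c(100, 200),
                                          intensity = c(10, 10)))
  b <- msms_spectrum("b", 510, data.frame(mz = c(150, 250),
                                          intensity = c(10, 10)))
  none <- modified_cosine(a, b)
  expect_equal(none$score, 0.0)
  expect_equal(none$n_matched, 0L)
})

test_that("greedy matching equals the exhaustive-enumeration oracle", {
  set.seed(8)
  for (i in 1:200) {
    pr <- rand_spectrum_pair()
    got <- modified_cosine(pr$a, pr$b)
    ora <- oracle_modified_cosine(pr$a, pr$b)
    expect_equal(got$score, ora$score, tolerance = 1e-9)
    expect_equal(got$n_matched, ora$n)
  }
})

test_that("cosine is symmetric, bounded and scale invariant", {
  set.seed(9)
  for (i in 1:25) {
    pr <- rand_spectrum_pair()
    ab <- modified_cosine(pr$a, pr$b)
    ba <- modified_cosine(pr$b, pr$a)
    expect_equal(ab$score, ba$score, tolerance = 1e-9)
    expect_equal(ab$n_matched, ba$n_matched)
    expect_gte(ab$score, 0); expect_lte(ab$score, 1)
    scaled <- pr$b; scaled$peaks$intensity <- scaled$peaks$intensity * 37.5
    expect_equal(modified_cosine(pr$a, scaled)$score, ab$score,
                 tolerance = 1e-9)
  }
})

test_that("network edges require both the cosine and the match-count threshold", {
  set.seed(10)
  base <- rand_spectrum("n1", 8)
  # clone shares 5 peaks -> high cosine, enough matches
  clone <- base; clone$spectrum_id <- "n2"
  clone$precursor_mz <- base$precursor_mz + 42.0106
  far <- rand_spectrum("n3", 8)
  net <- build_network(list(base, clone, far))
  expect_true(nrow(net$edges) >= 1)
  expect_true(all(net$edges$cosine >= 0.60 & net$edges$n_matched >= 4))
  expect_true(all(net$edges$a != net$edges$b))   # no self loops
  # raising thresholds past the observed values removes the edge
  strict <- build_network(list(base, clone, far), min_cosine = 1.01)
  expect_equal(nrow(strict$edges), 0L)
  few <- build_network(list(base, clone, far), min_matched = 9L)
  expect_equal(nrow(few$edges), 0L)
  expect_error(build_network(list(base, base)), "duplicate")
})

test_that("adding an unrelated spectrum never changes existing edge scores", {
  set.seed(11)
  pr <- rand_spectrum_pair(8)
  pr$a$spectrum_id <- "a"; pr$b$spectrum_id <- "b"
  lone <- rand_spectrum("c", 6)
  n2 <- build_network(list(pr$a, pr$b), min_cosine = 0, min_matched = 1L)
  n3 <- build_network(list(pr$a, pr$b, lone), min_cosine = 0, min_matched = 1L)
  e2 <- n2$edges[n2$edges$a == "a" & n2$edges$b == "b", ]
  e3 <- n3$edges[n3$edges$a == "a" & n3$edges$b == "b", ]
  expect_equal(e2$cosine, e3$cosine)
  expect_equal(e2$n_matched, e3$n_matched)
})

test_that("a planted compound family lands in one connected component", {
  ex <- simulate_experiment(demo_manifest(seed = 23, n_background = 0))
  filt <- lapply(ex$spectra, filter_peaks)
  net <- build_network(filt)
  comp <- igraph::components(net$graph)$membership
  fam <- names(comp)[startsWith(names(comp), "NGL")]
  expect_equal(length(fam), 8L)
  expect_equal(length(unique(comp[fam])), 1L)
  # the halide-independent family forms its own separate component
  hex <- names(comp)[startsWith(names(comp), "HGL")]
  expect_equal(length(unique(comp[hex])), 1L)
  expect_false(unique(comp[hex]) == unique(comp[fam]))
})

test_that("component report counts members, depleted and chlorinated nodes", {
  # family with 2 halide-independent members
  ex <- simulate_experiment(demo_manifest(seed = 24, n_background = 0,
                                          n_family_null = 2))
  tab <- gap_fill_floor(join_features(ex$runs))
  diff <- differential_stats(tab)
  chlor <- chlorine_scan(tab, ex$envelopes)
  ann <- merge(diff, chlor, by = "feature_id")
  filt <- lapply(ex$spectra, filter_peaks)
  map <- match_spectra_to_features(tab, filt)
  ann <- ann[match(names(map), ann$feature_id), ]
  ann$feature_id <- unname(map)
  used <- filt[vapply(filt, function(s) s$spectrum_id,
                      character(1)) %in% unname(map)]
  net <- build_network(used, annotations = ann)
  rep <- component_report(net)
  fam_row <- rep[grepl("NGL", rep$members), ]
  expect_equal(fam_row$n_members, 8L)
  expect_equal(fam_row$n_members - fam_row$n_depleted, 2L)
  expect_equal(fam_row$n_chlorinated, 8L)
  # empty network -> empty report
  empty <- build_network(list())
  expect_equal(nrow(component_report(empty)), 0L)
  # singleton -> component of size 1
  single <- build_network(list(rand_spectrum("solo", 5)))
  expect_equal(component_report(single)$n_members, 1L)
})

test_that("MGF files round-trip spectra with metadata", {
  set.seed(12)
  specs <- list(rand_spectrum("feat_A", 6), rand_spectrum("feat_B", 7))
  specs[[1]]$rt <- 5.5
  specs[[1]]$collision_energy <- collision_energy(specs[[1]]$precursor_mz)
  path <- tempfile(fileext = ".mgf")
  write_mgf(specs, path)
  back <- read_mgf(path)
  expect_equal(length(back), 2L)
  expect_equal(back[[1]]$spectrum_id, "feat_A")
  expect_equal(back[[1]]$precursor_mz, specs[[1]]$precursor_mz,
               tolerance = 1e-4)
  expect_equal(back[[1]]$rt, 5.5, tolerance = 1e-4)
  expect_equal(nrow(back[[2]]$peaks), 7L)
  expect_equal(back[[2]]$peaks$mz, specs[[2]]$peaks$mz, tolerance = 1e-4)
  expect_error(read_mgf(tempfile()), "not found")
})
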