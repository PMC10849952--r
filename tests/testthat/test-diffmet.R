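# Feature joining, gap filling, differential statistics and artifact
# grouping.

test_that("identical runs join one row per feature, present in all columns", {
  r1 <- data.frame(run_id = "replete_1", condition = "replete",
                   mz = c(200.1, 350.2, 500.3), rt = c(2, 5, 8),
                   intensity = c(1e4, 2e4, 3e4))
  r2 <- r1; r2$run_id <- "depleted_1"; r2$condition <- "depleted"
  tab <- join_features(rbind(r1, r2))
  expect_equal(nrow(tab$matrix), 3L)
  expect_true(all(tab$matrix > 0))
})

test_that("features outside the m/z tolerance stay separate rows", {
  r1 <- data.frame(run_id = "a", condition = "replete",
                   mz = 500.00, rt = 5, intensity = 1e4)
  r2 <- data.frame(run_id = "b", condition = "depleted",
                   mz = 500.05, rt = 5, intensity = 1e4)
  tab <- join_features(rbind(r1, r2), mz_abs = 0.01, mz_ppm = 20)
  expect_equal(nrow(tab$matrix), 2L)
  # within tolerance they merge
  r2$mz <- 500.008
  tab2 <- join_features(rbind(r1, r2), mz_abs = 0.01, mz_ppm = 20)
  expect_equal(nrow(tab2$matrix), 1L)
  # duplicate run id across condition labels errors
  r3 <- r2; r3$run_id <- "a"
  expect_error(join_features(rbind(r1, r3)), "duplicate run_id")
})

test_that("joining recovers the generator's ground-truth feature mapping", {
  ex <- simulate_experiment(demo_manifest(seed = 21, n_background = 60))
  tab <- join_features(ex$runs)
  truth <- ex$truth[ex$truth$n_detected > 0, ]
  expect_equal(nrow(tab$matrix), nrow(truth))
  # every truth feature matches exactly one consensus row within tolerance
  hits <- vapply(seq_len(nrow(truth)), function(i) {
    sum(abs(tab$features$mz - truth$mz[i]) <= 0.015 &
          abs(tab$features$rt - truth$rt[i]) <= 0.2)
  }, numeric(1))
  expect_true(all(hits == 1))
  # per-row detection counts agree with the censoring truth
  ord <- order(truth$mz)
  expect_equal(rowSums(tab$matrix > 0), truth$n_detected[ord],
               ignore_attr = TRUE)
})

test_that("join is idempotent on an already-joined consensus", {
  ex <- simulate_experiment(demo_manifest(seed = 22, n_background = 40))
  tab <- join_features(ex$runs)
  again <- data.frame(run_id = "joined", condition = "replete",
                      mz = tab$features$mz, rt = tab$features$rt,
                      intensity = rowSums(tab$matrix))
  tab2 <- join_features(again)
  expect_equal(nrow(tab2$matrix), nrow(tab$matrix))
  expect_equal(sort(tab2$features$mz), sort(tab$features$mz))
})

test_that("gap filling floors sub-noise cells, flags them, and is idempotent", {
  tab <- make_table(matrix(c(50, 100, 101), 3, 1),
                    matrix(c(200, 200, 200), 3, 1))
  out <- gap_fill_floor(tab, noise = 100)
  expect_equal(out$matrix[, 1], c(F0001 = 100, F0002 = 100, F0003 = 101))
  expect_equal(out$gap_filled[, 1], c(F0001 = TRUE, F0002 = FALSE,
                                      F0003 = FALSE))
  out2 <- gap_fill_floor(out, noise = 100)
  expect_identical(out2$matrix, out$matrix)
  expect_identical(out2$gap_filled, out$gap_filled)
})

test_that("differential statistics match the hand-computed pooled t-test", {
  tab <- make_table(matrix(c(1000, 1200, 1100), 1, 3),
                    matrix(c(100, 100, 100), 1, 3))
  d <- differential_stats(tab)
  expect_equal(d$fold_change, 11.0)
  expect_identical(d$direction, "depleted_without_halide")
  expect_equal(round(d$t_stat, 3), 17.321)
  expect_equal(d$df, 4)
  # dual route: stats::t.test as the independent implementation
  tt <- stats::t.test(c(1000, 1200, 1100), c(100, 100, 100),
                      var.equal = TRUE)
  expect_equal(d$t_stat, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(d$p_value, tt$p.value, tolerance = 1e-12)
})

test_that("degenerate and identical groups yield fold 1, p 1", {
  tab <- make_table(matrix(c(500, 500, 500, 100, 100, 100), 2, 3,
                           byrow = TRUE),
                    matrix(c(500, 500, 500, 100, 100, 100), 2, 3,
                           byrow = TRUE))
  d <- differential_stats(tab)
  expect_equal(d$fold_change, c(1, 1))
  expect_equal(d$p_value, c(1, 1))
  expect_identical(d$direction, c("unchanged", "unchanged"))
  expect_true(all(d$degenerate))
  # fewer than 2 samples per condition errors
  bad <- make_table(matrix(1000, 1, 1), matrix(100, 1, 2))
  expect_error(differential_stats(bad), "at least 2 samples")
})

test_that("swapping conditions preserves fold magnitude and flips direction", {
  set.seed(5)
  A <- matrix(10^stats::runif(60, 2, 6), 20, 3)
  B <- matrix(10^stats::runif(60, 2, 6), 20, 3)
  d1 <- differential_stats(make_table(A, B))
  d2 <- differential_stats(make_table(B, A))
  expect_equal(d1$fold_change, d2$fold_change)
  expect_equal(d1$p_value, d2$p_value)
  swapped <- d1$direction != "unchanged"
  expect_true(all(ifelse(d1$direction == "depleted_without_halide",
                         "enriched_without_halide",
                         "depleted_without_halide")[swapped] ==
                    d2$direction[swapped]))
  expect_equal(signed_fold_change(d1)[swapped], -signed_fold_change(d2)[swapped])
})

test_that("flooring censored depleted intensities only shrinks fold changes", {
  set.seed(6)
  for (i in 1:25) {
    rep_vals <- matrix(10^stats::runif(3, 3.5, 6), 1, 3)  # above the floor
    dep_vals <- matrix(10^stats::runif(3, 0.5, 3), 1, 3)  # some below 100
    raw <- differential_stats(make_table(rep_vals, dep_vals))
    floored <- differential_stats(gap_fill_floor(
      make_table(rep_vals, dep_vals), noise = 100))
    expect_lte(floored$fold_change, raw$fold_change + 1e-9)
  }
})

test_that("co-eluting adduct artifacts group together with the right parent", {
  runs <- data.frame(
    run_id = rep(c("replete_1", "replete_2"), each = 3),
    condition = "replete",
    mz = rep(c(555.3658, 572.3924, 300.10), 2),
    rt = rep(c(10.00, 10.01, 10.00), 2),
    intensity = rep(c(5e5, 1e5, 2e4), 2))
  tab <- join_features(runs)
  g <- artifact_group(tab, rt_window = 0.05)
  gid <- stats::setNames(g$group_id, sprintf("%.4f", tab$features$mz))
  expect_identical(gid[["555.3658"]], gid[["572.3924"]])
  expect_false(gid[["300.1000"]] == gid[["555.3658"]])
  expect_true(g$is_parent[tab$features$mz < 556 & tab$features$mz > 555])
  # 1 minute apart: no grouping
  runs2 <- runs; runs2$rt <- rep(c(10, 11, 10), 2)
  g2 <- artifact_group(join_features(runs2), rt_window = 0.1)
  expect_equal(length(unique(g2$group_id)), 3L)
})

test_that("null simulation keeps the t-test type-I error near nominal", {
  # planted null: no condition effect, log-normal CV 0.2, 3 vs 3
  ex <- simulate_experiment(null_manifest(2000, seed = 11))
  tab <- gap_fill_floor(join_features(ex$runs))
  d <- differential_stats(tab)
  fpr <- mean(d$p_value < 0.05)
  expect_gte(fpr, 0.03)
  expect_lte(fpr, 0.07)
})
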