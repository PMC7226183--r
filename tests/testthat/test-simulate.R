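test_that("simulate_truth honours degenerate and clustered phase modes", {
  t0 <- simulate_truth(100, frac_rhythmic = 0, seed = 1)
  expect_false(any(t0$is_rhythmic))
  expect_true(all(t0$relamp_true == 0))
  expect_true(all(is.na(t0$phase_true)))

  t1 <- simulate_truth(10, frac_rhythmic = 1,
                       phase_mode = phase_clustered(6, 0), seed = 1)
  expect_true(all(t1$is_rhythmic))
  expect_equal(t1$phase_true, rep(6, 10))
})

test_that("simulate_truth draws the exact rhythmic count and uniform phases", {
  truth <- simulate_truth(10000, frac_rhythmic = 0.2, seed = 1)
  expect_identical(sum(truth$is_rhythmic), 2000L)
  expect_false(anyDuplicated(truth$gene_id) > 0)
  # phases should pass the module's own circular uniformity test
  u <- truth$phase_true[truth$is_rhythmic] / 24
  V <- kuiper_statistic(u)
  expect_gt(kuiper_pvalue(V, length(u)), 0.01)
})

test_that("simulate_truth rejects invalid arguments", {
  expect_error(simulate_truth(10, frac_rhythmic = 1.2), "proportion")
  expect_error(simulate_truth(10, relamp_range = c(0, 0.5)), "relamp_range")
  expect_error(simulate_truth(10, relamp_range = c(0.6, 0.2)), "relamp_range")
})

test_that("noiseless intensity rendering matches the cosine closed form", {
  truth <- simulate_truth(2, frac_rhythmic = 0.5, seed = 3)
  truth$is_rhythmic <- c(TRUE, FALSE)
  truth$mesor_true <- c(100, 50)
  truth$relamp_true <- c(0.5, 0)
  truth$phase_true <- c(0, NA)
  em <- render_intensity(truth, platform_intensity(noise_sd = 0), seed = 1)
  expect_equal(unname(em$values[1, "MA_00h"]), log2(150))
  expect_equal(unname(em$values[1, "MA_12h"]), log2(50))
  # arrhythmic gene is flat across all time points
  expect_equal(diff(range(em$values[2, ])), 0)
  # wall-time replicate (24 h) equals 0 h circadianly when noiseless
  expect_equal(unname(em$values[1, "MA_24h"]), unname(em$values[1, "MA_00h"]))
})

test_that("emitted intensities respect the platform envelope", {
  truth <- simulate_truth(10000, frac_rhythmic = 0.2, seed = 2)
  em <- render_intensity(truth, platform_intensity(), seed = 2)
  expect_gte(min(em$values), 0)
  expect_lte(max(em$values), 13.5)
})

test_that("count rendering is integer, seeded, and linear in library size", {
  truth <- simulate_truth(500, frac_rhythmic = 0.2, seed = 4)
  p <- platform_counts()
  em1 <- render_counts(truth, p, seed = 9)
  em2 <- render_counts(truth, p, seed = 9)
  expect_identical(em1$values, em2$values)
  expect_true(all(em1$values == round(em1$values)))
  # doubling one library doubles that sample's expected total
  libs <- p$library_sizes
  libs[3] <- libs[3] * 2
  p2 <- platform_counts(library_sizes = libs)
  tot1 <- colSums(render_counts(truth, platform_counts(dispersion = 0),
                                seed = 5)$values)
  p2$dispersion <- 0
  tot2 <- colSums(render_counts(truth, p2, seed = 5)$values)
  expect_equal(unname(tot2[3] / tot1[3]), 2, tolerance = 0.01)
  expect_error(platform_counts(library_sizes = c(-1, rep(1e6, 10))),
               "positive")
})

test_that("count noise follows the stated negative-binomial moments", {
  # flat genes, equal libraries, many replicate draws: the moment estimator
  # of the variance should agree with mu + dispersion * mu^2 within 20%
  truth <- simulate_truth(30, frac_rhythmic = 0, seed = 6,
                          baseline_mean = 8, baseline_sd = 1)
  disp <- 0.05
  p <- platform_counts(time_grid = seq(0, 199) * 0.1, dispersion = disp,
                       library_sizes = 1e7)
  em <- render_counts(truth, p, seed = 7)
  mu_hat <- rowMeans(em$values)
  keep <- mu_hat > 50  # enough counts for stable moments
  v_hat <- apply(em$values[keep, ], 1, var)
  v_exp <- mu_hat[keep] + disp * mu_hat[keep]^2
  expect_lt(median(abs(v_hat / v_exp - 1)), 0.2)
})

test_that("counts track the closed-form cosine mean at low dispersion", {
  truth <- simulate_truth(50, frac_rhythmic = 1, seed = 8,
                          relamp_range = c(0.3, 0.3), baseline_mean = 9,
                          baseline_sd = 0.5)
  p <- platform_counts(dispersion = 0, library_sizes = 1e7)
  reps <- lapply(1:50, function(s) render_counts(truth, p, seed = s)$values)
  mean_obs <- Reduce(`+`, reps) / length(reps)
  rel <- truth$mesor_true %o% rep(1, length(p$time_grid)) *
    (1 + truth$relamp_true *
       cos(outer(-2 * pi * truth$phase_true / 24, 2 * pi * p$time_grid / 24,
                 `+`))) / sum(truth$mesor_true)
  mu <- rel * 1e7
  # chi-square goodness of fit of the 50-draw means against mu (Poisson)
  z <- (mean_obs - mu) / sqrt(mu / 50)
  chi <- sum(z^2)
  expect_gt(pchisq(chi, df = length(z), lower.tail = FALSE), 0.01)
})

test_that("simulate_gene_sets labels and windows are honoured", {
  truth <- simulate_truth(3000, frac_rhythmic = 0.5, seed = 10)
  gs0 <- simulate_gene_sets(truth, n_sets = 5, n_clustered = 0, seed = 1)
  expect_true(all(gs0$label == "null"))

  gs <- simulate_gene_sets(truth, n_sets = 50, n_clustered = 10,
                           set_size = 20, window_h = 0.5, seed = 2)
  expect_identical(sum(gs$label == "clustered"), 10L)
  for (nm in names(gs)[gs$label == "clustered"]) {
    center <- as.numeric(sub(".*center=([0-9.]+).*", "\\1",
                             gs$description[[nm]]))
    ph <- truth$phase_true[match(gs$sets[[nm]], truth$gene_id)]
    expect_true(all(circular_distance(ph, center) <= 0.25 + 1e-9))
  }
  # impossible window is rejected with the window reported
  tiny <- simulate_truth(40, frac_rhythmic = 0.5, seed = 3)
  expect_error(
    simulate_gene_sets(tiny, n_sets = 2, n_clustered = 1, set_size = 10,
                       window_h = 0.5, seed = 4),
    "window")
})

test_that("identical seeds give byte-identical simulations", {
  a <- simulate_truth(200, seed = 42)
  b <- simulate_truth(200, seed = 42)
  expect_identical(a, b)
  ia <- render_intensity(a, seed = 42)
  ib <- render_intensity(b, seed = 42)
  expect_identical(ia, ib)
})
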