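test_that("fit_tdm reproduces direct quartile arithmetic on uniform grids", {
  ref <- seq(0, 13.5, length.out = 1000)
  tgt <- seq(-8, 15, length.out = 1000)
  ref_em <- expression_matrix(
    matrix(ref, 50, 20, dimnames = list(paste0("g", 1:50), paste0("r", 1:20))),
    time_h = 1:20, platform = "ma", scale = "log2-intensity")
  tgt_em <- expression_matrix(
    matrix(tgt, 50, 20, dimnames = list(paste0("g", 1:50), paste0("t", 1:20))),
    time_h = 1:20, platform = "rs", scale = "log2-cpm")
  p <- fit_tdm(ref_em, tgt_em)
  # oracle: quartiles of the two uniform grids
  rq <- quantile(ref, c(0.25, 0.75), names = FALSE)
  tq <- quantile(tgt, c(0.25, 0.75), names = FALSE)
  expect_equal(p$spread_low, (rq[1] - 0) / (rq[2] - rq[1]))
  expect_equal(p$spread_low, p$spread_high, tolerance = 1e-9)
  # clamp bounds symmetric around the target median
  expect_equal(mean(c(p$clamp_low, p$clamp_high)), median(tgt),
               tolerance = 1e-9)

  degenerate <- tgt_em
  degenerate$values[] <- 1
  expect_error(fit_tdm(ref_em, degenerate), "degenerate")
  expect_error(fit_tdm(degenerate, tgt_em), "degenerate")
})

test_that("apply_tdm is a monotone map with exact endpoint behaviour", {
  study <- make_small_study(n_genes = 500, seed = 31L)
  ma <- preprocess_intensity(study$ma)
  rs <- preprocess_counts(study$rs)$log_cpm
  genes <- intersect(rownames(ma$values), rownames(rs$values))
  p <- fit_tdm(ma[genes, ], rs[genes, ])
  out <- apply_tdm(rs[genes, ], p)
  # monotone: Spearman correlation 1 up to clamping ties
  expect_equal(cor(as.numeric(rs[genes, ]$values), as.numeric(out$values),
                   method = "spearman"), 1, tolerance = 1e-6)
  ix <- order(as.numeric(rs[genes, ]$values))
  expect_true(all(diff(as.numeric(out$values)[ix]) >= -1e-12))
  # values at the clamp bounds map to the reference extremes
  tv <- rs[genes, ]
  tv$values[1, 1] <- p$clamp_low - 5
  tv$values[2, 1] <- p$clamp_high + 5
  out2 <- apply_tdm(tv, p)
  expect_equal(unname(out2$values[1, 1]), p$ref_min)
  expect_equal(unname(out2$values[2, 1]), p$ref_max)
  expect_equal(min(out2$values), p$ref_min)
  expect_equal(max(out2$values), p$ref_max)
})

test_that("TDM moves the count platform's distribution toward the reference", {
  study <- make_small_study(n_genes = 1500, seed = 32L)
  ma <- preprocess_intensity(study$ma)
  rs <- preprocess_counts(study$rs)$log_cpm
  genes <- intersect(rownames(ma$values), rownames(rs$values))
  p <- fit_tdm(ma[genes, ], rs[genes, ])
  before <- ks_distance(ma[genes, ], rs[genes, ])
  after <- ks_distance(ma[genes, ], apply_tdm(rs[genes, ], p))
  expect_lt(after, before)
})

test_that("self-matching TDM is monotone with full rank preservation", {
  study <- make_small_study(n_genes = 300, seed = 33L)
  ma <- preprocess_intensity(study$ma)
  p <- fit_tdm(ma, ma)
  expect_lte(p$clamp_low, min(ma$values) + 1e-9)
  expect_gte(p$clamp_high, max(ma$values) - 1e-9)
  matched <- ma
  matched$scale <- "log2-cpm"
  out <- apply_tdm(matched, p)
  expect_equal(cor(as.numeric(ma$values), as.numeric(out$values),
                   method = "spearman"), 1)
})

test_that("normalize_to_shared divides each gene by its shared-window mean", {
  m <- rbind(g1 = c(1, 2, 4, 8), g2 = rep(3, 4))
  colnames(m) <- paste0("s", 1:4)
  em <- expression_matrix(m, time_h = c(0, 12, 24, 36), platform = "x",
                          scale = "linear")
  out <- normalize_to_shared(em, c(12, 24))
  # g1 shared-window values {2, 4}: divided by 3
  expect_equal(unname(out$values["g1", ]), c(1, 2, 4, 8) / 3)
  expect_equal(mean(out$values["g1", 2:3]), 1, tolerance = 1e-12)
  # constant gene becomes all ones
  expect_equal(unname(out$values["g2", ]), rep(1, 4))
  expect_identical(out$scale, "linear-normalized")

  # log2 input is de-logged first
  em2 <- expression_matrix(log2(m), time_h = c(0, 12, 24, 36), platform = "x",
                           scale = "log2-intensity")
  expect_equal(normalize_to_shared(em2, c(12, 24))$values, out$values)

  expect_error(normalize_to_shared(em, c(100, 200)), "no samples")
})

test_that("both platforms have per-gene shared-window mean one", {
  study <- make_small_study(n_genes = 400, seed = 34L)
  ma <- preprocess_intensity(study$ma)
  rs <- preprocess_counts(study$rs)$log_cpm
  h <- harmonize_platforms(ma, rs)
  for (em in list(h$ref_norm, h$target_norm)) {
    win <- em$time_h >= 12 & em$time_h <= 24
    mu <- rowMeans(em$values[, win, drop = FALSE])
    expect_lt(max(abs(mu - 1)), 1e-9)
  }
})

test_that("concatenation pools the designs with doubled shared times", {
  study <- make_small_study(n_genes = 400, seed = 35L)
  ma <- preprocess_intensity(study$ma)
  rs <- preprocess_counts(study$rs)$log_cpm
  h <- harmonize_platforms(ma, rs)
  cc <- h$concat
  expect_identical(ncol(cc$values), 20L)
  expect_equal(sort(unique(cc$time_h)), seq(0, 42, by = 3))
  reps <- table(cc$time_h)
  expect_true(all(reps[as.character(seq(12, 24, by = 3))] == 2))
  expect_true(all(reps[as.character(seq(0, 9, by = 3))] == 1))
  # gene universes intersect
  a <- h$ref_norm; b <- h$target_norm
  expect_setequal(rownames(cc$values),
                  intersect(rownames(a$values), rownames(b$values)))
})

test_that("concatenating a series with itself leaves the cosinor fit alone", {
  t <- seq(0, 42, by = 3)
  y <- 10 + 3 * cos(2 * pi * (t - 8) / 24) + 0.3 * sin(2 * pi * t / 5)
  em <- expression_matrix(matrix(y, 1, dimnames = list("g1", paste0("s", t))),
                          time_h = t, platform = "x", scale = "linear")
  n1 <- normalize_to_shared(em)
  n2 <- n1
  colnames(n2$values) <- paste0("dup_", colnames(n2$values))
  names(n2$time_h) <- names(n2$platform) <- colnames(n2$values)
  cc <- concatenate_series(n1, n2)
  f1 <- harmonic_fit(n1$values[1, ], n1$time_h)
  f2 <- harmonic_fit(cc$values[1, ], cc$time_h)
  expect_equal(f2$mesor, f1$mesor, tolerance = 1e-12)
  expect_equal(f2$amplitude, f1$amplitude, tolerance = 1e-12)
  expect_equal(f2$phase_h, f1$phase_h, tolerance = 1e-12)

  em2 <- n1
  rownames(em2$values) <- "other"
  expect_error(concatenate_series(n1, em2), "disjoint")
})
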