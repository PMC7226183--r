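make_em <- function(m, scale = "counts", time = NULL) {
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  if (is.null(time)) time <- seq(0, by = 3, length.out = ncol(m))
  expression_matrix(m, time_h = time, platform = "test", scale = scale)
}

test_that("collapse_features keeps the highest-mean feature per gene", {
  m <- rbind(f1 = c(5, 5, 5), f2 = c(7, 7, 7), f3 = c(1, 1, 1))
  em <- make_em(m, scale = "log2-intensity")
  map <- data.frame(feature_id = c("f1", "f2", "f3"),
                    gene_id = c("G", "G", "H"))
  out <- collapse_features(em, map)
  expect_equal(out$values["G", ], c(s1 = 7, s2 = 7, s3 = 7))
  expect_setequal(rownames(out$values), c("G", "H"))

  # one feature per gene: identity up to renaming
  map1 <- data.frame(feature_id = c("f1", "f2", "f3"),
                     gene_id = c("A", "B", "C"))
  out1 <- collapse_features(em, map1)
  expect_equal(unname(out1$values), unname(m))

  expect_error(collapse_features(em, map[0, ]), "non-empty")
})

test_that("collapse_features breaks mean ties lexicographically", {
  # oracle: exhaustive comparison on a 3-feature toy with tied means
  m <- rbind(fB = c(4, 6), fA = c(6, 4), fC = c(5, 5))
  em <- make_em(m, scale = "log2-intensity")
  map <- data.frame(feature_id = c("fB", "fA", "fC"),
                    gene_id = rep("G", 3))
  means <- rowMeans(m)
  winners <- names(means)[means == max(means)]
  expect_identical(sort(winners)[1], "fA")  # the oracle's pick
  out <- collapse_features(em, map)
  expect_equal(unname(out$values["G", ]), unname(m["fA", ]))
})

test_that("TMM factors are centered and undo a pure scaling shift", {
  m <- matrix(rpois(400 * 2, 100), ncol = 2)
  m <- cbind(m[, 1], m[, 1])  # identical samples
  colnames(m) <- c("s1", "s2")
  rownames(m) <- paste0("g", 1:400)
  em <- make_em(m)
  f <- tmm_factors(em)
  expect_equal(unname(f$factors), c(1, 1))

  # sample B = 2 x sample A genewise: CPM with TMM factors equalizes them
  withr::with_seed(5, a <- rpois(500, 200))
  m2 <- cbind(s1 = a, s2 = 2L * a)
  rownames(m2) <- paste0("g", 1:500)
  em2 <- make_em(m2)
  f2 <- tmm_factors(em2)
  expect_equal(exp(mean(log(f2$factors))), 1, tolerance = 1e-9)
  cpm <- sweep(m2, 2, f2$effective_lib_size, `/`) * 1e6
  expect_equal(cpm[, 1], cpm[, 2], tolerance = 1e-9)

  bad <- make_em(cbind(s1 = c(1L, 2L), s2 = c(0L, 0L)))
  expect_error(tmm_factors(bad), "all-zero")
})

test_that("log_cpm matches the closed form and the edgeR convention", {
  m <- matrix(c(1000L, 999000L, 2000L, 1998000L), ncol = 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  em <- make_em(m)
  f <- tmm_factors(em)
  lc0 <- log_cpm(em, f, prior_count = 0)
  expect_equal(unname(lc0$values["g1", "s1"]), log2(1000), tolerance = 1e-9)
  # doubling every count and the library leaves log CPM unchanged
  expect_equal(lc0$values[, 1], lc0$values[, 2], tolerance = 1e-9)

  # zero counts stay finite with a pseudo-count
  m2 <- matrix(rpois(100, 50), ncol = 4,
               dimnames = list(paste0("g", 1:25), paste0("s", 1:4)))
  m2[1, 1] <- 0L
  em2 <- make_em(m2)
  f2 <- tmm_factors(em2)
  lc <- log_cpm(em2, f2, prior_count = 0.5)
  expect_true(all(is.finite(lc$values)))
  # cross-check against edgeR's implementation of the same convention
  ref <- edgeR::cpm(edgeR::DGEList(m2, norm.factors = unname(f2$factors)),
                    log = TRUE, prior.count = 0.5)
  expect_equal(unname(lc$values), unname(ref), tolerance = 1e-8)

  expect_error(log_cpm(em2, f2, prior_count = -1), "non-negative")
})

test_that("log CPM columns resum to one million without a pseudo-count", {
  m <- matrix(rpois(2000, 80), ncol = 4,
              dimnames = list(paste0("g", 1:500), paste0("s", 1:4)))
  m[, 2] <- m[, 1]; m[, 3] <- m[, 1]; m[, 4] <- m[, 1]  # factors = 1
  em <- make_em(m)
  lc <- log_cpm(em, tmm_factors(em), prior_count = 0)
  expect_equal(unname(colSums(2^lc$values)), rep(1e6, 4), tolerance = 1e-3)
})

test_that("filter_expressed is boundary-inclusive on the mean", {
  # the rule is scale-agnostic: per-gene means 0.4 / 0.5 / 0.6, cutoff 0.5
  cp <- rbind(gA = c(0.3, 0.4, 0.5), gB = c(0.5, 0.5, 0.5),
              gC = c(0.6, 0.6, 0.6))
  colnames(cp) <- paste0("s", 1:3)
  emc <- make_em(cp, scale = "linear")
  kept <- filter_expressed(emc, 0.5)
  expect_setequal(rownames(kept$values), c("gB", "gC"))

  # -Inf cutoff is the identity
  expect_identical(rownames(filter_expressed(emc, -Inf)$values),
                   rownames(cp))
  # removing everything is an error
  expect_error(filter_expressed(emc, 10), "removed all")

  # intensity rule: mean log2 intensity >= 3, inclusive
  mi <- rbind(lo = rep(2.9, 4), at = rep(3, 4), hi = rep(5, 4))
  colnames(mi) <- paste0("s", 1:4)
  emi <- make_em(mi, scale = "log2-intensity")
  expect_setequal(rownames(preprocess_intensity(emi, 3)$values),
                  c("at", "hi"))
})

test_that("counts are filtered on mean CPM and renormalized on survivors", {
  study <- make_small_study(n_genes = 600, seed = 21L)
  pp <- preprocess_counts(study$rs, cpm_cutoff = 0.5)
  # every retained gene clears the cut-off under its own (recomputed) factors
  cpm <- sweep(pp$counts$values, 2, pp$factors$effective_lib_size, `/`) * 1e6
  # recomputation can move borderline genes slightly; a second pass should
  # remove (almost) nothing
  expect_gte(min(rowMeans(cpm)), 0.4)
  expect_identical(pp$log_cpm$scale, "log2-cpm")
})

test_that("filtering with renormalization is stable on reseeded data", {
  # over 20 seeds, a second filter+renormalize pass removes no further genes
  stable <- vapply(1:20, function(s) {
    truth <- simulate_truth(800, frac_rhythmic = 0.2, seed = s,
                            baseline_mean = 5, baseline_sd = 2.5)
    rs <- render_counts(truth, platform_counts(library_sizes = 5e6),
                        seed = s + 100)
    p1 <- preprocess_counts(rs, cpm_cutoff = 0.5)
    p2 <- preprocess_counts(p1$counts, cpm_cutoff = 0.5)
    nrow(p2$counts$values) == nrow(p1$counts$values)
  }, logical(1))
  expect_gte(mean(stable), 0.99)
})
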