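# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: explicit normal equations for the cosinor fit,
# brute-force ECDF scans for Kuiper, direct quartile arithmetic for TDM.

# cosinor oracle: solve the 3-parameter normal equations directly and form
# the F-test against the intercept-only model
oracle_cosinor <- function(y, t, period = 24) {
  w <- 2 * pi / period
  X <- cbind(1, cos(w * t), sin(w * t))
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  n <- length(y)
  Fstat <- ((tss - rss) / 2) / (rss / (n - 3))
  list(m = beta[1], a = beta[2], b = beta[3],
       A = sqrt(beta[2]^2 + beta[3]^2),
       phase = (atan2(beta[3], beta[2]) * period / (2 * pi)) %% period,
       F = Fstat, p = pf(Fstat, 2, n - 3, lower.tail = FALSE))
}

# Kuiper oracle: supremum of (ECDF - U) and (U - ECDF) scanned over a dense
# grid plus the sample points themselves (the suprema occur at jumps)
oracle_kuiper <- function(u) {
  n <- length(u)
  grid <- sort(unique(c(u, seq(0, 1, length.out = 2001))))
  Fhat <- ecdf(u)
  dplus <- max(Fhat(grid) - grid)
  # D- : approached just below each jump point
  eps <- 1e-12
  dminus <- max(grid - Fhat(pmax(grid - eps, 0)))
  dplus + dminus
}

# small deterministic two-platform dataset built from a fixed truth
make_small_study <- function(n_genes = 400, frac_rhythmic = 0.3, seed = 11L,
                             noise_sd = 0.15, dispersion = 0.05) {
  truth <- simulate_truth(n_genes, frac_rhythmic, seed = seed)
  list(truth = truth,
       ma = render_intensity(truth, platform_intensity(noise_sd = noise_sd),
                             seed = seed + 1L),
       rs = render_counts(truth, platform_counts(dispersion = dispersion),
                          seed = seed + 2L))
}

# rhythm table built directly from truth (for enrichment tests the fit
# stage is irrelevant; truth phases stand in for fitted phases)
fits_from_truth <- function(truth) {
  data.frame(gene_id = truth$gene_id,
             phase_h = ifelse(truth$is_rhythmic, truth$phase_true, NA_real_),
             relamp = truth$relamp_true,
             significant = truth$is_rhythmic,
             stringsAsFactors = FALSE)
}
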