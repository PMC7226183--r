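#' Phase distribution specifications for the simulator
#'
#' `phase_uniform()` draws peak times uniformly on the 24-h circle;
#' `phase_clustered(center_h, sd_h)` draws them from a normal distribution
#' around `center_h` (hours) with standard deviation `sd_h`, wrapped into
#' `[0, 24)`.
#'
#' @param center_h Cluster center in hours.
#' @param sd_h Cluster standard deviation in hours (`>= 0`).
#' @return A phase-mode object consumed by [simulate_truth()].
#' @export
phase_uniform <- function() {
  structure(list(mode = "uniform"), class = "phase_mode")
}

#' @rdname phase_uniform
#' @export
phase_clustered <- function(center_h, sd_h) {
  stopifnot(is.finite(center_h), is.finite(sd_h), sd_h >= 0)
  structure(list(mode = "clustered", center_h = center_h, sd_h = sd_h),
            class = "phase_mode")
}

#' Simulate ground-truth rhythm parameters for a synthetic transcriptome
#'
#' Draws, per gene, a baseline log2 abundance, a rhythmicity flag, a relative
#' amplitude and a peak phase. The rhythmic signal model downstream is a pure
#' 24-h cosine on the linear scale,
#' `s(t) = mesor * (1 + relamp * cos(2*pi*(t - phase)/24))`,
#' so the truth table holds exactly the parameters the cosinor fit estimates.
#'
#' Baseline log2 abundances are drawn from a normal distribution (default
#' mean 7, sd 2, clamped to `[0.5, 13]`), spanning the dynamic range typical
#' of log2 microarray intensities; `mesor_true = 2^baseline`.
#'
#' @param n_genes Number of genes (`>= 1`).
#' @param frac_rhythmic Fraction of genes carrying a 24-h rhythm, in
#'   `[0, 1]`; exactly `round(n_genes * frac_rhythmic)` genes are flagged.
#' @param phase_mode [phase_uniform()] or [phase_clustered()].
#' @param relamp_range Two-element range `[lo, hi]` of relative amplitudes,
#'   `0 < lo <= hi <= 1`; rhythmic genes draw uniformly from it.
#' @param baseline_mean,baseline_sd Normal parameters of the baseline log2
#'   abundance.
#' @param seed Integer seed; identical arguments and seed give identical
#'   output.
#' @return A `data.frame` of class `SyntheticTruth` with columns `gene_id`,
#'   `is_rhythmic`, `mesor_true`, `relamp_true`, `phase_true` (`NA` for
#'   arrhythmic genes), `baseline_log_abundance`.
#' @examples
#' truth <- simulate_truth(100, frac_rhythmic = 0.2, seed = 1)
#' table(truth$is_rhythmic)
#' @export
simulate_truth <- function(n_genes,
                           frac_rhythmic = 0.2,
                           phase_mode = phase_uniform(),
                           relamp_range = c(0.2, 0.6),
                           baseline_mean = 7,
                           baseline_sd = 2,
                           seed = 1L) {
  stopifnot(n_genes >= 1)
  if (!is.numeric(frac_rhythmic) || frac_rhythmic < 0 || frac_rhythmic > 1)
    stop("`frac_rhythmic` must be a proportion in [0, 1]")
  if (length(relamp_range) != 2 || relamp_range[1] <= 0 ||
      relamp_range[1] > relamp_range[2] || relamp_range[2] > 1)
    stop("`relamp_range` must satisfy 0 < lo <= hi <= 1")
  if (!inherits(phase_mode, "phase_mode"))
    stop("`phase_mode` must be phase_uniform() or phase_clustered()")

  n_rhythmic <- round(n_genes * frac_rhythmic)
  withr::with_seed(as.integer(seed), {
    gene_id <- sprintf("g%0*d", nchar(n_genes), seq_len(n_genes))
    baseline <- pmin(pmax(stats::rnorm(n_genes, baseline_mean, baseline_sd),
                          0.5), 13)
    is_rhythmic <- rep(FALSE, n_genes)
    is_rhythmic[sample.int(n_genes, n_rhythmic)] <- TRUE
    relamp <- numeric(n_genes)
    relamp[is_rhythmic] <- stats::runif(n_rhythmic, relamp_range[1],
                                        relamp_range[2])
    phase <- rep(NA_real_, n_genes)
    if (n_rhythmic > 0) {
      phase[is_rhythmic] <- switch(
        phase_mode$mode,
        uniform = stats::runif(n_rhythmic, 0, 24),
        clustered = (stats::rnorm(n_rhythmic, phase_mode$center_h,
                                  phase_mode$sd_h)) %% 24)
    }
    structure(
      data.frame(gene_id = gene_id,
                 is_rhythmic = is_rhythmic,
                 mesor_true = 2^baseline,
                 relamp_true = relamp,
                 phase_true = phase,
                 baseline_log_abundance = baseline,
                 stringsAsFactors = FALSE),
      class = c("SyntheticTruth", "data.frame"))
  })
}

#' Platform profiles for the two simulated measurement technologies
#'
#' `platform_intensity()` describes a microarray-like platform: log2
#' fluorescence intensities bounded to a fixed range (default `[0, 13.5]`)
#' with additive Gaussian noise on the log2 scale, sampled 0-24 h every 3 h
#' (nine samples; the 24-h sample replicates 0 h circadianly).
#' `platform_counts()` describes an RNA-seq-like platform: negative-binomial
#' read counts with per-sample library sizes, sampled 12-42 h every 3 h
#' (eleven samples; 36/39/42 h replicate 12/15/18 h circadianly).
#'
#' @param time_grid Sampling times in hours, strictly increasing (default
#'   3-h steps over the platform's window).
#' @param noise_sd Standard deviation of the additive Gaussian noise on log2
#'   intensities (default 0.15).
#' @param intensity_range Two-element log2 clamp range of emitted
#'   intensities (default `c(0, 13.5)`).
#' @param dispersion Negative-binomial dispersion (variance =
#'   `mu + dispersion * mu^2`; default 0.05; 0 gives Poisson noise).
#' @param library_sizes Expected total read count per sample; scalar or one
#'   per time point (default `2e7`); must be positive.
#' @return A `PlatformProfile` list with element `kind` equal to
#'   `"intensity"` or `"counts"`.
#' @export
platform_intensity <- function(time_grid = seq(0, 24, by = 3),
                               noise_sd = 0.15,
                               intensity_range = c(0, 13.5)) {
  stopifnot(all(diff(time_grid) > 0), noise_sd >= 0,
            length(intensity_range) == 2,
            intensity_range[1] < intensity_range[2])
  structure(list(kind = "intensity", time_grid = time_grid,
                 noise_sd = noise_sd, intensity_range = intensity_range),
            class = "PlatformProfile")
}

#' @rdname platform_intensity
#' @export
platform_counts <- function(time_grid = seq(12, 42, by = 3),
                            dispersion = 0.05,
                            library_sizes = 2e7) {
  stopifnot(all(diff(time_grid) > 0), dispersion >= 0)
  if (length(library_sizes) == 1L)
    library_sizes <- rep(library_sizes, length(time_grid))
  if (length(library_sizes) != length(time_grid))
    stop("`library_sizes` must be scalar or one per time point")
  if (any(library_sizes <= 0))
    stop("`library_sizes` must be positive")
  structure(list(kind = "counts", time_grid = time_grid,
                 dispersion = dispersion, library_sizes = library_sizes),
            class = "PlatformProfile")
}

.sample_ids <- function(prefix, t) {
  if (all(t == round(t))) sprintf("%s_%02dh", prefix, as.integer(t))
  else sprintf("%s_%gh", prefix, t)
}

# noiseless linear signal, genes x times
.truth_signal <- function(truth, time_grid) {
  ph <- ifelse(truth$is_rhythmic, truth$phase_true, 0)
  osc <- outer(2 * pi * ph / 24, 2 * pi * time_grid / 24,
               function(p, wt) cos(wt - p))
  truth$mesor_true * (1 + truth$relamp_true * osc)
}

#' Render synthetic truth as a bounded log2-intensity matrix
#'
#' Each gene's noiseless linear signal
#' `s(t) = mesor * (1 + relamp * cos(2*pi*(t - phase)/24))` is log2-
#' transformed, Gaussian noise is added, and the result is clamped into the
#' platform's intensity range. Samples at circadianly equivalent wall times
#' (e.g. 24 h vs 0 h) share the same signal but receive independent noise.
#'
#' @param truth A [simulate_truth()] table.
#' @param profile A [platform_intensity()] profile.
#' @param seed Integer seed.
#' @return An [expression_matrix()] on scale `"log2-intensity"` with sample
#'   ids `MA_00h`, `MA_03h`, ...
#' @export
render_intensity <- function(truth, profile = platform_intensity(),
                             seed = 1L) {
  stopifnot(inherits(truth, "SyntheticTruth"),
            inherits(profile, "PlatformProfile"))
  if (profile$kind != "intensity")
    stop("`profile` must be of kind 'intensity'")
  sig <- .truth_signal(truth, profile$time_grid)
  withr::with_seed(as.integer(seed), {
    noise <- matrix(stats::rnorm(length(sig), 0, profile$noise_sd),
                    nrow = nrow(sig))
    v <- pmin(pmax(log2(sig) + noise, profile$intensity_range[1]),
              profile$intensity_range[2])
  })
  dimnames(v) <- list(truth$gene_id, .sample_ids("MA", profile$time_grid))
  expression_matrix(v, time_h = profile$time_grid, platform = "microarray",
                    scale = "log2-intensity")
}

#' Render synthetic truth as a negative-binomial count matrix
#'
#' Per gene and sample, the expected count is
#' `library_size * s(t) / sum(mesor)`: sampling a library proportionally to
#' each gene's momentary linear abundance. Counts are drawn from a negative
#' binomial with the profile's dispersion (Poisson when dispersion is 0), so
#' the variance is `mu + dispersion * mu^2`.
#'
#' @inheritParams render_intensity
#' @param profile A [platform_counts()] profile.
#' @return An [expression_matrix()] on scale `"counts"` with sample ids
#'   `RS_12h`, `RS_15h`, ...
#' @export
render_counts <- function(truth, profile = platform_counts(), seed = 1L) {
  stopifnot(inherits(truth, "SyntheticTruth"),
            inherits(profile, "PlatformProfile"))
  if (profile$kind != "counts")
    stop("`profile` must be of kind 'counts'")
  sig <- .truth_signal(truth, profile$time_grid)
  rel <- sig / sum(truth$mesor_true)
  mu <- sweep(rel, 2, profile$library_sizes, `*`)
  withr::with_seed(as.integer(seed), {
    if (profile$dispersion == 0) {
      v <- matrix(stats::rpois(length(mu), lambda = mu), nrow = nrow(mu))
    } else {
      v <- matrix(stats::rnbinom(length(mu), mu = mu,
                                 size = 1 / profile$dispersion),
                  nrow = nrow(mu))
    }
  })
  dimnames(v) <- list(truth$gene_id, .sample_ids("RS", profile$time_grid))
  expression_matrix(v, time_h = profile$time_grid, platform = "rnaseq",
                    scale = "counts")
}

#' Simulate gene sets with and without circadian phase clustering
#'
#' Builds a labelled gene-set collection for validating phase set enrichment:
#' `n_clustered` positive sets draw their members from rhythmic genes whose
#' true phases fall inside a random window of width `window_h` on the 24-h
#' circle; the remaining sets draw members from all genes irrespective of
#' phase (their rhythmic members' phases are therefore uniform).
#'
#' @param truth A [simulate_truth()] table.
#' @param n_sets Total number of sets.
#' @param n_clustered Number of phase-clustered sets (`<= n_sets`).
#' @param set_size Members per set (`>= 5`, so sets can survive the
#'   enrichment size filter).
#' @param window_h Width in hours of the phase window of clustered sets.
#' @param seed Integer seed.
#' @return A [gene_set_collection()] whose `label` element marks each set
#'   `"clustered"` or `"null"`; clustered sets record their window center in
#'   the `description`.
#' @export
simulate_gene_sets <- function(truth, n_sets = 50, n_clustered = 10,
                               set_size = 20, window_h = 2, seed = 1L) {
  stopifnot(inherits(truth, "SyntheticTruth"),
            n_clustered <= n_sets, set_size >= 5, window_h > 0)
  rhythmic <- truth[truth$is_rhythmic, ]
  withr::with_seed(as.integer(seed), {
    sets <- vector("list", n_sets)
    labels <- c(rep("clustered", n_clustered),
                rep("null", n_sets - n_clustered))
    desc <- character(n_sets)
    for (k in seq_len(n_sets)) {
      if (labels[k] == "clustered") {
        center <- stats::runif(1, 0, 24)
        eligible <- rhythmic$gene_id[
          circular_distance(rhythmic$phase_true, center) <= window_h / 2]
        if (length(eligible) < set_size)
          stop(sprintf(
            "only %d rhythmic genes in the %.2f-h window around %.2f h (need %d)",
            length(eligible), window_h, center, set_size))
        sets[[k]] <- sample(eligible, set_size)
        desc[k] <- sprintf("clustered|center=%.3f|window=%.3f", center,
                           window_h)
      } else {
        sets[[k]] <- sample(truth$gene_id, set_size)
        desc[k] <- "null"
      }
    }
    names(sets) <- sprintf("set%03d", seq_len(n_sets))
    gene_set_collection(sets, description = stats::setNames(desc, names(sets)),
                        label = stats::setNames(labels, names(sets)))
  })
}

#' Write a simulated two-platform study to a directory
#'
#' Convenience wrapper used by the command-line interface: simulates truth,
#' renders both platforms, and writes the matrices, a combined sample sheet,
#' the truth table and (optionally) simulated gene sets as plain-text files.
#'
#' @inheritParams simulate_truth
#' @param out_dir Output directory (created if needed).
#' @param intensity_profile,counts_profile Platform profiles.
#' @param gene_sets Logical: also write simulated gene sets (`sets.gmt`)?
#' @return Invisibly, a named list of the written file paths.
#' @export
simulate_study <- function(out_dir, n_genes = 10000, frac_rhythmic = 0.2,
                           phase_mode = phase_uniform(),
                           relamp_range = c(0.2, 0.6),
                           intensity_profile = platform_intensity(),
                           counts_profile = platform_counts(),
                           gene_sets = FALSE, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  truth <- simulate_truth(n_genes, frac_rhythmic, phase_mode, relamp_range,
                          seed = seed)
  ma <- render_intensity(truth, intensity_profile, seed = seed + 1L)
  rs <- render_counts(truth, counts_profile, seed = seed + 2L)
  paths <- list(
    intensity = file.path(out_dir, "intensity.tsv"),
    counts = file.path(out_dir, "counts.tsv"),
    samples = file.path(out_dir, "samples.tsv"),
    truth = file.path(out_dir, "truth.tsv"))
  write_expression_matrix(ma, paths$intensity)
  write_expression_matrix(rs, paths$counts)
  ss <- rbind(
    data.frame(sample_id = colnames(ma$values), time_h = ma$time_h,
               platform = ma$platform, stringsAsFactors = FALSE),
    data.frame(sample_id = colnames(rs$values), time_h = rs$time_h,
               platform = rs$platform, stringsAsFactors = FALSE))
  utils::write.table(ss, paths$samples, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (gene_sets) {
    gs <- simulate_gene_sets(truth, seed = seed + 3L)
    paths$gene_sets <- file.path(out_dir, "sets.gmt")
    write_gmt(gs, paths$gene_sets)
  }
  invisible(paths)
}
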