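#' Default pipeline configuration
#'
#' Returns the configuration skeleton understood by [run_pipeline()]. The
#' pipeline runs in exactly one of two modes: `simulate` (generate a
#' two-platform synthetic study with known truth) or `files` (load TSV
#' matrices and a sample sheet from disk). Cut-offs default to the standard
#' analysis choices: mean CPM 0.5 and mean log2 intensity 3 for expression
#' filtering, `q < 0.05` with relative amplitude `>= 0.1` for rhythmicity,
#' and a 5-gene minimum for phase set enrichment.
#'
#' @param out_dir Output directory.
#' @param seed Integer master seed.
#' @return A nested configuration list.
#' @export
default_config <- function(out_dir = tempfile("circaweld_run_"), seed = 1L) {
  list(
    mode = "simulate",
    simulate = list(n_genes = 10000, frac_rhythmic = 0.2,
                    phase_mode = "uniform",
                    relamp_range = c(0.2, 0.6),
                    noise_sd = 0.15, dispersion = 0.05,
                    library_size = 2e7,
                    gene_sets = list(n_sets = 50, n_clustered = 10,
                                     set_size = 20, window_h = 2)),
    files = NULL,
    shared_window = c(12, 24),
    cutoffs = list(cpm = 0.5, intensity = 3, q = 0.05, relamp = 0.1,
                   min_genes = 5),
    candidate_lists = NULL,
    seed = as.integer(seed),
    out_dir = out_dir)
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file and merges it over [default_config()]; any field not
#' present in the file keeps its default.
#'
#' @param path Path to a YAML configuration file.
#' @return A configuration list for [run_pipeline()].
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  merge_into <- function(base, upd) {
    for (nm in names(upd)) {
      if (is.list(upd[[nm]]) && is.list(base[[nm]]))
        base[[nm]] <- merge_into(base[[nm]], upd[[nm]])
      else base[[nm]] <- upd[[nm]]
    }
    base
  }
  cfg <- merge_into(cfg, user)
  if (!is.null(user$files) && is.null(user$mode)) cfg$mode <- "files"
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

.validate_config <- function(config) {
  if (is.null(config$mode) ||
      !config$mode %in% c("simulate", "files"))
    stop("config `mode` must be 'simulate' or 'files'")
  has_sim <- !is.null(config$simulate)
  has_files <- !is.null(config$files)
  if (config$mode == "simulate" && has_files)
    stop("config must carry exactly one of a simulate block or file paths")
  if (config$mode == "files" && (!has_files || is.null(config$files$intensity)))
    stop("files mode needs files$intensity, files$counts, files$samples")
  cut <- config$cutoffs
  stopifnot(cut$q > 0, cut$q < 1, cut$relamp >= 0, cut$relamp <= 1,
            cut$min_genes >= 1)
  invisible(config)
}

.log_stage <- function(log, stage, msg) {
  line <- sprintf("[%s] %s", stage, msg)
  message(line)
  c(log, line)
}

#' Run the full cross-platform circadian analysis workflow
#'
#' Executes the stages in order: simulate or load the two platform
#' matrices; preprocess (expression filters, TMM/CPM on counts); harmonize
#' (TDM, shared-window normalization, concatenation); cosinor rhythmicity
#' on the intensity platform, the count platform and the concatenated
#' series; cross-platform correlation of circadian parameters; phase set
#' enrichment; optional candidate-list annotation; and, when truth is
#' available, recovery scoring. Every table is written as TSV (reports as
#' JSON) into `config$out_dir`, together with a `manifest.json` recording
#' the package version, seed, parameters and MD5 checksums of all outputs.
#' Reruns with an identical configuration are byte-identical.
#'
#' @param config A configuration list from [default_config()] /
#'   [load_config()] (or a path to a YAML file).
#' @return Invisibly, a result bundle: `fits_intensity`, `fits_counts`,
#'   `fits_concat`, `correlation`, `psea`, `candidates`, `recovery`,
#'   `tdm`, `manifest`, `log`.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- load_config(config)
  .validate_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  log <- character()

  truth <- NULL
  gene_sets <- NULL
  if (config$mode == "simulate") {
    sim <- config$simulate
    pm <- if (identical(sim$phase_mode, "uniform")) phase_uniform()
          else phase_clustered(sim$phase_mode$center_h, sim$phase_mode$sd_h)
    truth <- simulate_truth(sim$n_genes, sim$frac_rhythmic, pm,
                            relamp_range = as.numeric(sim$relamp_range),
                            seed = seed)
    ma_raw <- render_intensity(
      truth, platform_intensity(noise_sd = sim$noise_sd), seed = seed + 1L)
    rs_raw <- render_counts(
      truth, platform_counts(dispersion = sim$dispersion,
                             library_sizes = sim$library_size),
      seed = seed + 2L)
    if (!is.null(sim$gene_sets)) {
      gs <- sim$gene_sets
      gene_sets <- simulate_gene_sets(truth, n_sets = gs$n_sets,
                                      n_clustered = gs$n_clustered,
                                      set_size = gs$set_size,
                                      window_h = gs$window_h,
                                      seed = seed + 3L)
    }
    utils::write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    log <- .log_stage(log, "simulate",
                      sprintf("%d genes, %d rhythmic", nrow(truth),
                              sum(truth$is_rhythmic)))
  } else {
    fl <- config$files
    ma_raw <- read_expression_matrix(fl$intensity, fl$samples,
                                     scale = "log2-intensity")
    rs_raw <- read_expression_matrix(fl$counts, fl$samples, scale = "counts")
    if (!is.null(fl$truth)) {
      truth <- utils::read.delim(fl$truth, stringsAsFactors = FALSE)
      class(truth) <- c("SyntheticTruth", "data.frame")
    }
    if (!is.null(fl$gene_sets)) gene_sets <- read_gmt(fl$gene_sets)
    log <- .log_stage(log, "load",
                      sprintf("intensity %d x %d, counts %d x %d",
                              nrow(ma_raw$values), ncol(ma_raw$values),
                              nrow(rs_raw$values), ncol(rs_raw$values)))
  }
  write_expression_matrix(ma_raw, file.path(out_dir, "intensity.tsv"))
  write_expression_matrix(rs_raw, file.path(out_dir, "counts.tsv"))
  ss <- rbind(
    data.frame(sample_id = colnames(ma_raw$values), time_h = ma_raw$time_h,
               platform = ma_raw$platform, stringsAsFactors = FALSE),
    data.frame(sample_id = colnames(rs_raw$values), time_h = rs_raw$time_h,
               platform = rs_raw$platform, stringsAsFactors = FALSE))
  utils::write.table(ss, file.path(out_dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  cut <- config$cutoffs
  ma <- preprocess_intensity(ma_raw, cutoff = cut$intensity)
  rs <- preprocess_counts(rs_raw, cpm_cutoff = cut$cpm)
  log <- .log_stage(log, "preprocess",
                    sprintf("expressed genes: intensity %d/%d, counts %d/%d",
                            nrow(ma$values), nrow(ma_raw$values),
                            nrow(rs$log_cpm$values), nrow(rs_raw$values)))

  harm <- harmonize_platforms(ma, rs$log_cpm,
                              shared_window = as.numeric(config$shared_window))
  log <- .log_stage(log, "harmonize",
                    sprintf("%d common genes, %d concatenated samples",
                            nrow(harm$concat$values),
                            ncol(harm$concat$values)))
  jsonlite::write_json(unclass(harm$tdm),
                       file.path(out_dir, "tdm_params.json"),
                       auto_unbox = TRUE, digits = NA)

  common <- rownames(harm$concat$values)
  fits_ma <- rhythmicity_table(to_linear(ma[common, ]),
                               q_cut = cut$q, relamp_cut = cut$relamp)
  fits_rs <- rhythmicity_table(to_linear(rs$log_cpm[common, ]),
                               q_cut = cut$q, relamp_cut = cut$relamp)
  fits_cc <- rhythmicity_table(harm$concat, q_cut = cut$q,
                               relamp_cut = cut$relamp)
  write_rhythm_table(fits_ma, file.path(out_dir, "fits_intensity.tsv"))
  write_rhythm_table(fits_rs, file.path(out_dir, "fits_counts.tsv"))
  write_rhythm_table(fits_cc, file.path(out_dir, "fits_concat.tsv"))
  log <- .log_stage(log, "rhythm",
                    sprintf("significant genes: intensity %d, counts %d, concatenated %d",
                            sum(fits_ma$significant), sum(fits_rs$significant),
                            sum(fits_cc$significant)))

  correlation <- list(
    intensity_vs_counts = correlation_report(
      fits_ma, fits_rs, ma, rs$log_cpm,
      shared_window = as.numeric(config$shared_window)),
    intensity_vs_concat = correlation_report(fits_ma, fits_cc),
    counts_vs_concat = correlation_report(fits_rs, fits_cc))
  jsonlite::write_json(lapply(correlation, unclass),
                       file.path(out_dir, "correlation.json"),
                       auto_unbox = TRUE, digits = NA)
  log <- .log_stage(log, "corr",
                    sprintf("%d genes rhythmic on both platforms",
                            correlation$intensity_vs_counts$n_genes))

  psea <- NULL
  if (!is.null(gene_sets)) {
    psea <- run_psea(fits_cc, gene_sets, min_genes = cut$min_genes,
                     q_cut = cut$q)
    utils::write.table(psea, file.path(out_dir, "psea.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    log <- .log_stage(log, "psea",
                      sprintf("%d/%d sets tested, %d enriched",
                              sum(psea$tested), nrow(psea),
                              sum(psea$enriched)))
  }

  candidates <- NULL
  if (!is.null(config$candidate_lists)) {
    lists <- lapply(config$candidate_lists, function(x) {
      if (length(x) == 1 && file.exists(x)) readLines(x) else as.character(x)
    })
    candidates <- annotate_candidates(
      list(intensity = fits_ma, counts = fits_rs, concat = fits_cc), lists)
    utils::write.table(candidates, file.path(out_dir, "candidates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log <- .log_stage(log, "annotate",
                      sprintf("%d unique candidate genes", nrow(candidates)))
  }

  recovery <- NULL
  if (!is.null(truth)) {
    recovery <- recovery_report(truth, fits_cc, missing_as_null = TRUE)
    jsonlite::write_json(recovery, file.path(out_dir, "recovery.json"),
                         auto_unbox = TRUE, digits = NA)
    log <- .log_stage(log, "recovery",
                      sprintf("sensitivity %.3f, FDR %.3f",
                              recovery$sensitivity, recovery$fdr))
  }

  writeLines(log, file.path(out_dir, "pipeline.log"))
  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    package = "circaweld",
    version = as.character(utils::packageVersion("circaweld")),
    seed = seed,
    mode = config$mode,
    cutoffs = cut,
    shared_window = as.numeric(config$shared_window),
    checksums = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out_dir, files))), files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(fits_intensity = fits_ma, fits_counts = fits_rs,
                 fits_concat = fits_cc, correlation = correlation,
                 psea = psea, candidates = candidates, recovery = recovery,
                 tdm = harm$tdm, concat = harm$concat, truth = truth,
                 manifest = manifest, log = log, out_dir = out_dir))
}

#' Annotate rhythmic genes against named candidate gene lists
#'
#' Intersects the significantly rhythmic genes of one or more rhythmicity
#' tables with user-supplied gene lists (e.g. cancer hallmark genes, drug
#' targets, disease genes, clock network members) and merges the hits into
#' one table: one row per unique gene carrying all matching list tags plus
#' the per-dataset significance flag and phase. A `summary` attribute
#' reports per-list hit counts and the unique total (so e.g. two lists of
#' 55 and 39 hits sharing 2 genes merge to 92 unique candidates).
#'
#' @param fits_per_dataset Named list of [rhythmicity_table()] results.
#' @param lists Named list of character vectors of gene ids.
#' @return A `data.frame` with columns `gene_id`, `lists`, and
#'   `significant_<dataset>` / `phase_<dataset>` per dataset; attribute
#'   `summary` holds the counting arithmetic.
#' @export
annotate_candidates <- function(fits_per_dataset, lists) {
  stopifnot(is.list(fits_per_dataset), length(fits_per_dataset) >= 1,
            !is.null(names(fits_per_dataset)))
  if (!is.list(lists) || length(lists) == 0 || is.null(names(lists)))
    stop("`lists` must be a non-empty named list of gene id vectors")
  sig_any <- unique(unlist(lapply(fits_per_dataset,
                                  function(f) f$gene_id[f$significant])))
  universe <- unique(unlist(lapply(fits_per_dataset, `[[`, "gene_id")))
  per_list_hits <- lapply(lists, function(l) {
    l <- unique(l)
    if (!any(l %in% universe))
      warning("candidate list with no overlap with the gene universe")
    intersect(l, sig_any)
  })
  genes <- sort(unique(unlist(per_list_hits)))
  tag <- vapply(genes, function(g) {
    paste(names(lists)[vapply(per_list_hits, function(h) g %in% h,
                              logical(1))], collapse = ";")
  }, character(1))
  out <- data.frame(gene_id = genes, lists = tag, stringsAsFactors = FALSE)
  for (nm in names(fits_per_dataset)) {
    f <- fits_per_dataset[[nm]]
    idx <- match(genes, f$gene_id)
    out[[paste0("significant_", nm)]] <- !is.na(idx) & f$significant[idx]
    out[[paste0("phase_", nm)]] <- f$phase_h[idx]
  }
  rownames(out) <- NULL
  attr(out, "summary") <- list(per_list = lengths(per_list_hits),
                               unique_total = length(genes))
  out
}

#' Score rhythm detection against synthetic ground truth
#'
#' Compares a rhythmicity table with the truth table it was simulated from:
#' sensitivity (fraction of truly rhythmic genes called significant),
#' realized false discovery rate (fraction of significant calls that are
#' truly arrhythmic), the median absolute circular phase error on true
#' positives (wrapped to at most 12 h), and the median relative error of
#' the relative amplitude on true positives.
#'
#' @param truth A [simulate_truth()] table.
#' @param fits A [rhythmicity_table()] result on (a subset of) the same
#'   genes.
#' @param missing_as_null Treat truth genes absent from `fits` (e.g.
#'   removed by expression filtering) as tested-but-not-significant
#'   (default `TRUE`); with `FALSE`, mismatched universes are an error.
#' @return A list with `sensitivity` (`NA` when no gene is truly rhythmic),
#'   `fdr`, `median_phase_error_h`, `median_relamp_rel_error`,
#'   `n_true_positive`, `n_significant`, `n_rhythmic_truth`.
#' @export
recovery_report <- function(truth, fits, missing_as_null = TRUE) {
  stopifnot(inherits(truth, "SyntheticTruth") || is.data.frame(truth),
            is.data.frame(fits))
  unknown <- setdiff(fits$gene_id, truth$gene_id)
  if (length(unknown))
    stop("fits contain genes absent from the truth: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  if (!missing_as_null && length(setdiff(truth$gene_id, fits$gene_id)))
    stop("gene universes do not match")
  idx <- match(truth$gene_id, fits$gene_id)
  sig <- !is.na(idx) & fits$significant[idx]
  tp <- sig & truth$is_rhythmic
  fp <- sig & !truth$is_rhythmic
  n_sig <- sum(sig)
  n_rhy <- sum(truth$is_rhythmic)
  phase_err <- relamp_err <- NA_real_
  if (any(tp)) {
    phase_err <- stats::median(circular_distance(
      truth$phase_true[tp], fits$phase_h[idx[tp]]))
    relamp_err <- stats::median(
      abs(fits$relamp[idx[tp]] - truth$relamp_true[tp]) /
        truth$relamp_true[tp])
  }
  list(sensitivity = if (n_rhy > 0) sum(tp) / n_rhy else NA_real_,
       fdr = if (n_sig > 0) sum(fp) / n_sig else 0,
       median_phase_error_h = phase_err,
       median_relamp_rel_error = relamp_err,
       n_true_positive = sum(tp),
       n_significant = n_sig,
       n_rhythmic_truth = n_rhy)
}
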