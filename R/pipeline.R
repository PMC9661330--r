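#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis into one list, either
#' from arguments or from a YAML file (see `read_pipeline_config`). When
#' `simulate` is non-NULL the cohort is generated; otherwise recordings,
#' leadfield and metadata are read from `paths`.
#'
#' @param simulate `NULL`, or a list of [sim_config()] arguments for the
#'   synthetic cohort (e.g. `list(n_neg = 20, n_pos = 20)`).
#' @param paths list with `recordings` (directory of EDF + marker files),
#'   `leadfield` (container directory), `metadata` (TSV); ignored when
#'   simulating.
#' @param f_lo,f_hi broadband filter edges (Hz).
#' @param z_threshold channel-rejection |z| threshold.
#' @param ic_corr_threshold ICA ocular-component |r| threshold.
#' @param bands band table (default [default_bands()]).
#' @param lambda_fraction beamformer regularization fraction.
#' @param condition analysis condition: `"EC"` (default), `"EO"`.
#' @param grid_spacing source-grid spacing (mm) for the simulated head
#'   model.
#' @param n_channels simulated scalp montage size.
#' @param stats a [stat_config()].
#' @param visit visit label carried into outputs.
#' @param reliability run the bootstrap equalization stage (slow; default
#'   `FALSE`).
#' @param seed master seed for every stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = list(n_neg = 20, n_pos = 20),
                            paths = NULL, f_lo = 1, f_hi = 80,
                            z_threshold = 2.5, ic_corr_threshold = 0.8,
                            bands = default_bands(),
                            lambda_fraction = 0.05, condition = "EC",
                            grid_spacing = 20, n_channels = 32,
                            stats = stat_config(), visit = "M0",
                            reliability = FALSE, seed = 1) {
  condition <- match.arg(condition, c("EC", "EO"))
  validate_bands(bands)
  if (is.null(simulate)) {
    need <- c("recordings", "leadfield", "metadata")
    if (is.null(paths) || !all(need %in% names(paths)))
      stop("without simulation, paths must give recordings, leadfield, ",
           "metadata")
    missing <- !vapply(paths[need], function(p) file.exists(p), logical(1))
    if (any(missing))
      stop("missing input path(s): ",
           paste(unlist(paths[need][missing]), collapse = ", "))
  }
  structure(list(simulate = simulate, paths = paths, f_lo = f_lo,
                 f_hi = f_hi, z_threshold = z_threshold,
                 ic_corr_threshold = ic_corr_threshold, bands = bands,
                 lambda_fraction = lambda_fraction, condition = condition,
                 grid_spacing = grid_spacing, n_channels = n_channels,
                 stats = stats, visit = visit, reliability = reliability,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file whose top-level keys are `pipeline_config`
#'   arguments (`stats` and `simulate` as nested maps).
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  y <- yaml::read_yaml(path)
  if (!is.null(y$stats)) y$stats <- do.call(stat_config, y$stats)
  if (!is.null(y$bands)) y$bands <- as.data.frame(y$bands)
  do.call(pipeline_config, y)
}

#' Source power maps for one subject
#'
#' The per-subject middle of the pipeline: band filter bank on the cleaned
#' recording, per-band covariance from the merged EC+EO data over the good
#' channels, one common LCMV filter set per band, projection of the
#' analysis condition, and the Hann-FFT power map.
#'
#' @param cleaned output of [preprocess_recording()].
#' @param leadfield a `leadfield` object.
#' @param config a [pipeline_config()].
#' @param subject_id,visit labels for the map.
#' @return a [source_power_map()] object.
#' @export
subject_source_power <- function(cleaned, leadfield, config,
                                 subject_id = "S000",
                                 visit = config$visit) {
  rec <- cleaned$recording
  good <- cleaned$good_channels
  good_names <- rec$channels[good]
  ch_idx <- match(good_names, leadfield$channels)
  if (anyNA(ch_idx))
    stop("leadfield lacks channels: ",
         paste(good_names[is.na(ch_idx)], collapse = ", "))
  per_band <- band_filter_bank(rec, config$bands)
  series <- lapply(per_band, function(br) {
    ec <- condition_samples(br, "EC", channels = good_names)
    eo <- condition_samples(br, "EO", channels = good_names)
    C <- merged_covariance(ec, eo)
    filt <- lcmv_filters(leadfield, C,
                         lambda_fraction = config$lambda_fraction,
                         channels = ch_idx)
    project_sources(if (config$condition == "EC") ec else eo, filt)
  })
  source_power_map(series, rec$fs, bands = config$bands,
                   subject_id = subject_id, visit = visit,
                   condition = config$condition)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> preprocess -> source power -> outlier
#' exclusion -> group statistics, writes all result tables plus a
#' provenance record to `out_dir`, and returns the result bundle. Stages
#' log their timing to stderr.
#'
#' Group statistics comprise, per band, the A- vs A+ cluster permutation
#' test on the z-power maps; for the best theta-band cluster, the SUVr
#' vincentile ANOVA (Bonferroni-corrected pairwise tests), the regression
#' of cluster-mean power on the memory score (overall and per group), the
#' amyloid-by-APOE ANCOVA with sex and age covariates, and (optionally)
#' the bootstrap-equalized reliability.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created).
#' @return invisibly, a list with `meta`, `maps`, `exclusion`,
#'   `cluster_tests` (per band), `theta` (downstream analyses),
#'   `provenance`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("amypower_out_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t_start <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- force(expr)
    message(sprintf("[amypower] %-14s %7.1f s", name,
                    proc.time()[["elapsed"]] - t0))
    r
  }

  inputs <- stage("load", {
    if (!is.null(config$simulate)) {
      sc_args <- config$simulate
      sc_args$seed <- sc_args$seed %||% config$seed
      sc_args$n_channels <- sc_args$n_channels %||% config$n_channels
      sc <- do.call(sim_config, sc_args)
      model <- head_model(electrodes = sc$n_channels,
                          grid_spacing = config$grid_spacing)
      simulate_cohort(sc, model = model)
    } else {
      lf <- read_leadfield(config$paths$leadfield)
      meta <- read_metadata(config$paths$metadata)
      recs <- lapply(meta$subject_id, function(sid) {
        read_edf(file.path(config$paths$recordings,
                           paste0(sid, ".edf")),
                 markers = read_markers(
                   file.path(config$paths$recordings,
                             paste0(sid, "_markers.tsv"))))
      })
      names(recs) <- meta$subject_id
      list(meta = meta, leadfield = lf, recordings = recs)
    }
  })
  meta <- inputs$meta
  meta$amyloid <- as.character(classify_amyloid(meta$suvr))
  lf <- inputs$leadfield

  per_subject <- stage("sourcepower", {
    lapply(seq_along(inputs$recordings), function(i) {
      cleaned <- preprocess_recording(
        inputs$recordings[[i]], f_lo = config$f_lo, f_hi = config$f_hi,
        z_threshold = config$z_threshold,
        ic_corr_threshold = config$ic_corr_threshold,
        seed = derive_seed(config$seed, 500000L + i))
      list(map = subject_source_power(cleaned, lf, config,
                                      subject_id = meta$subject_id[i]),
           rejected_channels = cleaned$qc$channel[cleaned$qc$rejected],
           removed_ics = cleaned$ica$removed_components)
    })
  })
  maps <- lapply(per_subject, `[[`, "map")

  exclusion <- stage("outliers", {
    if (length(maps) >= 10L) exclude_outlier_subjects(maps) else {
      message("[amypower] fewer than 10 subjects; outlier exclusion ",
              "skipped")
      list(kept = seq_along(maps), excluded = integer(0),
           global = vapply(maps, function(m) mean(m$power), numeric(1)),
           bounds = c(lower = -Inf, upper = Inf))
    }
  })
  kept <- exclusion$kept
  meta_k <- meta[kept, , drop = FALSE]
  labels <- factor(meta_k$amyloid, levels = c("A-", "A+"))

  cluster_tests <- stage("clusterstats", {
    res <- lapply(seq_len(nrow(config$bands)), function(b) {
      band <- config$bands$name[b]
      Z <- t(vapply(maps[kept], function(m) m$z[, band],
                    numeric(nrow(lf$grid))))
      cfg <- config$stats
      cfg$seed <- derive_seed(config$seed, 700000L + b)
      cluster_permutation_test(Z, labels, lf$adjacency, cfg)
    })
    names(res) <- config$bands$name
    res
  })

  theta <- stage("theta", {
    res <- cluster_tests[["theta"]]
    out <- list(cluster = NULL)
    if (!is.null(res) && nrow(res$clusters)) {
      # the effect of interest is ampler A+ theta power, i.e. a negative
      # cluster (A- minus A+); fall back to the overall best only if no
      # negative cluster exists
      neg <- which(res$clusters$sign == "-")
      best <- if (length(neg)) neg[which.min(res$clusters$p_mc[neg])] else
        which.min(res$clusters$p_mc)
      vox <- res$clusters$voxels[[best]]
      Zt <- t(vapply(maps[kept], function(m) m$z[, "theta"],
                     numeric(nrow(lf$grid))))
      cm <- rowMeans(Zt[, vox, drop = FALSE])
      bins <- tryCatch(
        vincentize_quantiles(meta_k$suvr, config$stats$n_quantiles),
        error = function(e) rep(NA_integer_, length(cm)))
      out <- list(
        cluster = res$clusters[best, c("sign", "size", "maxsum_t", "p_mc",
                                       "significant")],
        cluster_voxels = vox,
        cluster_mean_power = cm,
        quantile_bins = bins,
        anova = tryCatch(
          oneway_anova_bonferroni(cm, bins,
                                  bonferroni = config$stats$bonferroni),
          error = function(e) list(
            skipped = conditionMessage(e),
            bin_means = if (!all(is.na(bins)))
              tapply(cm, bins, mean))),
        regression = tryCatch(
          regress_power_on_score(cm, meta_k$fcsrt_tr, group = labels),
          error = function(e) list(skipped = conditionMessage(e))),
        ancova = tryCatch(ancova_amyloid_apoe(cm, meta_k),
                          error = function(e)
                            list(skipped = conditionMessage(e))))
      if (config$reliability) {
        out$reliability <- bootstrap_equalized_reliability(
          Zt, labels, lf$adjacency, config$stats,
          effect_spec = list(sign = res$clusters$sign[best],
                             roi_voxels = vox))
      }
    }
    out
  })

  stage("write", {
    write_metadata(meta, file.path(out_dir, "metadata.tsv"))
    write_power_maps(maps, file.path(out_dir, "power_maps.tsv"))
    for (band in names(cluster_tests)) {
      r <- cluster_tests[[band]]
      utils::write.table(
        data.frame(voxel = seq_along(r$t_map), t = r$t_map),
        file.path(out_dir, paste0("tmap_", band, ".tsv")),
        sep = "\t", row.names = FALSE, quote = FALSE)
    }
    cl_json <- lapply(cluster_tests, function(r) {
      list(threshold_t = r$threshold_t,
           clusters = if (nrow(r$clusters)) lapply(
             seq_len(nrow(r$clusters)), function(i) list(
               sign = r$clusters$sign[i], size = r$clusters$size[i],
               maxsum_t = r$clusters$maxsum_t[i],
               p_mc = r$clusters$p_mc[i],
               significant = r$clusters$significant[i],
               voxels = r$clusters$voxels[[i]])) else list())
    })
    jsonlite::write_json(cl_json, file.path(out_dir, "clusters.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(theta$cluster)) {
      utils::write.table(
        data.frame(subject_id = meta_k$subject_id,
                   bin = theta$quantile_bins,
                   cluster_mean_power = theta$cluster_mean_power),
        file.path(out_dir, "theta_quantiles.tsv"),
        sep = "\t", row.names = FALSE, quote = FALSE)
      jsonlite::write_json(
        list(anova = theta$anova[intersect(
               c("F", "df", "p", "eta_squared", "skipped"),
               names(theta$anova))],
             bin_means = as.list(theta$anova$bin_means),
             regression = theta$regression[intersect(
               c("slope", "intercept", "r_squared", "p", "n", "skipped"),
               names(theta$regression))],
             ancova = if (!is.null(theta$ancova$table)) lapply(
               seq_len(nrow(theta$ancova$table)),
               function(i) as.list(theta$ancova$table[i, ])) else
                 theta$ancova,
             reliability = if (!is.null(theta$reliability))
               theta$reliability[c("replication_count", "proportion")]),
        file.path(out_dir, "theta_analyses.json"),
        auto_unbox = TRUE, digits = NA, force = TRUE)
    }
    NULL
  })

  provenance <- list(
    package_version = as.character(utils::packageVersion("amypower")),
    seed = config$seed,
    condition = config$condition,
    parameters = list(f_lo = config$f_lo, f_hi = config$f_hi,
                      z_threshold = config$z_threshold,
                      ic_corr_threshold = config$ic_corr_threshold,
                      lambda_fraction = config$lambda_fraction,
                      stats = unclass(config$stats),
                      simulate = config$simulate),
    excluded_subjects = meta$subject_id[exclusion$excluded],
    rejected_channels = stats::setNames(
      lapply(per_subject, `[[`, "rejected_channels"), meta$subject_id),
    removed_ica_components = stats::setNames(
      lapply(per_subject, `[[`, "removed_ics"), meta$subject_id),
    file_hashes = as.list(tools::md5sum(
      list.files(out_dir, full.names = TRUE, pattern = "\\.(tsv|json)$"))),
    elapsed_s = proc.time()[["elapsed"]] - t_start)
  names(provenance$file_hashes) <-
    basename(names(provenance$file_hashes))
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(meta = meta, maps = maps, exclusion = exclusion,
                 cluster_tests = cluster_tests, theta = theta,
                 provenance = provenance, out_dir = out_dir))
}
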