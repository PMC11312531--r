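# End-to-end orchestration: simulate -> extract -> profile -> classify ->
# eccentricity -> develop -> report, with a YAML-round-trippable config and a
# manifest recording seeds and output hashes.

#' Pipeline configuration
#'
#' All tunable parameters of the full pipeline, each random stage with an
#' explicit seed. Round-trips losslessly through YAML via
#' [write_run_config()] / [read_run_config()].
#'
#' @param seed master seed; per-stage seeds default to fixed offsets of it.
#' @param n_streamlines_per_froi streamlines per (fROI, session).
#' @param radius_mm radial-search and vertex-assignment radius.
#' @param qc_threshold session exclusion threshold on outlier fraction.
#' @param n_components PCA components for classification (`"elbow"` or int).
#' @param balanced,n_resample_per_label balanced-training variant settings.
#' @param n_iter,subsample_fraction bootstrap settings.
#' @param renormalize renormalize profiles after parcel exclusion.
#' @param cohort,mesh cohort and mesh/ground-truth generator settings.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1, n_streamlines_per_froi = 2000,
                       radius_mm = 3, qc_threshold = 0.05,
                       n_components = "elbow", balanced = FALSE,
                       n_resample_per_label = 200,
                       n_iter = 1000, subsample_fraction = 0.75,
                       renormalize = FALSE,
                       cohort = cohort_config(), mesh = mesh_config()) {
  cfg <- as.list(environment())
  cfg$seeds <- list(cohort = seed, mesh = seed + 1000L,
                    tractogram_base = seed + 2000L,
                    classify = seed + 3000L, bootstrap = seed + 4000L,
                    areas = seed + 5000L)
  structure(cfg, class = "run_config")
}

#' Write / read a pipeline config as YAML
#' @param config a `run_config`; @param path YAML path.
#' @export
write_run_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$mesh$band_props <- as.list(as.data.frame(t(cfg$mesh$band_props)))
  # yaml flattens named atomic vectors to plain sequences; keep names by
  # converting them to maps
  for (nm in c("counts", "age_mean", "age_sd", "outlier_mean", "outlier_sd")) {
    cfg$cohort[[nm]] <- as.list(cfg$cohort[[nm]])
  }
  for (nm in c("band_offsets", "band_slopes")) {
    cfg$mesh[[nm]] <- as.list(cfg$mesh[[nm]])
  }
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  bp <- do.call(rbind, lapply(cfg$mesh$band_props, unlist))
  colnames(bp) <- c("0-5", "5-10", "10-20")
  cfg$mesh$band_props <- bp
  for (nm in c("counts", "age_mean", "age_sd", "outlier_mean", "outlier_sd")) {
    cfg$cohort[[nm]] <- unlist(cfg$cohort[[nm]])
  }
  for (nm in c("band_offsets", "band_slopes")) {
    cfg$mesh[[nm]] <- unlist(cfg$mesh[[nm]])
  }
  structure(cfg, class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Generates the synthetic cohort, mesh and tractograms, builds the profile
#' matrix, runs the three classification tasks, the eccentricity-band
#' analyses, and the developmental slope/similarity analyses, writing stage
#' outputs (TSV/JSON) plus a manifest (seeds, file hashes) to `out_dir`.
#' Rerunning with the same config reproduces all outputs bit-identically.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing); `NULL` skips all
#'   file output.
#' @param stages subset of stages to run (dependencies are always run
#'   in-memory).
#' @param progress print stage progress.
#' @return list with all stage results (invisible when writing files).
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         stages = c("classify", "eccentricity", "develop"),
                         progress = interactive()) {
  say <- function(...) if (progress) message(...)
  t0 <- Sys.time()
  say("simulate: cohort + mesh")
  cohort <- make_cohort(config$cohort, seed = config$seeds$cohort)
  cohort <- filter_sessions(cohort, config$qc_threshold)
  mm <- make_labeled_mesh(config$mesh, seed = config$seeds$mesh)
  mesh <- mm$mesh; truth <- mm$truth

  say("simulate + extract + profile: ", nrow(cohort), " sessions")
  # single-entry cache: stages sweep sessions in order, and regeneration is
  # seeded per session, so memory stays flat without losing determinism
  trk_cache <- new.env(parent = emptyenv())
  get_trk <- function(session) {
    id <- session$session_id
    if (!identical(trk_cache$id, id)) {
      si <- match(id, cohort$session_id)
      trk_cache$id <- id
      trk_cache$trk <- sample_tractogram(
        mesh, truth, session, config$n_streamlines_per_froi,
        seed = config$seeds$tractogram_base + si)
    }
    trk_cache$trk
  }
  profiles <- build_profile_matrix(cohort, mesh, get_trk, config$radius_mm,
                                   config$renormalize)
  areas <- sample_froi_areas(mesh, cohort, seed = config$seeds$areas)
  area_model <- relative_area_model(areas)
  res <- list(config = config, cohort = cohort, truth = truth,
              profiles = profiles, area_model = area_model)

  if ("classify" %in% stages) {
    say("classify: 3 tasks")
    pca <- fit_pca(profiles)
    res$pca <- pca
    res$classification <- lapply(
      setNames(c("cytoarchitecture", "category", "age_group"),
               c("cytoarchitecture", "category", "age_group")),
      function(task) loo_classify(profiles, task,
                                  n_components = config$n_components,
                                  balanced = config$balanced,
                                  n_resample_per_label = config$n_resample_per_label,
                                  seed = config$seeds$classify))
    res$task_comparison <- compare_tasks(res$classification)
    res$vs_chance <- lapply(res$classification, accuracy_vs_chance)
  }

  if ("eccentricity" %in% stages) {
    say("eccentricity: band profiles + models")
    bands <- band_profile_table(cohort, mesh, get_trk, hemisphere = "lh",
                                radius_mm = config$radius_mm)
    res$band_table <- bands
    res$factorial <- factorial_model(bands)
    fg_pairs <- list(c("lh.pFus-faces", "lh.pOTS-words"),
                     c("lh.mFus-faces", "lh.OTS-bodies"),
                     c("lh.mFus-faces", "lh.mOTS-words"),
                     c("lh.OTS-bodies", "lh.mOTS-words"))
    res$posthoc <- posthoc_paired_t(bands, fg_pairs)
    res$lmm <- lapply(setNames(.vtcwm_cytos, .vtcwm_cytos), function(cy) {
      sub <- bands[bands$cytoarchitecture == cy & !is.na(bands$pct_central), ]
      lmm_random_intercept(sub$pct_central, sub$age_days, sub$subject_id)
    })
  }

  if ("develop" %in% stages) {
    say("develop: slope maps + bootstrap similarity")
    lh_frois <- froi_metadata("lh")
    res$interaction <- lapply(setNames(lh_frois$froi, lh_frois$froi),
                              function(f) age_by_parcel_model(profiles, f))
    res$slope_maps <- lapply(setNames(lh_frois$froi, lh_frois$froi),
                             function(f) slope_map(profiles, f))
    n_prof <- length(.froi_rows(profiles, lh_frois$froi[1]))
    ages1 <- log10(profiles$meta$age_days[.froi_rows(profiles, lh_frois$froi[1])])
    idx <- bootstrap_indices(n_prof, config$n_iter, config$subsample_fraction,
                             seed = config$seeds$bootstrap, ages = ages1)
    res$boot_slopes <- lapply(setNames(lh_frois$froi, lh_frois$froi),
                              function(f) bootstrap_slopes(profiles, f,
                                                           indices = idx))
    res$similarity <- slope_similarity(res$boot_slopes, lh_frois)
  }
  res$elapsed_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))

  if (!is.null(out_dir)) .write_pipeline_outputs(res, out_dir)
  invisible(res)
}

.write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) {
    p <- file.path(out_dir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- character(0)
  paths <- c(paths, tsv(res$cohort, "sessions.tsv"))
  pmp <- file.path(out_dir, "profiles.tsv")
  write_profile_matrix(res$profiles, pmp)
  paths <- c(paths, pmp)
  if (!is.null(res$classification)) {
    for (task in names(res$classification)) {
      r <- res$classification[[task]]
      paths <- c(paths, tsv(r$per_session_accuracy,
                            paste0("accuracy_", task, ".tsv")))
      paths <- c(paths, tsv(as.data.frame.matrix(r$confusion),
                            paste0("confusion_", task, ".tsv")))
    }
    paths <- c(paths, tsv(res$task_comparison, "task_comparison.tsv"))
  }
  if (!is.null(res$band_table)) {
    paths <- c(paths, tsv(res$band_table, "band_profiles.tsv"))
    paths <- c(paths, tsv(res$factorial$anova, "factorial_anova.tsv"))
    paths <- c(paths, tsv(res$posthoc, "posthoc_paired_t.tsv"))
  }
  if (!is.null(res$slope_maps)) {
    sm <- do.call(rbind, lapply(names(res$slope_maps), function(f)
      cbind(froi = f, as.data.frame(res$slope_maps[[f]]))))
    paths <- c(paths, tsv(sm, "slope_maps.tsv"))
    paths <- c(paths, tsv(res$similarity$table, "slope_similarity.tsv"))
  }
  summary <- report_pipeline(res)
  jp <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, jp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(paths, jp)
  manifest <- data.frame(file = basename(paths),
                         md5 = as.character(tools::md5sum(paths)),
                         row.names = NULL, stringsAsFactors = FALSE)
  write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' Summarize pipeline results
#'
#' Collects the headline quantities of a [run_pipeline()] result into a flat
#' list suitable for JSON serialization.
#'
#' @param res a [run_pipeline()] result list.
#' @return named list of summary numbers and small tables.
#' @export
report_pipeline <- function(res) {
  out <- list(
    n_sessions = nrow(res$cohort),
    n_profiles = nrow(res$profiles$matrix),
    n_parcels = ncol(res$profiles$matrix),
    area_model = list(slope = res$area_model$slope$estimate,
                      t = res$area_model$slope$statistic,
                      residual_df = res$area_model$residual_df)
  )
  if (!is.null(res$pca)) {
    out$pca <- list(
      elbow = res$pca$n_components_elbow,
      var_explained_elbow =
        sum(res$pca$variance_explained[1:res$pca$n_components_elbow]),
      var_pc1 = res$pca$variance_explained[1],
      var_pc2 = res$pca$variance_explained[2])
  }
  if (!is.null(res$classification)) {
    out$accuracy <- lapply(res$classification, function(r)
      list(mean = r$overall_mean, sd = r$overall_sd, chance = r$chance))
    out$vs_chance <- lapply(res$vs_chance, function(v)
      list(t = v$t, df = v$df, cohens_d = v$cohens_d))
  }
  if (!is.null(res$factorial)) {
    a <- res$factorial$anova
    out$factorial <- list(
      residual_df = res$factorial$residual_df,
      cyto_F = a$F[a$term == "cytoarchitecture"],
      cyto_eta_sq = a$eta_sq[a$term == "cytoarchitecture"],
      cyto_by_category_df = a$df[a$term == "cytoarchitecture:category"])
    out$band_means_by_cyto <- lapply(
      split(res$band_table$pct_central, res$band_table$cytoarchitecture),
      mean, na.rm = TRUE)
    out$lmm_beta <- lapply(res$lmm, function(l)
      list(beta = l$beta, ci = l$ci, df = l$df))
  }
  if (!is.null(res$similarity)) {
    cf <- res$similarity$fit$coefficients
    out$similarity <- list(
      residual_df = res$similarity$fit$residual_df,
      same_cyto_coef = cf$estimate[cf$term == "same_cytoarchitecture"],
      same_cat_coef = cf$estimate[cf$term == "same_category"],
      mean_r_same_cyto = mean(res$similarity$table$r[
        res$similarity$table$same_cytoarchitecture == 1]),
      mean_r_diff_cyto = mean(res$similarity$table$r[
        res$similarity$table$same_cytoarchitecture == 0]))
  }
  out
}
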