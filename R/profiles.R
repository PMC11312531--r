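# Parcel-level connectivity profiles: aggregate endpoint-density maps over
# the parcellation, assemble the cohort profile matrix, and the fROI
# relative-surface-area model.

#' Aggregate an endpoint-density map to parcel level
#'
#' Sums per-vertex densities within each retained parcel of the fROI's
#' hemisphere. The density map is normalized over the whole surface first (in
#' [endpoint_density()]); excluded parcels are dropped *after* that
#' normalization, so with `renormalize = FALSE` (the default) the retained
#' vector may sum to less than 1 — the missing mass sat in excluded
#' (seed-region) parcels or the other hemisphere.
#'
#' @param dmap an `endpoint_density` map.
#' @param mesh the `labeled_mesh` the map was computed on.
#' @param hemisphere hemisphere whose parcels are retained (`"lh"`/`"rh"`).
#' @param renormalize if `TRUE`, rescale the retained vector to sum to 1.
#' @return named numeric vector over retained parcels (canonical parcel-name
#'   order, identical across hemispheres).
#' @export
aggregate_to_parcels <- function(dmap, mesh, hemisphere = "lh",
                                 renormalize = FALSE) {
  stopifnot(inherits(dmap, "endpoint_density"), inherits(mesh, "labeled_mesh"))
  if (length(dmap$density) != mesh$n_vertices) {
    stop("density map (", length(dmap$density), " vertices) does not match mesh (",
         mesh$n_vertices, ")")
  }
  lab <- mesh$labels
  if (is.null(lab$excluded)) stop("mesh labels lack the 'excluded' parcel flag")
  retained <- sort(unique(lab$parcel[!lab$excluded]))
  keep <- lab$hemisphere == hemisphere & !lab$excluded
  sums <- tapply(dmap$density[keep], factor(lab$parcel[keep], levels = retained),
                 sum, default = 0)
  out <- setNames(as.numeric(sums), retained)
  if (renormalize && sum(out) > 0) out <- out / sum(out)
  out
}

#' Build the cohort profile matrix
#'
#' One connectivity profile per (fROI, session): the session tractogram is
#' intersected with each fROI by radial search, endpoints are mapped to the
#' surface, and densities aggregated to retained parcels. Row order is
#' canonical: sessions in table order, fROIs in canonical order within each
#' session.
#'
#' @param sessions session table ([make_cohort()], after [filter_sessions()]).
#' @param mesh a `labeled_mesh` carrying fROI labels.
#' @param tractograms named list of `tractogram`s, one per `session_id`, or a
#'   function `function(session)` returning one (lazy generation).
#' @param radius_mm radial-search / vertex-assignment radius.
#' @param renormalize passed to [aggregate_to_parcels()].
#' @return object of class `profile_matrix`: list with `matrix` (rows x
#'   parcels), `meta` (froi, subject_id, session_id, age_days, age_group,
#'   hemisphere, category, cytoarchitecture), `parcels`.
#' @export
build_profile_matrix <- function(sessions, mesh, tractograms, radius_mm = 3,
                                 renormalize = FALSE) {
  frois <- froi_metadata(intersect(c("lh", "rh"), unique(mesh$labels$hemisphere)))
  missing <- setdiff(frois$froi, unique(mesh$labels$froi))
  if (length(missing) > 0) {
    stop("mesh lacks fROI labels: ", paste(missing, collapse = ", "))
  }
  # canonical row order: sessions by id, fROIs in canonical order within each
  sessions <- sessions[order(sessions$session_id), , drop = FALSE]
  get_trk <- if (is.function(tractograms)) {
    tractograms
  } else {
    function(session) {
      trk <- tractograms[[session$session_id]]
      if (is.null(trk)) stop("no tractogram for session ", session$session_id)
      trk
    }
  }
  rows <- list()
  meta <- list()
  for (si in seq_len(nrow(sessions))) {
    ses <- sessions[si, ]
    trk <- get_trk(ses)
    for (fi in seq_len(nrow(frois))) {
      fr <- frois[fi, ]
      roi_pts <- project_roi(mesh, froi_vertices(mesh, fr$froi), 0)
      sub <- extract_fsub(trk, roi_pts, radius_mm)
      dmap <- endpoint_density(sub$tractogram, mesh, radius_mm)
      vals <- aggregate_to_parcels(dmap, mesh, fr$hemisphere, renormalize)
      rows[[length(rows) + 1L]] <- vals
      meta[[length(meta) + 1L]] <- data.frame(
        froi = fr$froi, subject_id = ses$subject_id,
        session_id = ses$session_id, age_days = ses$age_days,
        age_group = as.character(ses$age_group), hemisphere = fr$hemisphere,
        category = fr$category, cytoarchitecture = fr$cytoarchitecture,
        stringsAsFactors = FALSE)
    }
  }
  mat <- do.call(rbind, rows)
  meta <- do.call(rbind, meta)
  meta$age_group <- factor(meta$age_group, levels = .vtcwm_age_groups)
  structure(list(matrix = mat, meta = meta, parcels = colnames(mat)),
            class = "profile_matrix")
}

#' @exportS3Method
print.profile_matrix <- function(x, ...) {
  cat("profile_matrix:", nrow(x$matrix), "profiles x", ncol(x$matrix),
      "parcels (", length(unique(x$meta$session_id)), "sessions,",
      length(unique(x$meta$froi)), "fROIs )\n")
  invisible(x)
}

#' Serialize / read a profile matrix as TSV
#' @param pm a `profile_matrix`; @param path output path.
#' @export
write_profile_matrix <- function(pm, path) {
  df <- cbind(pm$meta, as.data.frame(pm$matrix, check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_matrix
#' @export
read_profile_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta_cols <- c("froi", "subject_id", "session_id", "age_days", "age_group",
                 "hemisphere", "category", "cytoarchitecture")
  meta <- df[, meta_cols]
  meta$age_group <- factor(meta$age_group, levels = .vtcwm_age_groups)
  mat <- as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE])
  structure(list(matrix = mat, meta = meta, parcels = colnames(mat)),
            class = "profile_matrix")
}

#' Relative fROI surface-area model
#'
#' Ordinary least squares of fROI surface area divided by hemisphere surface
#' area on log10(age in days), pooled over fROIs and sessions. With relative
#' fROI size stationary over development the slope is indistinguishable from
#' zero.
#'
#' @param areas data.frame with columns `froi_area`, `hemi_area`, `age_days`
#'   (e.g. from [sample_froi_areas()]).
#' @return list: `fit` (`vtcwm_fit`), `slope` row of the coefficient table,
#'   `residual_df` (n - 2).
#' @export
relative_area_model <- function(areas) {
  stopifnot(nrow(areas) >= 3)
  if (any(areas$hemi_area <= 0)) stop("hemisphere area must be positive")
  ratio <- areas$froi_area / areas$hemi_area
  la <- log10(areas$age_days)
  if (sd(ratio) == 0) {
    # degenerate: constant ratios; slope and t are exactly zero
    return(list(fit = NULL,
                slope = data.frame(term = "log10_age", estimate = 0, se = 0,
                                   statistic = 0, p = NA_real_,
                                   ci_lo = 0, ci_hi = 0),
                residual_df = nrow(areas) - 2L))
  }
  fit <- ols_fit(ratio ~ la, data = data.frame(ratio = ratio, la = la))
  slope <- fit$coefficients[fit$coefficients$term == "la", ]
  slope$term <- "log10_age"
  list(fit = fit, slope = slope, residual_df = fit$residual_df)
}
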