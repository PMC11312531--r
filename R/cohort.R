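# Synthetic cohort: session tables with longitudinal structure and a
# simulated dMRI outlier-volume share, plus the session QC filter.

# Evaluate expr under an explicit RNG seed, restoring global RNG state after.
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Deterministic small-integer hash of a string (for per-subject effects).
.string_seed <- function(x, salt = 0L) {
  h <- 0
  for (ch in utf8ToInt(x)) h <- (h * 131 + ch) %% 2147483647
  as.integer((h + salt) %% 2147483647)
}

#' Cohort generator configuration
#'
#' Defaults emulate the study cohort: 88 sessions in four age groups
#' (23 newborn, 23 three-month, 21 six-month, 21 adult), 42 infant subjects of
#' whom 21 are longitudinal (4 with three timepoints, 17 with two), and adult
#' ages drawn in years and converted to days (365.25 days/year).
#'
#' @param counts named sessions per age group (newborn, 3mo, 6mo, adult).
#' @param age_mean,age_sd per-group age distribution; infant groups in days,
#'   adults in years.
#' @param age_bins_days group bin edges in days; draws are truncated to bins
#'   so `age_group` is always consistent with `age_days`.
#' @param n_triple,n_double longitudinal infant subjects with 3 resp. 2
#'   sessions; `"auto"` scales the default allocation (4 and 17 at 67 infant
#'   sessions) proportionally with floor, so tiny cohorts degrade to
#'   cross-sectional.
#' @param outlier_mean,outlier_sd age-group-wise distribution of the simulated
#'   fraction of dMRI outlier volumes (infants 0.45% +/- 0.43%, adults
#'   0.29% +/- 0.10%).
#' @return list of settings for [make_cohort()].
#' @export
cohort_config <- function(counts = c(newborn = 23, "3mo" = 23, "6mo" = 21, adult = 21),
                          age_mean = c(newborn = 28.6, "3mo" = 106.9, "6mo" = 189.0,
                                       adult = 28.21),
                          age_sd = c(newborn = 10.2, "3mo" = 19.3, "6mo" = 15.8,
                                     adult = 5.51),
                          age_bins_days = c(0, 60, 150, 250, Inf),
                          n_triple = "auto", n_double = "auto",
                          outlier_mean = c(infant = 0.0045, adult = 0.0029),
                          outlier_sd = c(infant = 0.0043, adult = 0.0010)) {
  if (any(counts <= 0)) stop("session counts must be positive")
  list(counts = counts, age_mean = age_mean, age_sd = age_sd,
       age_bins_days = age_bins_days, n_triple = n_triple, n_double = n_double,
       outlier_mean = outlier_mean, outlier_sd = outlier_sd)
}

# truncated-normal draw within (lo, hi), vectorized by rejection
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0) {
    x <- rnorm(length(need), mean, sd)
    ok <- x > lo & x < hi
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

#' Generate a synthetic session table
#'
#' Builds the subject/session layout (longitudinal infants first, then
#' cross-sectional infants, then adults), draws ages within the group bins and
#' simulated outlier fractions. Deterministic given `(config, seed)`.
#'
#' @param config from [cohort_config()].
#' @param seed integer RNG seed.
#' @return data.frame of session records: `subject_id`, `session_id`,
#'   `age_days`, `age_group` (factor in age order), `outlier_fraction`.
#' @export
make_cohort <- function(config = cohort_config(), seed = 1) {
  if (any(config$counts <= 0)) stop("session counts must be positive")
  groups <- .vtcwm_age_groups
  counts <- config$counts[groups]
  if (anyNA(counts)) stop("counts must name all four age groups")
  ic <- counts[1:3]  # infant groups
  s_inf <- sum(ic)
  n_tri <- config$n_triple
  n_dbl <- config$n_double
  if (identical(n_tri, "auto")) n_tri <- floor(4 * s_inf / 67)
  if (identical(n_dbl, "auto")) n_dbl <- floor(17 * s_inf / 67)
  n_tri <- min(n_tri, min(ic))
  # allocate double-session subjects over the three group pairs, near-evenly
  pair_groups <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  d <- c(n_dbl %/% 3, n_dbl %/% 3, n_dbl %/% 3)
  extra <- n_dbl - sum(d)
  if (extra >= 1) d[1] <- d[1] + 1
  if (extra >= 2) d[2] <- d[2] + 1
  used <- c(n_tri + d[1] + d[2], n_tri + d[1] + d[3], n_tri + d[2] + d[3])
  if (any(used > ic)) {
    stop("longitudinal allocation infeasible for these group counts; ",
         "lower n_triple/n_double")
  }
  singles <- ic - used
  # subject -> vector of group indices
  subj_groups <- c(
    rep(list(1:3), n_tri),
    unlist(lapply(1:3, function(k) rep(pair_groups[k], d[k])), recursive = FALSE),
    unlist(lapply(1:3, function(k) rep(list(k), singles[k])), recursive = FALSE),
    rep(list(4L), counts[4])
  )
  n_subj <- length(subj_groups)
  subject_id <- sprintf("sub%03d", seq_len(n_subj))
  rows <- do.call(rbind, lapply(seq_len(n_subj), function(i) {
    g <- subj_groups[[i]]
    data.frame(subject_id = subject_id[i],
               session_index = seq_along(g),
               group_index = g, stringsAsFactors = FALSE)
  }))
  rows$session_id <- sprintf("%s_ses%02d", rows$subject_id, rows$session_index)
  rows$age_group <- groups[rows$group_index]
  .with_seed(seed, {
    bins <- config$age_bins_days
    age <- numeric(nrow(rows))
    for (k in 1:4) {
      ix <- which(rows$group_index == k)
      if (length(ix) == 0) next
      m <- config$age_mean[groups[k]]
      s <- config$age_sd[groups[k]]
      if (k == 4) {  # adults sampled in years
        yrs <- .rtruncnorm(length(ix), m, s, bins[4] / 365.25, bins[5] / 365.25)
        age[ix] <- yrs * 365.25
      } else {
        age[ix] <- .rtruncnorm(length(ix), m, s, bins[k], bins[k + 1])
      }
    }
    rows$age_days <- age
    infant <- rows$group_index < 4
    who <- ifelse(infant, "infant", "adult")
    rows$outlier_fraction <- abs(rnorm(nrow(rows),
                                       config$outlier_mean[who],
                                       config$outlier_sd[who]))
  })
  out <- rows[, c("subject_id", "session_id", "age_days", "age_group",
                  "outlier_fraction")]
  out$age_group <- factor(out$age_group, levels = groups)
  stopifnot(all(out$age_days > 0))
  # longitudinal ages strictly increase by construction (bins are ordered)
  rownames(out) <- NULL
  out
}

#' Session quality-control filter
#'
#' Retains exactly the sessions whose outlier-volume fraction is less than or
#' equal to `threshold`: the exclusion criterion is strictly "more than
#' threshold", so a session at exactly the threshold is retained.
#'
#' @param records session table with an `outlier_fraction` column.
#' @param threshold exclusion threshold in \[0, 1\] (default 0.05).
#' @return the retained rows of `records`.
#' @export
filter_sessions <- function(records, threshold = 0.05) {
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1) {
    stop("threshold must be in [0, 1]")
  }
  if (is.null(records$outlier_fraction) || anyNA(records$outlier_fraction)) {
    stop("records must have a populated outlier_fraction column")
  }
  out <- records[records$outlier_fraction <= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulated fROI and hemisphere surface areas per session
#'
#' Measures fROI and hemisphere surface areas on the mesh (barycentric vertex
#' areas) and applies small per-session lognormal jitter to the fROI areas,
#' emulating individual anatomical variability; the jitter is independent of
#' age, so relative fROI size is stationary over development.
#'
#' @param mesh a `labeled_mesh` with fROI labels.
#' @param sessions session table from [make_cohort()].
#' @param seed RNG seed.
#' @param jitter_sd lognormal sd of the per-(fROI, session) area jitter.
#' @return data.frame: froi, session_id, age_days, froi_area, hemi_area.
#' @export
sample_froi_areas <- function(mesh, sessions, seed = 1, jitter_sd = 0.03) {
  va <- vertex_areas(mesh)
  frois <- froi_metadata(intersect(c("lh", "rh"), unique(mesh$labels$hemisphere)))
  hemi_area <- vapply(c(lh = "lh", rh = "rh"), function(h)
    sum(va[mesh$labels$hemisphere == h]), numeric(1))
  base <- vapply(frois$froi, function(f) sum(va[froi_vertices(mesh, f)]),
                 numeric(1))
  grid <- expand.grid(froi = frois$froi, session_id = sessions$session_id,
                      stringsAsFactors = FALSE)
  grid$age_days <- sessions$age_days[match(grid$session_id, sessions$session_id)]
  hemi <- frois$hemisphere[match(grid$froi, frois$froi)]
  .with_seed(seed, {
    grid$froi_area <- base[grid$froi] * rlnorm(nrow(grid), 0, jitter_sd)
  })
  grid$hemi_area <- hemi_area[hemi]
  grid
}
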