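# Connections to eccentricity bands in early visual cortex: per-fROI band
# profiles (streamline counts, not endpoint density), the three-way factorial
# model on the central-5-degree percentage, post-hoc paired t tests, and
# random-intercept mixed models of development.

#' Eccentricity-band profile of one fROI
#'
#' Selects streamlines with one terminal point within `radius_mm` of the fROI
#' and the other terminal point within `radius_mm` of any eccentricity-band
#' vertex, assigns each to the band of its nearest band vertex (ties go to
#' the lowest vertex index, hence the lowest band), and reports per-band
#' counts and percentages of the EVC-connected total.
#'
#' @param trk a `tractogram` (whole session).
#' @param mesh a `labeled_mesh` with `eccentricity_band` vertex labels.
#' @param froi fROI id on the mesh.
#' @param radius_mm radial search radius (default 3).
#' @return list: `froi`, `counts` (length 3), `percentages` (sum 100), and
#'   `total` EVC-connected streamlines. With zero EVC-connected streamlines
#'   the percentages are `NA` (undefined-percentage sentinel).
#' @export
band_profile <- function(trk, mesh, froi, radius_mm = 3) {
  stopifnot(inherits(trk, "tractogram"), inherits(mesh, "labeled_mesh"))
  band_lab <- mesh$labels$eccentricity_band
  band_ix <- which(!is.na(band_lab))
  if (length(band_ix) == 0) stop("mesh has no eccentricity_band labels")
  hemi <- unique(mesh$labels$hemisphere[froi_vertices(mesh, froi)])
  band_ix <- band_ix[mesh$labels$hemisphere[band_ix] %in% hemi]
  roi_pts <- project_roi(mesh, froi_vertices(mesh, froi), 0)
  counts <- c(0L, 0L, 0L)
  if (trk$count > 0) {
    ep <- streamline_endpoints(trk)
    odd <- seq(1, nrow(ep), by = 2)
    nn_roi <- .nearest_ref(ep, roi_pts)
    hit1 <- nn_roi$dist[odd] <= radius_mm
    hit2 <- nn_roi$dist[odd + 1] <= radius_mm
    sel <- hit1 | hit2
    if (any(sel)) {
      # the seed endpoint is the one closer to the fROI; the other endpoint
      # is tested against the bands
      d1 <- nn_roi$dist[odd][sel]; d2 <- nn_roi$dist[odd + 1][sel]
      seed_first <- ifelse(hit1[sel] & hit2[sel], d1 <= d2, hit1[sel])
      other <- ifelse(seed_first, odd[sel] + 1, odd[sel])
      nn_band <- .nearest_ref(ep[other, , drop = FALSE],
                              mesh$vertices[band_ix, , drop = FALSE])
      in_band <- nn_band$dist <= radius_mm
      band_of <- band_lab[band_ix][nn_band$index[in_band]]
      counts <- vapply(1:3, function(b) sum(band_of == b), integer(1))
    }
  }
  total <- sum(counts)
  pct <- if (total > 0) 100 * counts / total else rep(NA_real_, 3)
  list(froi = froi, counts = counts, percentages = pct, total = total,
       bands = c("0-5", "5-10", "10-20"))
}

#' Eccentricity-band profiles for a whole cohort
#'
#' @param sessions session table; @param mesh labeled mesh;
#' @param tractograms named list or generator function as in
#'   [build_profile_matrix()].
#' @param hemisphere restrict to fROIs of this hemisphere (default `"lh"`,
#'   where all six regions exist).
#' @param radius_mm radial search radius.
#' @return data.frame: froi, session/subject metadata, category,
#'   cytoarchitecture, pct_central (0-5), pct_mid (5-10), pct_far (10-20),
#'   n_evc.
#' @export
band_profile_table <- function(sessions, mesh, tractograms, hemisphere = "lh",
                               radius_mm = 3) {
  frois <- froi_metadata(hemisphere)
  get_trk <- if (is.function(tractograms)) tractograms else {
    function(session) tractograms[[session$session_id]]
  }
  out <- list()
  for (si in seq_len(nrow(sessions))) {
    ses <- sessions[si, ]
    trk <- get_trk(ses)
    for (fi in seq_len(nrow(frois))) {
      bp <- band_profile(trk, mesh, frois$froi[fi], radius_mm)
      out[[length(out) + 1L]] <- data.frame(
        froi = frois$froi[fi], subject_id = ses$subject_id,
        session_id = ses$session_id, age_days = ses$age_days,
        age_group = as.character(ses$age_group),
        category = frois$category[fi],
        cytoarchitecture = frois$cytoarchitecture[fi],
        pct_central = bp$percentages[1], pct_mid = bp$percentages[2],
        pct_far = bp$percentages[3], n_evc = bp$total,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res$age_group <- factor(res$age_group, levels = .vtcwm_age_groups)
  res
}

#' Factorial model of central-band connectivity
#'
#' OLS of the central-5-degree percentage on the full three-way factorial
#' cytoarchitecture x category x age-group design (treatment coding), with
#' sequential type-I sums of squares in that factor order. Aliased columns
#' (the place-selective region exists only in FG3) are dropped by the
#' pivoted rank-revealing fit, which is what produces the characteristic
#' 1-df cytoarchitecture-by-category interaction.
#'
#' @param band_table from [band_profile_table()] (typically left hemisphere).
#' @return list: `anova` (term, df, sum_sq, F, p, eta_sq), `fit`
#'   (`vtcwm_fit`), `residual_df`.
#' @export
factorial_model <- function(band_table) {
  dat <- band_table[complete.cases(band_table[, c("pct_central")]), ]
  dat$cytoarchitecture <- factor(dat$cytoarchitecture, levels = .vtcwm_cytos)
  dat$category <- factor(dat$category, levels = .vtcwm_categories)
  dat$age_group <- droplevels(factor(dat$age_group, levels = .vtcwm_age_groups))
  for (v in c("cytoarchitecture", "category", "age_group")) {
    if (nlevels(droplevels(dat[[v]])) < 2) stop("factor ", v, " has < 2 levels")
  }
  fit <- lm(pct_central ~ cytoarchitecture * category * age_group, data = dat)
  if (fit$df.residual == 0) stop("rank-0 residual: design saturates the data")
  list(anova = sequential_anova(fit), fit = as_vtcwm_fit(fit),
       residual_df = fit$df.residual)
}

#' Post-hoc paired t tests between fROIs within a cytoarchitectonic area
#'
#' Session-matched paired t tests of the central-band percentage for given
#' fROI pairs, Bonferroni-corrected over `m` comparisons.
#'
#' @param band_table from [band_profile_table()].
#' @param pairs list of length-2 character vectors of fROI ids.
#' @param m Bonferroni denominator (default `length(pairs)`).
#' @return data.frame: froi_a, froi_b, n, t, df, p, p_adj, cohens_d,
#'   mean_diff, ci_lo, ci_hi.
#' @export
posthoc_paired_t <- function(band_table, pairs, m = length(pairs)) {
  out <- list()
  for (pr in pairs) {
    a <- band_table[band_table$froi == pr[1], c("session_id", "pct_central")]
    b <- band_table[band_table$froi == pr[2], c("session_id", "pct_central")]
    mrg <- merge(a, b, by = "session_id", suffixes = c("_a", "_b"))
    mrg <- mrg[complete.cases(mrg), ]
    tt <- t_test_d(mrg$pct_central_a, mrg$pct_central_b)
    out[[length(out) + 1L]] <- data.frame(
      froi_a = pr[1], froi_b = pr[2], n = tt$n, t = tt$t, df = tt$df,
      p = tt$p, cohens_d = tt$cohens_d, mean_diff = tt$estimate,
      ci_lo = tt$ci[1], ci_hi = tt$ci[2], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res$p_adj <- bonferroni(res$p, m)
  res
}

#' Random-intercept mixed model of development
#'
#' REML fit of `value ~ log10(age_days) + (1 | subject)` via
#' [lmerTest::lmer], with Satterthwaite degrees of freedom for the fixed age
#' slope. A boundary fit (between-subject variance estimated at zero)
#' collapses to the OLS solution and is flagged.
#'
#' @param values numeric response (e.g. central-band percentage).
#' @param age_days ages in days; @param subjects subject ids.
#' @return list: beta (slope per log10 day), se, df (Satterthwaite), t, p,
#'   ci (95%), intercept, var_subject, var_residual, boundary flag.
#' @export
lmm_random_intercept <- function(values, age_days, subjects) {
  stopifnot(length(values) == length(age_days),
            length(values) == length(subjects))
  dat <- data.frame(y = values, la = log10(age_days),
                    subject = factor(subjects))
  dat <- dat[complete.cases(dat), ]
  if (nlevels(droplevels(dat$subject)) < 2) stop("need at least 2 subjects")
  fit <- suppressMessages(
    lmerTest::lmer(y ~ la + (1 | subject), data = dat, REML = TRUE))
  sm <- coef(summary(fit))
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_subj <- vc$vcov[vc$grp == "subject"]
  var_resid <- vc$vcov[vc$grp == "Residual"]
  est <- sm["la", "Estimate"]; se <- sm["la", "Std. Error"]
  df <- sm["la", "df"]
  list(beta = est, se = se, df = df, t = sm["la", "t value"],
       p = sm["la", "Pr(>|t|)"],
       ci = est + c(-1, 1) * qt(0.975, df) * se,
       intercept = sm["(Intercept)", "Estimate"],
       var_subject = var_subj, var_residual = var_resid,
       boundary = lme4::isSingular(fit, tol = 1e-5))
}
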