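# a small mesh with one fROI parcel and three band parcels, plus hand-made
# streamlines, for direct band-assignment checks
band_fixture <- function() {
  mm <- tiny_mesh(n_parcels = 8, n_excluded = 1)
  mesh <- mm$mesh
  mesh$labels$froi[mesh$labels$parcel == "P001"] <- "lh.CoS-places"
  for (b in 1:3) {
    mesh$labels$eccentricity_band[mesh$labels$parcel ==
                                    sprintf("P%03d", b + 1)] <- b
  }
  mesh
}

test_that("band profiles count streamlines into nearest-band percentages", {
  mesh <- band_fixture()
  froi_v <- froi_vertices(mesh, "lh.CoS-places")
  b1 <- which(!is.na(mesh$labels$eccentricity_band) &
                mesh$labels$eccentricity_band == 1)
  sl <- lapply(1:5, function(i)
    sline(mesh$vertices[froi_v[1], ] + 0.2 * i,
          mesh$vertices[b1[1 + i %% length(b1)], ] + 0.1))
  bp <- band_profile(tractogram(sl), mesh, "lh.CoS-places")
  expect_equal(bp$percentages, c(100, 0, 0))
  expect_equal(bp$total, 5)

  # no EVC-connected streamlines: undefined-percentage sentinel
  far <- tractogram(list(sline(mesh$vertices[froi_v[1], ],
                               c(1000, 1000, 0))))
  bp0 <- band_profile(far, mesh, "lh.CoS-places")
  expect_true(all(is.na(bp0$percentages)))
  expect_equal(bp0$total, 0)
})

test_that("band assignment matches a brute-force nearest-vertex oracle", {
  mesh <- band_fixture()
  froi_v <- froi_vertices(mesh, "lh.CoS-places")
  band_ix <- which(!is.na(mesh$labels$eccentricity_band))
  set.seed(51)
  targets <- band_ix[sample.int(length(band_ix), 30, replace = TRUE)]
  sl <- lapply(seq_along(targets), function(i)
    sline(mesh$vertices[froi_v[1 + i %% length(froi_v)], ] +
            runif(3, -0.5, 0.5),
          mesh$vertices[targets[i], ] + runif(3, -0.5, 0.5)))
  bp <- band_profile(tractogram(sl), mesh, "lh.CoS-places")
  # oracle: nearest band vertex of each target endpoint
  oracle <- vapply(seq_along(targets), function(i) {
    e <- sl[[i]][3, ]
    d <- sqrt(colSums((t(mesh$vertices[band_ix, ]) - e)^2))
    mesh$labels$eccentricity_band[band_ix[which.min(d)]]
  }, integer(1))
  expect_equal(bp$counts, vapply(1:3, function(b) sum(oracle == b),
                                 integer(1)))
  expect_equal(sum(bp$percentages), 100, tolerance = 1e-9)
})

test_that("planted band proportions are recovered within multinomial bounds", {
  # a noise-free generator session: the only variation is multinomial
  cfg <- mesh_config(sigma_noise = 0, band_subject_sd = 0,
                     band_session_sd = 0, band_offsets = c("pFus-faces" = 0),
                     band_slopes = c("pFus-faces" = 0))
  mm <- make_labeled_mesh(cfg, seed = 6)
  ses <- data.frame(subject_id = "s1", session_id = "s1_1",
                    age_days = 10 ^ mm$truth$params$c0, age_group = "adult")
  trk <- sample_tractogram(mm$mesh, mm$truth, ses, 2000, seed = 9)
  bp <- band_profile(trk, mm$mesh, "lh.pFus-faces")
  planted <- mm$truth$band_props["FG2", ]   # (0.636, 0.098, 0.266)
  # each band count within its binomial 99% interval around n * p
  for (b in 1:3) {
    lim <- qnorm(0.995) * sqrt(bp$total * planted[b] * (1 - planted[b]))
    expect_lte(abs(bp$counts[b] - bp$total * planted[b]), lim + 1)
  }
})

test_that("factorial replica design yields the forced df pattern", {
  # 6 left-hemisphere fROIs x 88 sessions with synthetic percentages
  frois <- froi_metadata("lh")
  co <- make_cohort(seed = 3)
  set.seed(52)
  tab <- merge(frois, co)
  tab$pct_central <- rnorm(nrow(tab), 50, 10)
  res <- factorial_model(tab)
  expect_equal(res$residual_df, 504)
  a <- res$anova
  expect_equal(a$df[match(c("cytoarchitecture", "category", "age_group",
                            "cytoarchitecture:category",
                            "cytoarchitecture:age_group",
                            "category:age_group",
                            "cytoarchitecture:category:age_group"),
                          a$term)],
               c(2, 2, 3, 1, 6, 6, 3))
  expect_lte(sum(a$eta_sq[a$term != "Residuals"]), 1)
})

test_that("factorial type-I error is calibrated under the null", {
  frois <- froi_metadata("lh")
  groups <- c("newborn", "3mo", "6mo", "adult")
  base <- merge(frois, expand.grid(age_group = groups, rep = 1:3))
  base$age_group <- factor(base$age_group, levels = groups)
  set.seed(53)
  hits <- vapply(1:500, function(i) {
    base$pct_central <- rnorm(nrow(base), 40, 8)  # all cell means equal
    a <- factorial_model(base)$anova
    a$p[a$term == "cytoarchitecture"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.03)
  expect_lte(mean(hits), 0.07)
})

test_that("paired post-hoc t tests: null, closed form, session matching", {
  tab <- data.frame(froi = rep(c("A", "B"), each = 3),
                    session_id = rep(1:3, 2),
                    pct_central = c(5, 6, 7, 5, 6, 7))
  res <- posthoc_paired_t(tab, list(c("A", "B")))
  expect_equal(res$t, 0)
  expect_equal(res$p_adj, 1)

  tab2 <- data.frame(froi = rep(c("A", "B"), each = 3),
                     session_id = rep(1:3, 2),
                     pct_central = c(1, 0, 2, 0, 0, 0))
  res2 <- posthoc_paired_t(tab2, list(c("A", "B")), m = 4)
  expect_equal(res2$t, sqrt(3), tolerance = 1e-10)
  expect_equal(res2$df, 2)
  expect_equal(res2$p_adj, min(1, res2$p * 4))
})

test_that("mixed model collapses to OLS without between-subject variance", {
  set.seed(54)
  n <- 60
  la <- runif(n, 1.3, 4)
  subj <- rep(sprintf("s%d", 1:20), 3)
  y <- 10 - 2 * la + rnorm(n, 0, 1)   # no subject effect
  res <- lmm_random_intercept(y, 10^la, subj)
  ols <- coef(lm(y ~ la))[2]
  expect_equal(res$beta, unname(ols), tolerance = 1e-6)
  expect_true(res$boundary)
})

test_that("REML optimum beats a grid of variance ratios", {
  set.seed(55)
  subj <- rep(sprintf("s%d", 1:15), each = 3)
  la <- runif(45, 1.3, 4)
  y <- 5 + 2 * la + rep(rnorm(15, 0, 2), each = 3) + rnorm(45, 0, 1)
  dat <- data.frame(y = y, la = la, subject = factor(subj))
  fit <- lme4::lmer(y ~ la + (1 | subject), data = dat, REML = TRUE)
  dev_opt <- lme4::REMLcrit(fit)
  devfun <- lme4::lmer(y ~ la + (1 | subject), data = dat, REML = TRUE,
                       devFunOnly = TRUE)
  grid <- seq(0.01, 5, length.out = 50)
  expect_lte(dev_opt, min(vapply(grid, devfun, numeric(1))) + 1e-6)
})

test_that("planted mixed-model slopes are recovered at cohort scale", {
  # cohort-like layout: 67 infant sessions over 42 subjects + 21 adults
  co <- make_cohort(seed = 8)
  la <- log10(co$age_days)
  set.seed(999)
  hits <- vapply(1:100, function(i) {
    subj_re <- rnorm(length(unique(co$subject_id)), 0, 3)
    names(subj_re) <- unique(co$subject_id)
    y <- 50 - 2.75 * la + subj_re[co$subject_id] + rnorm(nrow(co), 0, 5)
    r <- lmm_random_intercept(y, co$age_days, co$subject_id)
    r$ci[1] <= -2.75 && -2.75 <= r$ci[2]
  }, logical(1))
  expect_gte(sum(hits), 93)
})
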