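# a small profile matrix with planted per-parcel slopes, built directly
planted_pm <- function(n_ses = 40, n_parcel = 30, slopes = NULL, noise = 0.01,
                       seed = 61, froi = "lh.mFus-faces") {
  set.seed(seed)
  la <- runif(n_ses, log10(20), log10(11000))
  if (is.null(slopes)) slopes <- rnorm(n_parcel, 0, 0.004)
  base <- runif(n_parcel, 0.01, 0.05)
  Y <- outer(rep(1, n_ses), base) + outer(la - 2.7, slopes) +
    matrix(rnorm(n_ses * n_parcel, 0, noise), n_ses, n_parcel)
  colnames(Y) <- sprintf("P%03d", seq_len(n_parcel))
  meta <- data.frame(
    froi = froi, subject_id = sprintf("s%02d", seq_len(n_ses)),
    session_id = sprintf("s%02d_1", seq_len(n_ses)), age_days = 10^la,
    age_group = "3mo", hemisphere = "lh", category = "faces",
    cytoarchitecture = "FG4", stringsAsFactors = FALSE)
  list(pm = structure(list(matrix = Y, meta = meta, parcels = colnames(Y)),
                      class = "profile_matrix"),
       la = la, slopes = slopes, base = base)
}

test_that("slope maps recover planted slopes and flag constants", {
  fx <- planted_pm()
  sm <- slope_map(fx$pm, "lh.mFus-faces")
  expect_equal(nrow(sm), 30)
  # coverage: planted slope inside the 95% CI for most parcels
  covered <- mean(sm$ci_lo <= fx$slopes & fx$slopes <= sm$ci_hi)
  expect_gte(covered, 0.8)
  # constant-density parcel: slope exactly 0
  fx2 <- planted_pm(slopes = rep(0, 30), noise = 0)
  sm2 <- slope_map(fx2$pm, "lh.mFus-faces")
  expect_equal(sm2$slope, rep(0, 30), tolerance = 1e-12)
})

test_that("per-parcel CI coverage hits the nominal rate across simulations", {
  covered <- vapply(1:100, function(i) {
    fx <- planted_pm(n_ses = 30, n_parcel = 12, seed = 600 + i)
    sm <- slope_map(fx$pm, "lh.mFus-faces")
    mean(sm$ci_lo <= fx$slopes & fx$slopes <= sm$ci_hi)
  }, numeric(1))
  expect_gte(mean(covered), 0.93)
})

test_that("slope maps agree with the interaction-model parameterization", {
  fx <- planted_pm(n_ses = 25, n_parcel = 8)
  sm <- slope_map(fx$pm, "lh.mFus-faces")
  mod <- age_by_parcel_model(fx$pm, "lh.mFus-faces")
  expect_equal(mod$n_long, 25 * 8)
  cf <- coef(mod$fit$lm)
  # per-parcel slope = la coefficient + la:parcel interaction contrast
  slopes_lm <- cf["la"] + c(0, cf[grep("^la:parcel", names(cf))])
  expect_equal(sm$slope, unname(slopes_lm), tolerance = 1e-8)
})

test_that("age-by-parcel interaction detects planted heterogeneity", {
  hits <- vapply(1:50, function(i) {
    fx <- planted_pm(n_ses = 60, n_parcel = 10,
                     slopes = seq(-0.006, 0.006, length.out = 10),
                     noise = 0.008, seed = 700 + i)
    a <- age_by_parcel_model(fx$pm, "lh.mFus-faces")$anova
    a$p[a$term == "la:parcel"] < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("age-by-parcel interaction is calibrated under identical slopes", {
  hits <- vapply(1:500, function(i) {
    fx <- planted_pm(n_ses = 16, n_parcel = 5,
                     slopes = rep(0.003, 5), noise = 0.01, seed = 800 + i)
    a <- age_by_parcel_model(fx$pm, "lh.mFus-faces")$anova
    a$p[a$term == "la:parcel"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.03)
  expect_lte(mean(hits), 0.07)
})

test_that("degenerate bootstrap equals the plain slope map", {
  fx <- planted_pm(n_ses = 20, n_parcel = 6)
  bs <- bootstrap_slopes(fx$pm, "lh.mFus-faces", n_iter = 1,
                         subsample_fraction = 1.0, seed = 1)
  sm <- slope_map(fx$pm, "lh.mFus-faces")
  expect_equal(as.numeric(bs[1, ]), sm$slope, tolerance = 1e-12)
})

test_that("bootstrap spread is commensurate with the analytic slope SE", {
  fx <- planted_pm(n_ses = 60, n_parcel = 6, noise = 0.01, seed = 62)
  bs <- bootstrap_slopes(fx$pm, "lh.mFus-faces", n_iter = 400,
                         subsample_fraction = 0.75, seed = 2)
  sm <- slope_map(fx$pm, "lh.mFus-faces")
  for (k in 1:6) {
    expect_lt(sd(bs[, k]), 2 * sm$se[k])
    expect_gt(sd(bs[, k]), sm$se[k] / 4)
  }
})

test_that("bootstrap subsampling is 75% without replacement, deterministic", {
  idx <- bootstrap_indices(88, n_iter = 10, subsample_fraction = 0.75,
                           seed = 5)
  expect_equal(ncol(idx), 66)
  expect_true(all(apply(idx, 1, function(r) !anyDuplicated(r))))
  expect_identical(idx, bootstrap_indices(88, 10, 0.75, seed = 5))
})

test_that("slope similarity is symmetric with finite boundary z", {
  fx1 <- planted_pm(n_ses = 30, n_parcel = 10, seed = 63,
                    froi = "lh.mFus-faces")
  A <- bootstrap_slopes(fx1$pm, "lh.mFus-faces", n_iter = 20, seed = 3)
  B <- A + matrix(rnorm(length(A), 0, 1e-4), nrow(A))
  frois <- froi_metadata("lh")
  sim <- slope_similarity(list("lh.mFus-faces" = A, "lh.OTS-bodies" = B),
                          frois)
  # symmetry: recompute with the pair order swapped
  sim2 <- slope_similarity(list("lh.OTS-bodies" = B, "lh.mFus-faces" = A),
                           frois)
  expect_equal(sort(sim$table$r), sort(sim2$table$r), tolerance = 1e-12)
  # near-identical vectors: r ~ 1 but z stays finite
  expect_true(all(is.finite(sim$table$z)))
  expect_gt(min(sim$table$r), 0.99)
  # identical vectors: clipped finite z
  simid <- suppressWarnings(
    slope_similarity(list("lh.mFus-faces" = A, "lh.OTS-bodies" = A), frois))
  expect_true(all(is.finite(simid$table$z)))
  expect_equal(simid$table$r, rep(1, 20))
})

test_that("similarity model flags planted parallel development", {
  # three fROIs: two share a drift pattern (same area), one independent
  set.seed(64)
  sh <- rnorm(20, 0, 0.004)
  mk <- function(froi, slopes, seed)
    bootstrap_slopes(planted_pm(n_ses = 50, n_parcel = 20, slopes = slopes,
                                noise = 0.01, seed = seed, froi = froi)$pm,
                     froi, n_iter = 50, seed = seed)
  boots <- list(
    "lh.mFus-faces" = mk("lh.mFus-faces", sh, 101),
    "lh.OTS-bodies" = mk("lh.OTS-bodies", sh, 102),           # same FG4
    "lh.pFus-faces" = mk("lh.pFus-faces", rnorm(20, 0, 0.004), 103))
  sim <- slope_similarity(boots, froi_metadata("lh"))
  cf <- sim$fit$coefficients
  same_cyto <- cf$estimate[cf$term == "same_cytoarchitecture"]
  same_cat <- cf$estimate[cf$term == "same_category"]
  expect_gt(same_cyto, 0)
  expect_gt(same_cyto, same_cat)
})
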