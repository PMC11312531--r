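test_that("PCA: rank-1 data, eigen oracle, reconstruction identity", {
  # rank-1 matrix: first component carries all variance
  u <- 1:8; v <- c(2, -1, 3)
  p1 <- fit_pca(outer(u, v))
  expect_equal(p1$variance_explained[1], 100, tolerance = 1e-9)

  set.seed(41)
  X <- matrix(rnorm(60), 10, 6)
  pc <- fit_pca(X)
  # oracle: eigen-decomposition of the covariance
  ev <- eigen(cov(X), symmetric = TRUE)$values
  expect_equal(pc$variance_explained, 100 * ev / sum(ev), tolerance = 1e-8)
  # scores x loadings' reproduces the centered data at full rank
  rec <- pc$scores %*% t(pc$loadings)
  ctr <- sweep(X, 2, colMeans(X))
  expect_lt(max(abs(rec - ctr)), 1e-8)
  # sign convention: largest-magnitude loading entry positive
  for (k in seq_len(ncol(pc$loadings))) {
    lv <- pc$loadings[, k]
    expect_gt(lv[which.max(abs(lv))], 0)
  }
})

test_that("elbow finding matches brute-force perpendicular distance", {
  brute <- function(curve) {
    n <- length(curve)
    p1 <- c(1, curve[1]); p2 <- c(n, curve[n])
    d <- vapply(1:n, function(i) {
      v <- p2 - p1; w <- c(i, curve[i]) - p1
      abs(v[1] * w[2] - v[2] * w[1]) / sqrt(sum(v^2))
    }, numeric(1))
    which.max(d)
  }
  curve <- c(50, 30, 10, 5, 3, 2)
  expect_equal(find_elbow(curve), brute(curve))
  expect_equal(find_elbow(c(90, 5, 5)), 2)
  # straight line: zero distance everywhere, tie -> index 1
  expect_equal(find_elbow(c(30, 20, 10)), 1)
  expect_error(find_elbow(c(1, 5, 2)), "non-increasing")
  set.seed(42)
  for (i in 1:10) {
    cv <- sort(runif(8, 0, 100), decreasing = TRUE)
    expect_equal(find_elbow(cv), brute(cv))
  }
})

test_that("two-class multinomial matches binary logistic regression", {
  set.seed(43)
  X <- matrix(rnorm(120), 60, 2)
  y <- ifelse(X[, 1] + rnorm(60, 0, 2) > 0, "pos", "neg")
  fit <- fit_multinomial(X, y, levels = c("neg", "pos"), ridge = 0)
  pr <- predict_wta(fit, X)$probabilities
  oracle <- glm(factor(y, levels = c("neg", "pos")) ~ X,
                family = binomial())
  expect_equal(unname(pr[, "pos"]), unname(fitted(oracle)), tolerance = 1e-5)
})

test_that("multinomial likelihood is invariant to row duplication", {
  set.seed(44)
  X <- matrix(rnorm(90), 30, 3)
  y <- rep(c("a", "b", "c"), 10)
  f1 <- fit_multinomial(X, y, levels = c("a", "b", "c"))
  f2 <- fit_multinomial(rbind(X, X), c(y, y), levels = c("a", "b", "c"))
  p1 <- predict_wta(f1, X)$probabilities
  p2 <- predict_wta(f2, X)$probabilities
  expect_equal(p1, p2, tolerance = 1e-3)
})

test_that("winner-take-all is an exhaustive argmax with canonical ties", {
  set.seed(45)
  X <- matrix(rnorm(40), 20, 2)
  y <- sample(c("u", "v", "w"), 20, replace = TRUE)
  fit <- fit_multinomial(X, y, levels = c("u", "v", "w"))
  res <- predict_wta(fit, X)
  expect_equal(unname(rowSums(res$probabilities)), rep(1, 20),
               tolerance = 1e-12)
  # brute-force max over classes
  oracle <- colnames(res$probabilities)[apply(res$probabilities, 1, which.max)]
  expect_equal(res$labels, oracle)
  # separable single-feature data: decision boundary sign correct
  xs <- matrix(c(-3, -2, -1, 1, 2, 3), ncol = 1)
  ys <- c("lo", "lo", "lo", "hi", "hi", "hi")
  fs <- fit_multinomial(xs, ys, levels = c("lo", "hi"), ridge = 1e-4)
  expect_equal(predict_wta(fs, xs)$labels, ys)
})

test_that("leave-one-subject-out recovers separable labels and guards folds", {
  set.seed(46)
  n_sub <- 12
  meta <- data.frame(
    froi = rep(c("f1", "f2"), n_sub),
    subject_id = rep(sprintf("s%02d", 1:n_sub), each = 2),
    session_id = rep(sprintf("s%02d_1", 1:n_sub), each = 2),
    age_days = 100, age_group = "3mo", hemisphere = "lh",
    category = rep(c("faces", "places"), n_sub),
    cytoarchitecture = rep(c("FG2", "FG3"), n_sub),
    stringsAsFactors = FALSE)
  X <- matrix(rnorm(n_sub * 2 * 6, sd = 0.1), n_sub * 2, 6)
  X[meta$cytoarchitecture == "FG2", 1] <- X[meta$cytoarchitecture == "FG2", 1] + 5
  pm <- structure(list(matrix = X, meta = meta,
                       parcels = paste0("P", 1:6)), class = "profile_matrix")
  res <- loo_classify(pm, "cytoarchitecture", n_components = 3)
  expect_equal(res$overall_mean, 1)
  expect_equal(nrow(res$per_session_accuracy), n_sub)
  expect_equal(unname(rowSums(res$confusion)), rep(100, 2), tolerance = 1e-9)
  # balanced variant agrees on balanced-by-construction data
  resb <- loo_classify(pm, "cytoarchitecture", n_components = 3,
                       balanced = TRUE, n_resample_per_label = 50, seed = 2)
  expect_lte(abs(resb$overall_mean - res$overall_mean), 0.03)
  # a label absent from a training fold is a hard error
  meta2 <- meta
  meta2$cytoarchitecture <- c("FG4", rep(c("FG2", "FG3"), n_sub))[1:(2 * n_sub)]
  pm2 <- structure(list(matrix = X, meta = meta2, parcels = paste0("P", 1:6)),
                   class = "profile_matrix")
  expect_error(loo_classify(pm2, "cytoarchitecture", n_components = 2),
               "absent from training fold")
})

test_that("task comparison reproduces closed-form odds ratios", {
  mk <- function(task, correct) {
    structure(list(task = task,
                   predictions = data.frame(correct = correct)),
              class = "classification_result")
  }
  # identical correctness vectors: OR = 1
  cc <- c(rep(1, 30), rep(0, 10))
  out <- compare_tasks(list(mk("cytoarchitecture", cc), mk("category", cc)))
  expect_equal(out$or, 1, tolerance = 1e-8)
  # 2x2 closed form ad/bc
  a <- 25; b <- 15; c <- 10; d <- 30
  out2 <- compare_tasks(list(mk("cytoarchitecture", c(rep(1, a), rep(0, b))),
                             mk("category", c(rep(1, c), rep(0, d)))))
  expect_equal(out2$or, (a * d) / (b * c), tolerance = 1e-6)
})

test_that("accuracy-vs-chance uses the closed-form one-sample t", {
  acc <- c(0.6, 0.5, 0.7)
  res <- accuracy_vs_chance(acc, chance = 0.5)
  m <- mean(acc); s <- sd(acc)
  expect_equal(res$t, (m - 0.5) / (s / sqrt(3)), tolerance = 1e-10)
  expect_equal(res$df, 2)
  expect_equal(res$cohens_d, (m - 0.5) / s, tolerance = 1e-10)
  # accuracies all equal to chance: degenerate SD sentinel with t = 0
  flat <- accuracy_vs_chance(rep(0.25, 5), chance = 0.25)
  expect_equal(flat$t, 0)
})
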