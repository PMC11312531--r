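test_that("parcel aggregation drops excluded mass after normalization", {
  mesh <- square_mesh(parcels = c("A", "A", "X", "X"),
                      excluded = c(FALSE, FALSE, TRUE, TRUE))
  # 6 endpoints at vertices of A (density 0.6), 4 at excluded X
  dm <- structure(list(density = c(0.3, 0.3, 0.2, 0.2), total_endpoints = 10L,
                       dropped = 0L), class = "endpoint_density")
  vals <- aggregate_to_parcels(dm, mesh, "lh", renormalize = FALSE)
  expect_equal(unname(vals["A"]), 0.6)
  expect_equal(sum(vals), 0.6)
  expect_false("X" %in% names(vals))

  ren <- aggregate_to_parcels(dm, mesh, "lh", renormalize = TRUE)
  expect_equal(unname(ren["A"]), 1.0)

  bad <- structure(list(density = c(0.5, 0.5), total_endpoints = 2L,
                        dropped = 0L), class = "endpoint_density")
  expect_error(aggregate_to_parcels(bad, mesh, "lh"), "does not match")
})

test_that("parcel aggregation matches a brute-force group sum", {
  set.seed(31)
  mm <- tiny_mesh(n_parcels = 5)$mesh   # 50-ish vertices over 5 parcels
  d <- runif(mm$n_vertices)
  d <- d / sum(d)
  dm <- structure(list(density = d, total_endpoints = 100L, dropped = 0L),
                  class = "endpoint_density")
  vals <- aggregate_to_parcels(dm, mm, "lh")
  oracle <- vapply(sort(unique(mm$labels$parcel)), function(p)
    sum(d[mm$labels$parcel == p]), numeric(1))
  expect_equal(vals, oracle[names(vals)], tolerance = 1e-12)
  # conservation: retained + excluded mass is the full surface mass
  expect_equal(sum(vals), sum(d), tolerance = 1e-12)
})

test_that("profiles are invariant to parcel-preserving vertex relabeling", {
  mm <- tiny_mesh(n_parcels = 5)$mesh
  set.seed(32)
  d <- runif(mm$n_vertices); d <- d / sum(d)
  dm <- structure(list(density = d, total_endpoints = 50L, dropped = 0L),
                  class = "endpoint_density")
  v1 <- aggregate_to_parcels(dm, mm, "lh")
  # permute vertices within parcels (permute density the same way)
  perm <- unlist(lapply(split(seq_len(mm$n_vertices), mm$labels$parcel),
                        sample), use.names = FALSE)
  mm2 <- mm
  mm2$labels <- mm$labels[perm, ]
  dm2 <- dm; dm2$density <- d[perm]
  v2 <- aggregate_to_parcels(dm2, mm2, "lh")
  expect_equal(v1, v2, tolerance = 1e-12)
})

test_that("profile matrix has canonical shape and ordering", {
  mm <- fixture("default_mesh", function() make_labeled_mesh(seed = 1))
  ses <- data.frame(subject_id = c("s2", "s1"), session_id = c("s2_1", "s1_1"),
                    age_days = c(30, 120),
                    age_group = factor(c("newborn", "3mo"),
                                       levels = levels(make_cohort()$age_group)),
                    stringsAsFactors = FALSE)
  gen <- function(session) sample_tractogram(mm$mesh, mm$truth, session, 100,
                                             seed = 1 + match(session$session_id,
                                                              c("s1_1", "s2_1")))
  pm <- build_profile_matrix(ses, mm$mesh, gen)
  expect_equal(dim(pm$matrix), c(20, 169))
  expect_equal(pm$meta$session_id[1:10], rep("s1_1", 10))  # canonical order
  # shuffled session input gives the identical matrix
  pm2 <- build_profile_matrix(ses[2:1, ], mm$mesh, gen)
  expect_identical(pm$matrix, pm2$matrix)
  expect_identical(pm$meta, pm2$meta)
  # one session, one fROI
  mesh1 <- mm$mesh
  ses1 <- ses[2, ]
  pm1 <- build_profile_matrix(ses1, mesh1, gen)
  expect_equal(sum(pm1$meta$session_id == "s1_1"), 10)
})

test_that("profile matrices round-trip through TSV", {
  mm <- fixture("default_mesh", function() make_labeled_mesh(seed = 1))
  ses <- data.frame(subject_id = "s1", session_id = "s1_1", age_days = 200,
                    age_group = factor("6mo", levels = .lvls <- c("newborn", "3mo", "6mo", "adult")),
                    stringsAsFactors = FALSE)
  pm <- build_profile_matrix(ses, mm$mesh, function(s)
    sample_tractogram(mm$mesh, mm$truth, s, 80, seed = 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profile_matrix(pm, path)
  back <- read_profile_matrix(path)
  expect_equal(back$matrix, pm$matrix, tolerance = 1e-12)
  expect_equal(back$meta$froi, pm$meta$froi)
})

test_that("relative-area model: nulls, degenerate input, slope recovery", {
  # constant ratio in age: slope 0, t 0
  ar <- data.frame(froi_area = rep(5, 10), hemi_area = rep(100, 10),
                   age_days = seq(20, 10000, length.out = 10))
  res <- relative_area_model(ar)
  expect_equal(res$slope$estimate, 0)
  expect_equal(res$slope$statistic, 0)
  expect_equal(res$residual_df, 8)
  expect_error(relative_area_model(transform(ar, hemi_area = 0)), "positive")

  # planted slope recovered within the 95% CI in >= 93/100 simulations
  set.seed(33)
  la <- log10(rep(seq(20, 10000, length.out = 88), each = 10))
  hits <- vapply(1:100, function(i) {
    ratio <- 0.05 + 0.01 * la + rnorm(length(la), 0, 1e-4)
    r <- relative_area_model(data.frame(froi_area = ratio, hemi_area = 1,
                                        age_days = 10^la))
    r$slope$ci_lo <= 0.01 && 0.01 <= r$slope$ci_hi
  }, logical(1))
  expect_gte(sum(hits), 93)
})
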