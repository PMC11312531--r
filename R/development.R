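# Developmental analysis: per-parcel endpoint-density slopes against
# log10(age), the global age-by-parcel interaction test, bootstrap slope
# estimation, and slope-similarity modelling across fROI pairs.

# rows of a profile matrix belonging to one fROI, in session order
.froi_rows <- function(pm, froi) {
  ix <- which(pm$meta$froi == froi)
  if (length(ix) == 0) stop("fROI not present in profile matrix: ", froi)
  ix
}

#' Age-by-parcel interaction model for one fROI
#'
#' Reshapes the fROI's profiles to long form (one row per profile x parcel)
#' and fits an OLS with parcel main effect, log10(age) main effect, and the
#' age-by-parcel interaction. No per-subject random intercept is used:
#' densities are normalized over the surface, which removes the subject-level
#' scale a random intercept would absorb. Parcels with all-zero density are
#' retained (zeros are data) but flagged.
#'
#' @param pm a `profile_matrix`; @param froi fROI id.
#' @return list: `anova` (sequential), `n_long` (long-form rows),
#'   `zero_parcels` (all-zero parcel names), `fit`.
#' @export
age_by_parcel_model <- function(pm, froi) {
  ix <- .froi_rows(pm, froi)
  Y <- pm$matrix[ix, , drop = FALSE]
  la <- log10(pm$meta$age_days[ix])
  zero_parcels <- colnames(Y)[colSums(Y != 0) == 0]
  long <- data.frame(
    density = as.vector(Y),
    la = rep(la, times = ncol(Y)),
    parcel = factor(rep(colnames(Y), each = nrow(Y)), levels = colnames(Y)))
  fit <- lm(density ~ la * parcel, data = long)
  list(anova = sequential_anova(fit), n_long = nrow(long),
       zero_parcels = zero_parcels, fit = as_vtcwm_fit(fit))
}

# vectorized per-parcel simple regressions of Y columns on x
.colwise_slopes <- function(x, Y) {
  n <- length(x)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  if (sxx == 0) stop("no age variation in the (sub)sample")
  ym <- colMeans(Y)
  slope <- as.numeric(crossprod(xc, Y)) / sxx
  intercept <- ym - slope * mean(x)
  fitted_ss <- outer(xc, slope)
  resid <- Y - rep(ym, each = n) - fitted_ss
  rss <- colSums(resid^2)
  se <- sqrt(rss / (n - 2) / sxx)
  tstat <- ifelse(se > 0, slope / se, 0)
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  data.frame(parcel = colnames(Y), slope = slope, intercept = intercept,
             se = se, t = tstat, p = p, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Per-parcel developmental slope map for one fROI
#'
#' Independent simple regressions of each parcel's endpoint density on
#' log10(age in days); a positive slope means increasing density with age.
#'
#' @param pm a `profile_matrix`; @param froi fROI id.
#' @return data.frame (class `slope_map`): parcel, slope
#'   (density per log10 day), intercept, se, t, p, plus 95% CI columns.
#' @export
slope_map <- function(pm, froi) {
  ix <- .froi_rows(pm, froi)
  la <- log10(pm$meta$age_days[ix])
  out <- .colwise_slopes(la, pm$matrix[ix, , drop = FALSE])
  crit <- qt(0.975, length(ix) - 2)
  out$ci_lo <- out$slope - crit * out$se
  out$ci_hi <- out$slope + crit * out$se
  attr(out, "froi") <- froi
  class(out) <- c("slope_map", class(out))
  out
}

#' Bootstrap distribution of developmental slopes
#'
#' Repeatedly subsamples a fraction of the fROI's profiles *without*
#' replacement (66 of 88 at the defaults) and refits all per-parcel slopes.
#' Iterations whose subsample has a single unique age are redrawn (counted,
#' capped). Deterministic given `seed`.
#'
#' @param pm a `profile_matrix`; @param froi fROI id.
#' @param n_iter bootstrap iterations (default 1000).
#' @param subsample_fraction fraction of profiles per iteration (default
#'   0.75; subsample size is `floor(fraction * n)`).
#' @param seed RNG seed.
#' @param indices optional `n_iter x subsample_size` matrix of precomputed
#'   row indices (used to pair subsamples across fROIs).
#' @return `n_iter x parcels` matrix of slopes, with attributes `froi` and
#'   `n_redrawn`.
#' @export
bootstrap_slopes <- function(pm, froi, n_iter = 1000,
                             subsample_fraction = 0.75, seed = 1,
                             indices = NULL) {
  ix <- .froi_rows(pm, froi)
  n <- length(ix)
  m <- floor(subsample_fraction * n)
  if (m < 3) stop("subsample size must be at least 3")
  la <- log10(pm$meta$age_days[ix])
  Y <- pm$matrix[ix, , drop = FALSE]
  if (is.null(indices)) {
    indices <- bootstrap_indices(n, n_iter, subsample_fraction, seed,
                                 ages = la)
  }
  stopifnot(ncol(indices) == m)
  out <- matrix(NA_real_, nrow(indices), ncol(Y),
                dimnames = list(NULL, colnames(Y)))
  for (b in seq_len(nrow(indices))) {
    s <- indices[b, ]
    out[b, ] <- .colwise_slopes(la[s], Y[s, , drop = FALSE])$slope
  }
  attr(out, "froi") <- froi
  attr(out, "n_redrawn") <- attr(indices, "n_redrawn")
  out
}

#' Precompute paired bootstrap subsample indices
#'
#' Draws `n_iter` subsamples of `floor(fraction * n)` out of `n` without
#' replacement; when `ages` is supplied, any subsample with a single unique
#' age (which would make the slope regression degenerate) is redrawn, up to
#' `max_redraw` times, and the redraws are counted. Sharing this matrix
#' across fROIs pairs iteration k across all of them.
#'
#' @param n profiles available; @param n_iter iterations;
#' @param subsample_fraction fraction; @param seed RNG seed.
#' @param ages optional per-profile ages used for the degeneracy check.
#' @param max_redraw cap on redraws.
#' @return `n_iter x m` integer matrix with attribute `n_redrawn`.
#' @export
bootstrap_indices <- function(n, n_iter = 1000, subsample_fraction = 0.75,
                              seed = 1, ages = NULL, max_redraw = 100) {
  m <- floor(subsample_fraction * n)
  stopifnot(m >= 1, m <= n)
  .with_seed(seed, {
    redrawn <- 0L
    mat <- matrix(NA_integer_, n_iter, m)
    for (b in seq_len(n_iter)) {
      for (try in seq_len(max_redraw + 1L)) {
        s <- sample.int(n, m)
        if (is.null(ages) || length(unique(ages[s])) > 1) break
        redrawn <- redrawn + 1L
      }
      mat[b, ] <- sort(s)
    }
    attr(mat, "n_redrawn") <- redrawn
    mat
  })
}

#' Similarity of developmental slopes across fROI pairs
#'
#' For every unordered fROI pair and bootstrap iteration, the Pearson
#' correlation between the two per-parcel slope vectors; Fisher-z transformed
#' correlations are modelled on same-category and same-cytoarchitecture
#' indicators (1 = same, 0 = different) by OLS.
#'
#' @param boot_slopes named list of bootstrap slope matrices (one per fROI,
#'   equal dimensions; pair iterations by sharing [bootstrap_indices()]).
#' @param froi_meta data.frame with `froi`, `category`, `cytoarchitecture`
#'   (e.g. [froi_metadata()]).
#' @param method correlation method (`"pearson"` default, `"spearman"`
#'   available).
#' @return list: `table` (froi_a, froi_b, iteration, r, z, same_category,
#'   same_cytoarchitecture), `fit` (`vtcwm_fit` of z on the indicators),
#'   `dropped` (zero-variance pair-iterations removed), `pair_summary`.
#' @export
slope_similarity <- function(boot_slopes, froi_meta, method = "pearson") {
  frois <- names(boot_slopes)
  stopifnot(length(frois) >= 2, all(frois %in% froi_meta$froi))
  dims <- lapply(boot_slopes, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1) {
    stop("all bootstrap slope arrays must share dimensions")
  }
  n_iter <- nrow(boot_slopes[[1]])
  meta <- froi_meta[match(frois, froi_meta$froi), ]
  rows <- list()
  dropped <- 0L
  for (i in seq_along(frois)) for (j in seq_along(frois)) {
    if (i >= j) next
    A <- boot_slopes[[i]]; B <- boot_slopes[[j]]
    sa <- apply(A, 1, sd); sb <- apply(B, 1, sd)
    ok <- sa > 0 & sb > 0
    dropped <- dropped + sum(!ok)
    r <- rep(NA_real_, n_iter)
    r[ok] <- vapply(which(ok), function(b)
      cor(A[b, ], B[b, ], method = method), numeric(1))
    rows[[length(rows) + 1L]] <- data.frame(
      froi_a = frois[i], froi_b = frois[j], iteration = seq_len(n_iter),
      r = r, z = fisher_z(r),
      same_category = as.integer(meta$category[i] == meta$category[j]),
      same_cytoarchitecture =
        as.integer(meta$cytoarchitecture[i] == meta$cytoarchitecture[j]),
      stringsAsFactors = FALSE)[ok, ]
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  fit <- ols_fit(z ~ same_category + same_cytoarchitecture, data = tab)
  pair_summary <- stats::aggregate(r ~ froi_a + froi_b + same_category +
                                     same_cytoarchitecture, data = tab, FUN = mean)
  list(table = tab, fit = fit, dropped = dropped, pair_summary = pair_summary)
}
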