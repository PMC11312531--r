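# Synthetic labeled mesh + ground truth. The mesh is a flat 4-mm grid per
# hemisphere, tiled into square parcels (180/hemisphere by default, the first
# 11 flagged as seed-region-excluded and housing the fROIs, the next three
# serving as the early-visual-cortex eccentricity bands). The ground truth
# plants the statistical structure every downstream stage is tested against:
# endpoint distributions clustered strongly by cytoarchitectonic area, weakly
# by category, drifting with log10(age), and eccentricity-band proportions
# differing by cytoarchitectonic area.

#' Mesh/ground-truth generator configuration
#'
#' @param n_parcels parcels per hemisphere (default 180).
#' @param n_excluded leading parcels flagged as seed-region-excluded (11).
#' @param hemispheres which hemispheres to build.
#' @param spacing_mm vertex grid spacing.
#' @param with_frois,with_bands place fROI / eccentricity-band labels
#'   (requires enough parcels).
#' @param n_hub,hub_weight hub parcels per cytoarchitectonic area and their
#'   weight relative to the floor weight 1 (the dominant, cytoarchitecture
#'   effect).
#' @param n_cat_parcels,cat_tilt parcels per category receiving a
#'   multiplicative tilt (the weaker category effect).
#' @param amp relative endpoint-density change per log10(day) along each
#'   fROI's drift pattern (the weakest, age effect).
#' @param rho correlation between the drift patterns of fROIs sharing a
#'   cytoarchitectonic area (development is parallel within an area).
#' @param c0 reference log10(age in days) at which planted profiles equal
#'   their base value (about the cohort's log-age centre).
#' @param sigma_noise lognormal sd of per-(session, fROI, parcel) density
#'   noise.
#' @param p_evc fraction of a sub-bundle's streamlines reaching early visual
#'   cortex; @param loop_frac fraction looping back to the seed parcel.
#' @param band_props 3x3 matrix (cytoarchitecture x band) of eccentricity-band
#'   proportions; rows sum to 1.
#' @param band_offsets per-fROI-name additive offset on the central-band
#'   proportion; @param band_slopes per-fROI-name central-band change per
#'   log10(day), as fractions.
#' @param band_subject_sd,band_session_sd subject and residual sd of the
#'   central-band proportion (fractions).
#' @param jitter_mm uniform endpoint jitter half-width.
#' @return settings list for [make_labeled_mesh()].
#' @export
mesh_config <- function(n_parcels = 180, n_excluded = 11,
                        hemispheres = c("lh", "rh"), spacing_mm = 4,
                        with_frois = TRUE, with_bands = TRUE,
                        n_hub = 25, hub_weight = 8,
                        n_cat_parcels = 10, cat_tilt = 1.5,
                        amp = 0.12, rho = 0.9, c0 = 2.7,
                        sigma_noise = 0.25, p_evc = 0.18, loop_frac = 0.05,
                        band_props = rbind(FG2 = c(0.636, 0.098, 0.266),
                                           FG3 = c(0.266, 0.334, 0.400),
                                           FG4 = c(0.440, 0.240, 0.320)),
                        band_offsets = c("pFus-faces" = 0.05,
                                         "pOTS-words" = -0.05),
                        band_slopes = c("mFus-faces" = -0.0275,
                                        "OTS-bodies" = -0.0275,
                                        "mOTS-words" = -0.0275,
                                        "pOTS-words" = 0.0395),
                        band_subject_sd = 0.03, band_session_sd = 0.05,
                        jitter_mm = 0.75) {
  stopifnot(n_parcels >= 1, n_excluded >= 0, n_excluded < n_parcels,
            all(abs(rowSums(band_props) - 1) < 1e-12))
  colnames(band_props) <- c("0-5", "5-10", "10-20")
  as.list(environment())
}

# vertex/parcel layout of one hemisphere grid
.hemi_grid <- function(cfg, x_offset) {
  np <- cfg$n_parcels
  ncol_p <- if (np == 180) 15L else max(1L, ceiling(sqrt(np)))
  nrow_p <- ceiling(np / ncol_p)
  nvc <- 2L * ncol_p; nvr <- 2L * nrow_p
  g <- expand.grid(col = seq_len(nvc), row = seq_len(nvr))
  verts <- cbind(x = (g$col - 1) * cfg$spacing_mm + x_offset,
                 y = (g$row - 1) * cfg$spacing_mm, z = 0)
  parcel_idx <- pmin(((g$row - 1L) %/% 2L) * ncol_p + ((g$col - 1L) %/% 2L) + 1L,
                     np)
  faces <- NULL
  fl <- vector("list", nvr - 1L)
  for (r in seq_len(nvr - 1L)) {
    base <- (r - 1L) * nvc + seq_len(nvc - 1L)
    fl[[r]] <- rbind(cbind(base, base + 1L, base + nvc),
                     cbind(base + 1L, base + nvc + 1L, base + nvc))
  }
  faces <- do.call(rbind, fl)
  list(vertices = verts, faces = faces, parcel_idx = parcel_idx)
}

#' Build the synthetic labeled mesh and its ground truth
#'
#' @param config from [mesh_config()].
#' @param seed RNG seed for the planted-structure draws.
#' @return list with `mesh` (a [labeled_mesh()]) and `truth` (class
#'   `vtcwm_truth`; see Details).
#' @details The truth object carries: `mean_profile` (per
#'   cytoarchitecture-category pair, a probability vector over retained
#'   parcels summing to 1), `age_slope` (fROI x retained-parcel density change
#'   per log10 day), `band_props`, per-fROI band offsets/slopes,
#'   `effect_scales` (ordered cytoarchitecture > category > age), and the
#'   generator parameters.
#' @export
make_labeled_mesh <- function(config = mesh_config(), seed = 1) {
  cfg <- config
  hemis <- cfg$hemispheres
  parcel_names <- sprintf("P%03d", seq_len(cfg$n_parcels))
  excluded_parcels <- parcel_names[seq_len(cfg$n_excluded)]
  frois <- if (cfg$with_frois) froi_metadata(hemis) else froi_metadata(hemis)[0, ]
  if (cfg$with_frois && cfg$n_excluded < 6) {
    stop("need at least 6 excluded parcels to house the fROIs")
  }
  band_parcels <- character(0)
  if (cfg$with_bands) {
    if (cfg$n_parcels < cfg$n_excluded + 3) stop("not enough parcels for EVC bands")
    band_parcels <- parcel_names[cfg$n_excluded + 1:3]
  }
  # fROI -> own (excluded) parcel, by canonical fROI name order
  froi_parcel <- setNames(excluded_parcels[match(frois$name, .vtcwm_froi_table$name)],
                          frois$froi)

  meshes <- lapply(seq_along(hemis), function(i)
    .hemi_grid(cfg, x_offset = (i - 1) * 200))
  vertices <- do.call(rbind, lapply(meshes, `[[`, "vertices"))
  offs <- cumsum(c(0, vapply(meshes, function(m) nrow(m$vertices), numeric(1))))
  faces <- do.call(rbind, lapply(seq_along(meshes), function(i)
    meshes[[i]]$faces + offs[i]))
  hemi_lab <- rep(hemis, vapply(meshes, function(m) nrow(m$vertices), numeric(1)))
  parcel_lab <- parcel_names[unlist(lapply(meshes, `[[`, "parcel_idx"))]
  labels <- data.frame(parcel = parcel_lab, hemisphere = hemi_lab,
                       excluded = parcel_lab %in% excluded_parcels,
                       froi = NA_character_,
                       eccentricity_band = NA_integer_,
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(frois))) {
    ix <- labels$parcel == froi_parcel[frois$froi[i]] &
      labels$hemisphere == frois$hemisphere[i]
    if (any(!is.na(labels$froi[ix]))) stop("overlapping fROI vertex sets")
    labels$froi[ix] <- frois$froi[i]
  }
  for (b in seq_along(band_parcels)) {
    labels$eccentricity_band[labels$parcel == band_parcels[b]] <- b
  }
  normals <- matrix(rep(c(0, 0, 1), each = nrow(vertices)), ncol = 3)
  mesh <- labeled_mesh(vertices, faces, normals, labels)

  truth <- .make_ground_truth(cfg, seed, parcel_names, excluded_parcels,
                              band_parcels, frois, froi_parcel)
  list(mesh = mesh, truth = truth)
}

.make_ground_truth <- function(cfg, seed, parcel_names, excluded_parcels,
                               band_parcels, frois, froi_parcel) {
  retained <- setdiff(parcel_names, excluded_parcels)
  nonevc <- setdiff(retained, band_parcels)
  cytos <- .vtcwm_cytos
  cats <- .vtcwm_categories
  .with_seed(seed, {
    # hub parcels per cytoarchitectonic area: disjoint draws
    pool <- sample(nonevc)
    n_hub <- min(cfg$n_hub, floor(length(nonevc) / 3))
    hubs <- split(pool[seq_len(3 * n_hub)], rep(cytos, each = n_hub))
    # category tilt parcels (drawn over all non-EVC parcels, may overlap hubs)
    cat_parcels <- lapply(setNames(cats, cats), function(ct)
      sample(nonevc, min(cfg$n_cat_parcels, length(nonevc))))
    base_profiles <- list()
    for (cy in cytos) {
      w0 <- setNames(rep(1, length(nonevc)), nonevc)
      w0[hubs[[cy]]] <- cfg$hub_weight
      for (ct in cats) {
        w <- w0
        w[cat_parcels[[ct]]] <- w[cat_parcels[[ct]]] * cfg$cat_tilt
        base_profiles[[paste(cy, ct, sep = "|")]] <- w / sum(w)
      }
    }
    # age drift patterns: shared per cytoarchitecture, perturbed per fROI,
    # weighted-centred so each profile's total mass is conserved exactly
    centre <- function(s, w) s - sum(w * s) / sum(w)
    s_cyto <- lapply(setNames(cytos, cytos), function(cy) rnorm(length(nonevc)))
    s_pattern <- NULL
    if (nrow(frois) > 0) {
      s_pattern <- t(vapply(seq_len(nrow(frois)), function(i) {
        cy <- frois$cytoarchitecture[i]
        ct <- frois$category[i]
        s <- cfg$rho * s_cyto[[cy]] + sqrt(1 - cfg$rho^2) * rnorm(length(nonevc))
        centre(s, base_profiles[[paste(cy, ct, sep = "|")]])
      }, numeric(length(nonevc))))
      dimnames(s_pattern) <- list(frois$froi, nonevc)
    }
  })
  rownames(cfg$band_props) <- cytos
  colnames(cfg$band_props) <- c("0-5", "5-10", "10-20")
  # spec'd mean_profile: probability over retained parcels, summing to 1
  mean_profile <- list()
  for (key in names(base_profiles)) {
    cy <- sub("\\|.*", "", key)
    v <- setNames(numeric(length(retained)), retained)
    v[nonevc] <- (1 - cfg$p_evc) * base_profiles[[key]]
    if (length(band_parcels) == 3) {
      v[band_parcels] <- cfg$p_evc * cfg$band_props[cy, ]
    } else {
      v[nonevc] <- v[nonevc] / (1 - cfg$p_evc)
    }
    mean_profile[[key]] <- v
  }
  # planted density slope per (fROI, retained parcel), in density/log10(day),
  # on the scale of the measured (unrenormalized) profile: both terminal
  # points of every streamline enter the density map, and only the non-seed
  # endpoint lands in retained parcels, hence the factor 1/2
  age_slope <- NULL
  if (nrow(frois) > 0) {
    age_slope <- matrix(0, nrow(frois), length(retained),
                        dimnames = list(frois$froi, retained))
    half <- 0.5 * (1 - cfg$loop_frac)
    for (i in seq_len(nrow(frois))) {
      key <- paste(frois$cytoarchitecture[i], frois$category[i], sep = "|")
      evc_share <- if (length(band_parcels) == 3) cfg$p_evc else 0
      age_slope[i, nonevc] <- half * (1 - evc_share) *
        base_profiles[[key]] * cfg$amp * s_pattern[i, ]
      if (length(band_parcels) == 3) {
        bs <- cfg$band_slopes[frois$name[i]]
        if (!is.na(bs) && bs != 0) {
          # central band gains bs; the remainder is lost by bands 2 and 3 in
          # their base ratio
          cy <- frois$cytoarchitecture[i]
          ratio <- cfg$band_props[cy, 2:3] / sum(cfg$band_props[cy, 2:3])
          age_slope[i, band_parcels[1]] <- half * cfg$p_evc * bs
          age_slope[i, band_parcels[2:3]] <- -half * cfg$p_evc * bs * ratio
        }
      }
    }
  }
  structure(list(
    parcel_names = parcel_names, retained_parcels = retained,
    nonevc_parcels = nonevc, band_parcels = band_parcels,
    excluded_parcels = excluded_parcels,
    frois = frois, froi_parcel = froi_parcel,
    base_profiles = base_profiles, s_pattern = s_pattern,
    mean_profile = mean_profile, age_slope = age_slope,
    band_props = cfg$band_props,
    band_offsets = cfg$band_offsets, band_slopes = cfg$band_slopes,
    effect_scales = c(cytoarchitecture = cfg$hub_weight - 1,
                      category = cfg$cat_tilt - 1, age = cfg$amp),
    params = cfg[c("amp", "rho", "c0", "sigma_noise", "p_evc", "loop_frac",
                   "band_subject_sd", "band_session_sd", "jitter_mm",
                   "spacing_mm")],
    seed = seed
  ), class = "vtcwm_truth")
}

#' @exportS3Method
print.vtcwm_truth <- function(x, ...) {
  cat("vtcwm_truth:", length(x$retained_parcels), "retained parcels,",
      nrow(x$frois), "fROIs,", length(x$band_parcels), "EVC band parcels\n")
  invisible(x)
}

#' Planted between-group profile separation
#'
#' Mean pairwise Euclidean distance between group-mean profiles when grouping
#' the planted generator means by cytoarchitecture, by category, and by age
#' group (profiles displaced along the planted drift to each group's typical
#' log-age). With default settings the ordering is
#' cytoarchitecture > category > age.
#'
#' @param truth a `vtcwm_truth`.
#' @param group_log_ages typical log10(age in days) per age group.
#' @return named numeric: mean distances for cytoarchitecture, category, age.
#' @export
planted_separation <- function(truth,
                               group_log_ages = c(newborn = log10(28.6),
                                                  "3mo" = log10(106.9),
                                                  "6mo" = log10(189),
                                                  adult = log10(28.21 * 365.25))) {
  frois <- truth$frois
  key <- paste(frois$cytoarchitecture, frois$category, sep = "|")
  prof <- t(vapply(key, function(k) truth$mean_profile[[k]],
                   numeric(length(truth$retained_parcels))))
  mean_dist <- function(groups) {
    g <- unique(groups)
    centroids <- t(vapply(g, function(x)
      colMeans(prof[groups == x, , drop = FALSE]), numeric(ncol(prof))))
    d <- as.matrix(dist(centroids))
    mean(d[upper.tri(d)])
  }
  cyto_d <- mean_dist(frois$cytoarchitecture)
  cat_d <- mean_dist(frois$category)
  # age: cohort-average profile displaced along the planted slopes (rescaled
  # from measured-density units back to the target-distribution simplex)
  c0 <- truth$params$c0
  scale <- 0.5 * (1 - truth$params$loop_frac)
  age_prof <- t(vapply(group_log_ages, function(la)
    colMeans(prof + truth$age_slope / scale * (la - c0)),
    numeric(ncol(prof))))
  dd <- as.matrix(dist(age_prof))
  c(cytoarchitecture = cyto_d, category = cat_d, age = mean(dd[upper.tri(dd)]))
}
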