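# Streamline sampler: one synthetic tractogram per session, with endpoint
# distributions drawn from the session-adjusted ground truth.

# internal: wrap a pre-validated streamline list without re-checking
.tractogram_unsafe <- function(streamlines) {
  structure(list(streamlines = streamlines, count = length(streamlines)),
            class = "tractogram")
}

# per-session eccentricity-band triple for one fROI (fractions, sum 1)
.session_band_triple <- function(truth, froi_row, la, subj_re, sess_noise) {
  cy <- froi_row$cytoarchitecture
  base <- truth$band_props[cy, ]
  off <- truth$band_offsets[froi_row$name]
  slp <- truth$band_slopes[froi_row$name]
  central <- base[1] + (if (is.na(off)) 0 else off) +
    (if (is.na(slp)) 0 else slp) * (la - truth$params$c0) + subj_re + sess_noise
  central <- min(max(central, 0.01), 0.97)
  ratio <- base[2:3] / sum(base[2:3])
  c(central, (1 - central) * ratio)
}

#' Sample a synthetic whole-session tractogram
#'
#' For every fROI on the mesh, draws `n_streamlines_per_froi` streamlines: the
#' seed endpoint is placed uniformly over the fROI's vertices (with spatial
#' jitter), the other endpoint lands in a parcel drawn from the
#' session-adjusted multinomial (planted mean profile plus age drift,
#' per-session lognormal density noise, clipped to the simplex and
#' renormalized). A `loop_frac` share loops back to the seed parcel and a
#' `p_evc` share reaches the eccentricity-band parcels with per-session band
#' proportions (subject random effect + residual noise on the central band).
#' Streamlines are jittered 3-point polylines; only endpoints carry signal.
#'
#' @param mesh a `labeled_mesh` from [make_labeled_mesh()].
#' @param truth the matching `vtcwm_truth`.
#' @param session one row of a [make_cohort()] table.
#' @param n_streamlines_per_froi streamlines per fROI (default 2000).
#' @param seed RNG seed for this call; the subject random effect is derived
#'   from `subject_id` and the truth seed, so it is stable across sessions of
#'   one subject.
#' @return a `tractogram` (fROI blocks in canonical order).
#' @export
sample_tractogram <- function(mesh, truth, session,
                              n_streamlines_per_froi = 2000, seed = 1) {
  stopifnot(inherits(mesh, "labeled_mesh"), inherits(truth, "vtcwm_truth"),
            n_streamlines_per_froi >= 1)
  n <- n_streamlines_per_froi
  frois <- truth$frois
  if (nrow(frois) == 0) stop("truth carries no fROIs to seed from")
  la <- log10(session$age_days)
  p <- truth$params
  has_bands <- length(truth$band_parcels) == 3
  # vertex index lists per (hemisphere, parcel)
  vert_key <- paste(mesh$labels$hemisphere, mesh$labels$parcel)
  parcel_verts <- split(seq_len(mesh$n_vertices), vert_key)
  subj_re <- if (has_bands && p$band_subject_sd > 0) {
    .with_seed(.string_seed(session$subject_id, truth$seed),
               rnorm(1, 0, p$band_subject_sd))
  } else 0
  .with_seed(seed, {
    out <- vector("list", nrow(frois))
    for (i in seq_len(nrow(frois))) {
      fr <- frois[i, ]
      key <- paste(fr$cytoarchitecture, fr$category, sep = "|")
      base <- truth$base_profiles[[key]]
      drift <- if (!is.null(truth$s_pattern)) truth$s_pattern[fr$froi, ] else 0
      w <- base * (1 + p$amp * drift * (la - p$c0))
      w <- pmax(w, 0)
      if (p$sigma_noise > 0) w <- w * rlnorm(length(w), 0, p$sigma_noise)
      if (sum(w) <= 0) stop("adjusted probability vector has no mass for ",
                            fr$froi)
      w <- w / sum(w)
      evc_share <- if (has_bands) p$p_evc else 0
      slots <- c(truth$froi_parcel[[fr$froi]], truth$band_parcels,
                 truth$nonevc_parcels)
      probs <- c(p$loop_frac,
                 if (has_bands) {
                   (1 - p$loop_frac) * evc_share *
                     .session_band_triple(truth, fr, la, subj_re,
                                          rnorm(1, 0, p$band_session_sd))
                 },
                 (1 - p$loop_frac) * (1 - evc_share) * w)
      counts <- as.integer(rmultinom(1, n, probs))
      # endpoints: seed side uniform over fROI vertices, target side uniform
      # over the target parcel's same-hemisphere vertices
      seed_verts <- froi_vertices(mesh, fr$froi)
      e1_ix <- seed_verts[sample.int(length(seed_verts), n, replace = TRUE)]
      e2_ix <- integer(n)
      pos <- 1L
      for (s in which(counts > 0L)) {
        vs <- parcel_verts[[paste(fr$hemisphere, slots[s])]]
        k <- counts[s]
        e2_ix[pos:(pos + k - 1L)] <- vs[sample.int(length(vs), k, replace = TRUE)]
        pos <- pos + k
      }
      j <- p$jitter_mm
      e1 <- mesh$vertices[e1_ix, , drop = FALSE] +
        cbind(runif(n, -j, j), runif(n, -j, j), 0)
      e2 <- mesh$vertices[e2_ix, , drop = FALSE] +
        cbind(runif(n, -j, j), runif(n, -j, j), 0)
      mid <- (e1 + e2) / 2 + cbind(runif(n, -j, j), runif(n, -j, j),
                                   runif(n, 5, 15))
      dimnames(e1) <- dimnames(e2) <- dimnames(mid) <- NULL
      out[[i]] <- lapply(seq_len(n), function(k)
        rbind(e1[k, ], mid[k, ], e2[k, ]))
    }
  })
  .tractogram_unsafe(do.call(c, out))
}
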