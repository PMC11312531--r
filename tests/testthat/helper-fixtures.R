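# Shared fixtures, built in code.

# a tiny labeled mesh: one hemisphere grid, small parcel count
tiny_mesh <- function(n_parcels = 12, n_excluded = 0, with_frois = FALSE,
                      with_bands = FALSE, seed = 42) {
  make_labeled_mesh(mesh_config(n_parcels = n_parcels, n_excluded = n_excluded,
                                hemispheres = "lh", with_frois = with_frois,
                                with_bands = with_bands),
                    seed = seed)
}

# hand-built 4-vertex square mesh with two triangles (unit normals +z)
square_mesh <- function(parcels = c("A", "A", "B", "B"),
                        excluded = c(FALSE, FALSE, FALSE, FALSE)) {
  labeled_mesh(
    vertices = rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(10, 10, 0)),
    faces = rbind(c(1, 2, 3), c(2, 4, 3)),
    normals = matrix(rep(c(0, 0, 1), each = 4), ncol = 3),
    labels = data.frame(parcel = parcels, hemisphere = "lh",
                        excluded = excluded, froi = NA_character_,
                        eccentricity_band = NA_integer_,
                        stringsAsFactors = FALSE))
}

# straight 3-point streamline between two endpoints
sline <- function(a, b) rbind(a, (a + b) / 2 + c(0, 0, 5), b)

# small full-featured cohort for pipeline-level tests (fast)
small_config <- function(seed = 7, n_streamlines = 300) {
  run_config(
    seed = seed,
    n_streamlines_per_froi = n_streamlines,
    n_iter = 25,
    cohort = cohort_config(counts = c(newborn = 5, "3mo" = 5, "6mo" = 4,
                                      adult = 4)))
}

# memoised expensive fixtures (shared across acceptance test blocks)
.fixture_env <- new.env(parent = emptyenv())
fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}
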