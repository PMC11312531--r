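# Labeled triangle mesh: the anatomical coordinate frame. Vertices/faces/
# normals plus named per-vertex categorical label maps (parcel, hemisphere,
# froi, cytoarchitecture, eccentricity band, excluded flag).

#' Construct a labeled mesh
#'
#' @param vertices `n x 3` numeric matrix, mm coordinates.
#' @param faces `m x 3` integer matrix of 1-based vertex indices.
#' @param normals `n x 3` matrix of unit per-vertex normals.
#' @param labels data.frame with `n` rows of per-vertex labels; must contain a
#'   `parcel` column covering all vertices; conventional columns are
#'   `hemisphere`, `froi`, `eccentricity_band` (`NA` where unlabeled) and the
#'   logical `excluded` seed-region flag on parcels.
#' @return object of class `labeled_mesh`.
#' @export
labeled_mesh <- function(vertices, faces, normals, labels) {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  faces <- as.matrix(faces); storage.mode(faces) <- "integer"
  normals <- as.matrix(normals); storage.mode(normals) <- "double"
  dimnames(vertices) <- dimnames(faces) <- dimnames(normals) <- NULL
  n <- nrow(vertices)
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3, ncol(normals) == 3,
            nrow(normals) == n, is.data.frame(labels), nrow(labels) == n)
  if (nrow(faces) > 0 && (min(faces) < 1 || max(faces) > n)) {
    stop("face vertex indices out of range")
  }
  nrm <- sqrt(rowSums(normals^2))
  if (any(abs(nrm - 1) > 1e-6)) stop("normals must be unit length")
  if (!"parcel" %in% names(labels) || anyNA(labels$parcel)) {
    stop("labels must contain a complete 'parcel' column")
  }
  structure(list(vertices = vertices, faces = faces, normals = normals,
                 labels = labels, n_vertices = n),
            class = "labeled_mesh")
}

#' @exportS3Method
print.labeled_mesh <- function(x, ...) {
  cat("labeled_mesh:", x$n_vertices, "vertices,", nrow(x$faces), "faces;",
      length(unique(x$labels$parcel)), "parcels\n")
  invisible(x)
}

#' Project ROI vertices along their surface normals
#'
#' Displaces the given vertices by `offset_mm` along the per-vertex normal;
#' with `offset_mm = 0` this is the identity (a mesh that already sits on the
#' gray/white interface needs no displacement).
#'
#' @param mesh a `labeled_mesh`.
#' @param roi_vertices integer vertex indices (1-based).
#' @param offset_mm displacement in mm (signed).
#' @return `length(roi_vertices) x 3` matrix of projected points.
#' @export
project_roi <- function(mesh, roi_vertices, offset_mm = 0) {
  stopifnot(inherits(mesh, "labeled_mesh"))
  roi_vertices <- as.integer(roi_vertices)
  if (length(roi_vertices) == 0) stop("empty ROI vertex set")
  if (min(roi_vertices) < 1 || max(roi_vertices) > mesh$n_vertices) {
    stop("ROI vertex index out of range")
  }
  mesh$vertices[roi_vertices, , drop = FALSE] +
    offset_mm * mesh$normals[roi_vertices, , drop = FALSE]
}

#' Per-vertex surface areas (barycentric convention)
#'
#' Each triangle contributes one third of its area to each of its vertices.
#'
#' @param mesh a `labeled_mesh`.
#' @return numeric vector of per-vertex areas in mm^2.
#' @export
vertex_areas <- function(mesh) {
  stopifnot(inherits(mesh, "labeled_mesh"))
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  tri_area <- 0.5 * sqrt(rowSums(cr^2))
  out <- numeric(mesh$n_vertices)
  for (k in 1:3) {
    contrib <- tapply(tri_area / 3, f[, k], sum)
    ix <- as.integer(names(contrib))
    out[ix] <- out[ix] + as.numeric(contrib)
  }
  out
}

#' Vertex indices of an fROI
#' @param mesh a `labeled_mesh`; @param froi fROI id (e.g. `"lh.CoS-places"`).
#' @return integer vertex indices.
#' @export
froi_vertices <- function(mesh, froi) {
  ix <- which(!is.na(mesh$labels$froi) & mesh$labels$froi == froi)
  if (length(ix) == 0) stop("fROI not present on mesh: ", froi)
  ix
}

#' Write / read a labeled mesh as ASCII PLY plus TSV label table
#'
#' Geometry (vertices, normals, faces) goes to an ASCII PLY file; the label
#' data.frame goes to `<path>.labels.tsv` with a leading `vertex_index`
#' column.
#'
#' @param mesh a `labeled_mesh`; @param path output `.ply` path.
#' @return `path`, invisibly.
#' @export
write_mesh_ply <- function(mesh, path) {
  stopifnot(inherits(mesh, "labeled_mesh"))
  n <- mesh$n_vertices; m <- nrow(mesh$faces)
  header <- c(
    "ply", "format ascii 1.0", paste("element vertex", n),
    "property float x", "property float y", "property float z",
    "property float nx", "property float ny", "property float nz",
    paste("element face", m), "property list uchar int vertex_indices",
    "end_header")
  vl <- apply(cbind(mesh$vertices, mesh$normals), 1, paste, collapse = " ")
  fl <- apply(cbind(3L, mesh$faces - 1L), 1, paste, collapse = " ")
  writeLines(c(header, vl, fl), path)
  lab <- cbind(vertex_index = seq_len(n), mesh$labels)
  write.table(lab, paste0(path, ".labels.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_mesh_ply
#' @export
read_mesh_ply <- function(path) {
  lines <- readLines(path)
  if (!identical(lines[1], "ply")) stop("not a PLY file: ", path)
  hdr_end <- which(lines == "end_header")[1]
  if (is.na(hdr_end)) stop("malformed PLY: no end_header")
  hdr <- lines[seq_len(hdr_end)]
  n <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr, value = TRUE)))
  m <- as.integer(sub("element face ", "", grep("^element face", hdr, value = TRUE)))
  vl <- lines[hdr_end + seq_len(n)]
  vm <- matrix(as.numeric(unlist(strsplit(vl, " "))), ncol = 6, byrow = TRUE)
  fl <- lines[hdr_end + n + seq_len(m)]
  fm <- matrix(as.integer(unlist(strsplit(fl, " "))), ncol = 4, byrow = TRUE)
  lab <- read.delim(paste0(path, ".labels.tsv"), stringsAsFactors = FALSE)
  lab$vertex_index <- NULL
  if ("excluded" %in% names(lab)) lab$excluded <- as.logical(lab$excluded)
  labeled_mesh(vm[, 1:3], fm[, 2:4] + 1L, vm[, 4:6], lab)
}
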