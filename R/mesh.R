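# Triangle-mesh helpers. A mesh is list(vertices = n x 3 numeric matrix,
# faces = m x 3 integer matrix of 1-based vertex indices). Units: meters.

new_mesh <- function(vertices, faces) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (!all(is.finite(vertices))) stop("mesh vertices must be finite")
  if (nrow(faces) && (min(faces) < 1 || max(faces) > nrow(vertices))) {
    stop("face indices out of range")
  }
  list(vertices = vertices, faces = faces)
}

#' Total surface area of a triangle mesh
#'
#' @param mesh A mesh (list with `vertices` and `faces`).
#' @return Summed triangle area in the mesh's squared length unit.
#' @export
mesh_area <- function(mesh) {
  if (!nrow(mesh$faces)) return(0)
  v <- mesh$vertices
  a <- v[mesh$faces[, 1], , drop = FALSE]
  b <- v[mesh$faces[, 2], , drop = FALSE]
  c_ <- v[mesh$faces[, 3], , drop = FALSE]
  e1 <- b - a
  e2 <- c_ - a
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  v <- mesh$vertices %*% t(rotation)
  v <- sweep(v, 2, translation, "+")
  new_mesh(v, mesh$faces)
}

scale_mesh <- function(mesh, sx = 1, sy = 1, sz = 1) {
  v <- mesh$vertices
  v[, 1] <- v[, 1] * sx; v[, 2] <- v[, 2] * sy; v[, 3] <- v[, 3] * sz
  new_mesh(v, mesh$faces)
}

# Rotation matrices (right-handed, z-up), angles in degrees.
rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}
rot_y <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)), 3, 3,
         byrow = TRUE)
}

#' Write a scene or plant to a Wavefront OBJ file
#'
#' Emits one named group per surface (`leaf_<plant>_<stem>_<node>_<k>` and
#' `stem_<plant>_<id>`), plain `v`/`f` records, ASCII. The matching reader is
#' [read_scene_obj()]; a write/read round trip preserves vertex and triangle
#' counts and areas.
#'
#' @param scene A `canopy_scene` or `plant_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scene_obj <- function(scene, path) {
  flat <- flatten_scene(scene)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# canopyray scene export", con)
  offset <- 0L
  for (i in seq_along(flat$meshes)) {
    m <- flat$meshes[[i]]
    writeLines(paste0("g ", flat$surfaces$name[i]), con)
    writeLines(sprintf("v %.9g %.9g %.9g",
                       m$vertices[, 1], m$vertices[, 2], m$vertices[, 3]),
               con)
    writeLines(sprintf("f %d %d %d",
                       m$faces[, 1] + offset, m$faces[, 2] + offset,
                       m$faces[, 3] + offset), con)
    offset <- offset + nrow(m$vertices)
  }
  invisible(path)
}

#' Read a scene OBJ written by [write_scene_obj()]
#'
#' @param path OBJ file path.
#' @return A list with `meshes` (one per group) and `surfaces` (a data frame
#'   with the group names and areas), mirroring the flattened scene layout.
#' @export
read_scene_obj <- function(path) {
  lines <- readLines(path)
  type <- substr(lines, 1, 2)
  verts <- do.call(rbind, lapply(strsplit(lines[type == "v "], "\\s+"),
                                 function(x) as.numeric(x[2:4])))
  face_idx <- which(type == "f ")
  group_idx <- which(substr(lines, 1, 2) == "g ")
  group_of_face <- findInterval(face_idx, group_idx)
  fmat <- do.call(rbind, lapply(strsplit(lines[face_idx], "\\s+"),
                                function(x) as.integer(x[2:4])))
  meshes <- list()
  names_out <- character(0)
  for (g in seq_along(group_idx)) {
    rows <- fmat[group_of_face == g, , drop = FALSE]
    if (!nrow(rows)) next
    vids <- sort(unique(as.vector(rows)))
    remap <- match(as.vector(rows), vids)
    meshes[[length(meshes) + 1L]] <-
      new_mesh(verts[vids, , drop = FALSE],
               matrix(remap, ncol = 3))
    names_out <- c(names_out, sub("^g ", "", lines[group_idx[g]]))
  }
  areas <- vapply(meshes, mesh_area, numeric(1))
  list(meshes = meshes,
       surfaces = data.frame(name = names_out, area_m2 = areas,
                             stringsAsFactors = FALSE))
}
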