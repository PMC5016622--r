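# Parametric reconstruction of a two-stem, V-trellised sweet pepper plant.
# Internal units are meters; the structural table is in cm/mm and converted
# at this boundary. Coordinates: right-handed, z up, ground at z = 0, rows
# along x.

#' Unit-area leaf blade template
#'
#' A flat, ovate-cordate polygon fan (24 triangles) lying in the z = 0 plane,
#' midrib along +x, petiole attachment at the origin, normalised to unit
#' planform area and unit length/width. Interception at canopy scale depends
#' mainly on area and angle, so the outline is a fixed smooth template scaled
#' anisotropically to each leaf's target area.
#'
#' @param n_side Outline points per blade side.
#' @return A mesh (see [mesh_area()]) with unit area.
#' @export
leaf_template <- function(n_side = 11) {
  t_up <- seq(0, 1, length.out = n_side + 2)[2:(n_side + 1)]
  half_width <- function(t) 0.5 * sin(pi * t^0.7)
  outline <- rbind(
    c(0, 0),
    cbind(t_up, half_width(t_up)),
    c(1, 0),
    cbind(rev(t_up), -half_width(rev(t_up)))
  )
  centroid <- colMeans(outline)
  n <- nrow(outline)
  verts <- cbind(rbind(outline, centroid), 0)
  faces <- cbind(seq_len(n), c(seq_len(n)[-1], 1L), n + 1L)
  m <- new_mesh(verts, faces)
  a0 <- mesh_area(m)
  scale_mesh(m, 1 / sqrt(a0), 1 / sqrt(a0), 1)
}

# Leaves borne per node on one stem: an odd structural layer k spans nodes
# {k, k+1} on both stems, so its n_leaves count divides by 4; the terminal
# node 15 carries its whole layer count on a single node pair (n/2 per stem).
leaves_per_node <- function(node, n_leaves, top_node = 15) {
  ifelse(node == top_node,
         pmax(1, round(n_leaves / 2)),
         pmax(1, round(n_leaves / 4)))
}

# Hexagonal prism between two points, used for stem internodes.
prism_mesh <- function(p0, p1, radius, n_sides = 6) {
  axis <- p1 - p0
  len <- sqrt(sum(axis^2))
  axis <- axis / len
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- ref - sum(ref * axis) * axis
  u <- u / sqrt(sum(u^2))
  w <- c(axis[2] * u[3] - axis[3] * u[2],
         axis[3] * u[1] - axis[1] * u[3],
         axis[1] * u[2] - axis[2] * u[1])
  ang <- 2 * pi * (seq_len(n_sides) - 1) / n_sides
  ring0 <- t(vapply(ang, function(a)
    p0 + radius * (cos(a) * u + sin(a) * w), numeric(3)))
  ring1 <- t(vapply(ang, function(a)
    p1 + radius * (cos(a) * u + sin(a) * w), numeric(3)))
  verts <- rbind(ring0, ring1)
  i <- seq_len(n_sides)
  j <- c(i[-1], 1L)
  faces <- rbind(cbind(i, j, i + n_sides),
                 cbind(j, j + n_sides, i + n_sides))
  new_mesh(verts, faces)
}

#' Build the 3D plant model from a structural specification
#'
#' Constructs a two-stem plant, 15 nodes per stem, from a per-layer
#' structural table: internode lengths stack each stem along an axis
#' inclined `stem_incline_deg` off vertical in the row plane (the "V"
#' trellis), each node bears leaves whose blade is scaled to the tabulated
#' area (within 1 percent), displaced by the petiole length and pitched
#' below horizontal by the droop angle. Leaf azimuths alternate by 180
#' degrees per node with a small seeded jitter.
#'
#' @param spec A `layer_spec` table (see [read_layer_spec()]), tabulated at
#'   odd nodes; expanded internally with [expand_layer_spec()].
#' @param seed Integer seed for the azimuth jitter; the build is
#'   deterministic for a fixed seed.
#' @param azimuth_jitter_deg Standard deviation of the azimuth jitter.
#' @param aspect Blade length-to-width ratio.
#' @param stem_incline_deg Stem inclination from vertical, one stem each way.
#' @param n_nodes Nodes per stem.
#' @return A `plant_model`: list with `stems` (2 meshes), `leaves` (list of
#'   per-leaf records with `mesh`, `area_m2`, `stem`, `node`, `azimuth`,
#'   `droop`), `spec` (expanded), `origin`, `height`.
#' @export
#' @examples
#' plant <- build_plant(read_layer_spec(), seed = 1)
#' plant
build_plant <- function(spec, seed = 1L, azimuth_jitter_deg = 10,
                        aspect = 1.5, stem_incline_deg = 30,
                        n_nodes = 15L) {
  nodes <- expand_layer_spec(spec, nodes = seq_len(n_nodes))
  if (any(nodes$leaf_area_cm2 <= 0)) stop("leaf areas must be positive")
  template <- leaf_template()
  n_per_node <- leaves_per_node(nodes$node, nodes$n_leaves, top_node = n_nodes)
  n_jit <- 2L * sum(n_per_node)
  jit <- rng_stream(seed, n_jit) # uniform (0,1), independent of R's RNG state
  jitters <- (jit - 0.5) * 2 * azimuth_jitter_deg
  ji <- 0L

  stems <- vector("list", 2)
  leaves <- list()
  leaf_id <- 0L
  top_z <- 0
  for (s in 1:2) {
    sign_s <- if (s == 1) 1 else -1
    incl <- sign_s * stem_incline_deg * pi / 180
    axis <- c(sin(incl), 0, cos(incl))
    node_pos <- t(vapply(seq_len(n_nodes), function(k)
      axis * sum(nodes$internode_cm[seq_len(k)]) / 100, numeric(3)))
    top_z <- max(top_z, node_pos[, 3])
    segs <- lapply(seq_len(n_nodes), function(k) {
      p0 <- if (k == 1) c(0, 0, 0) else node_pos[k - 1, ]
      prism_mesh(p0, node_pos[k, ], nodes$stem_radius_mm[k] / 1000)
    })
    verts <- do.call(rbind, lapply(segs, `[[`, "vertices"))
    offs <- cumsum(c(0L, vapply(segs, function(m) nrow(m$vertices),
                                integer(1))))
    faces <- do.call(rbind, lapply(seq_along(segs), function(k)
      segs[[k]]$faces + offs[k]))
    stems[[s]] <- new_mesh(verts, faces)

    for (k in seq_len(n_nodes)) {
      n_here <- n_per_node[k]
      area_m2 <- nodes$leaf_area_cm2[k] * 1e-4
      sx <- sqrt(area_m2 * aspect)
      sy <- sqrt(area_m2 / aspect)
      blade0 <- scale_mesh(template, sx, sy, 1)
      base_az <- (k %% 2) * 180 + (s - 1) * 90
      for (q in seq_len(n_here)) {
        ji <- ji + 1L
        az <- base_az + (q - 1) * 360 / n_here + jitters[ji]
        droop <- nodes$droop_deg[k]
        rot <- rot_z(az) %*% rot_y(droop)
        pet <- nodes$petiole_cm[k] / 100
        tip <- node_pos[k, ] + pet * c(cos(az * pi / 180),
                                       sin(az * pi / 180), 0)
        mesh <- transform_mesh(blade0, rot, tip)
        leaf_id <- leaf_id + 1L
        leaves[[leaf_id]] <- list(leaf_id = leaf_id, stem = s, node = k,
                                  k = q, mesh = mesh, area_m2 = area_m2,
                                  azimuth = az %% 360, droop = droop)
      }
    }
  }
  structure(list(stems = stems, leaves = leaves, spec = nodes,
                 origin = c(0, 0, 0), height = top_z, seed = seed),
            class = "plant_model")
}

#' @export
print.plant_model <- function(x, ...) {
  areas <- vapply(x$leaves, `[[`, numeric(1), "area_m2")
  cat(sprintf(
    "<plant_model> 2 stems x %d nodes, %d leaves, leaf area %.3f m2, height %.2f m\n",
    max(vapply(x$leaves, `[[`, numeric(1), "node")), length(x$leaves),
    sum(areas), x$height))
  invisible(x)
}

#' Total planform leaf area of a plant (m^2)
#' @param plant A `plant_model`.
#' @export
plant_leaf_area <- function(plant) {
  sum(vapply(plant$leaves, `[[`, numeric(1), "area_m2"))
}

#' Replicate a plant into a rectangular canopy array
#'
#' Places rigid copies of the plant on a rows x cols grid (rows along x)
#' with the given spacing, centred on the origin. For odd x odd arrays the
#' central plant is flagged: light-interception detectors are attached to
#' it while the neighbours act as shading geometry.
#'
#' @param plant A `plant_model`.
#' @param rows,cols Grid dimensions (>= 1).
#' @param spacing_m Plant-to-plant distance in meters.
#' @return A `canopy_scene`.
#' @export
#' @examples
#' scene <- build_canopy(build_plant(read_layer_spec()), 3, 3, 0.8)
build_canopy <- function(plant, rows = 1L, cols = 1L, spacing_m = 0.8) {
  if (rows < 1 || cols < 1) stop("rows and cols must be >= 1")
  origins <- expand.grid(
    x = (seq_len(rows) - (rows + 1) / 2) * spacing_m,
    y = (seq_len(cols) - (cols + 1) / 2) * spacing_m)
  center_id <- if (rows %% 2 == 1 && cols %% 2 == 1) {
    which(abs(origins$x) < 1e-12 & abs(origins$y) < 1e-12)[1]
  } else NA_integer_
  structure(list(plant = plant,
                 origins = cbind(origins$x, origins$y, 0),
                 rows = rows, cols = cols, spacing = spacing_m,
                 center_plant_id = center_id),
            class = "canopy_scene")
}

#' @export
print.canopy_scene <- function(x, ...) {
  cat(sprintf("<canopy_scene> %d x %d plants at %.2f m; center plant %s\n",
              x$rows, x$cols, x$spacing,
              ifelse(is.na(x$center_plant_id), "undefined",
                     x$center_plant_id)))
  invisible(x)
}

# Flatten a plant or scene into per-surface meshes plus a surface table.
flatten_scene <- function(scene) {
  if (inherits(scene, "plant_model")) {
    scene <- build_canopy(scene, 1L, 1L)
  }
  stopifnot(inherits(scene, "canopy_scene"))
  meshes <- list()
  rows <- list()
  plant <- scene$plant
  for (p in seq_len(nrow(scene$origins))) {
    shift <- scene$origins[p, ]
    for (lf in plant$leaves) {
      meshes[[length(meshes) + 1L]] <-
        transform_mesh(lf$mesh, diag(3), shift)
      rows[[length(rows) + 1L]] <- data.frame(
        name = sprintf("leaf_%d_%d_%d_%d", p, lf$stem, lf$node, lf$k),
        kind = "leaf", plant = p, stem = lf$stem, node = lf$node,
        leaf_k = lf$k, leaf_id = lf$leaf_id, area_m2 = lf$area_m2,
        stringsAsFactors = FALSE)
    }
    for (s in 1:2) {
      meshes[[length(meshes) + 1L]] <-
        transform_mesh(plant$stems[[s]], diag(3), shift)
      rows[[length(rows) + 1L]] <- data.frame(
        name = sprintf("stem_%d_%d", p, s), kind = "stem", plant = p,
        stem = s, node = NA_integer_, leaf_k = NA_integer_,
        leaf_id = NA_integer_,
        area_m2 = mesh_area(plant$stems[[s]]), stringsAsFactors = FALSE)
    }
  }
  surfaces <- do.call(rbind, rows)
  surfaces$surface_id <- seq_len(nrow(surfaces))
  list(meshes = meshes, surfaces = surfaces,
       center_plant_id = scene$center_plant_id)
}
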