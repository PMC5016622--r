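#' Sky condition at one time step
#'
#' @param global_ppfd Global PPFD on the horizontal above the canopy
#'   (umol m-2 s-1).
#' @param diffuse_fraction Share of global PPFD arriving from the sky
#'   hemisphere, in \[0, 1\].
#' @param timestamp Optional POSIXct label.
#' @return A `sky_condition` list.
#' @export
sky_condition <- function(global_ppfd, diffuse_fraction, timestamp = NULL) {
  stopifnot(global_ppfd >= 0, diffuse_fraction >= 0, diffuse_fraction <= 1)
  structure(list(global_ppfd = global_ppfd,
                 diffuse_fraction = diffuse_fraction,
                 timestamp = timestamp),
            class = "sky_condition")
}

#' Leaf optical properties
#'
#' Identical on both blade sides; absorptance is `1 - rho - tau`. The
#' defaults are integrating-sphere values for sweet pepper leaves. Stems are
#' modelled as opaque black by default.
#'
#' @param reflectance rho in \[0, 1\].
#' @param transmittance tau, with `rho + tau <= 1`.
#' @param stem_reflectance,stem_transmittance Optics of stem surfaces.
#' @return An `optical_props` list.
#' @export
optical_props <- function(reflectance = 0.1, transmittance = 0.07,
                          stem_reflectance = 0, stem_transmittance = 0) {
  stopifnot(reflectance >= 0, transmittance >= 0,
            reflectance + transmittance <= 1,
            stem_reflectance >= 0, stem_transmittance >= 0,
            stem_reflectance + stem_transmittance <= 1)
  structure(list(reflectance = reflectance, transmittance = transmittance,
                 absorptance = 1 - reflectance - transmittance,
                 stem_reflectance = stem_reflectance,
                 stem_transmittance = stem_transmittance),
            class = "optical_props")
}

#' Monte Carlo budget and seed for a trace
#'
#' The default desk-scale budget of 1e6 rays resolves per-leaf irradiance of
#' a single plant to a few percent; the sampling scheme is unchanged at any
#' budget, so results converge toward the many-giga-ray regime simply by
#' raising `n_rays`.
#'
#' @param n_rays Number of rays (>= 1).
#' @param max_impacts Interactions before a ray is truncated (default 10).
#' @param seed Integer seed for the tracer's own RNG streams.
#' @return A `trace_config` list.
#' @export
trace_config <- function(n_rays = 1e6, max_impacts = 10L, seed = 1L) {
  stopifnot(n_rays >= 1, max_impacts >= 1)
  structure(list(n_rays = n_rays, max_impacts = as.integer(max_impacts),
                 seed = as.integer(seed)),
            class = "trace_config")
}

#' Emitters for one sky/sun state
#'
#' Splits the global horizontal PPFD into a parallel direct beam along the
#' sun vector carrying `(1 - d) * global` per unit horizontal area, and an
#' isotropic diffuse sky carrying `d * global`, both emitted from a
#' horizontal source plane sized at trace time to over-cover the scene.
#' A sun at or below the horizon sends its direct share to zero.
#'
#' @param sky A [sky_condition()].
#' @param sun A [solar_position()] result, or `NULL` for a fully diffuse sky.
#' @return An `emitter_set` list with `beam_flux`, `diffuse_flux`
#'   (umol m-2 s-1 of horizontal plane) and `beam_dir` (unit propagation
#'   vector, NULL if no beam).
#' @export
make_sources <- function(sky, sun = NULL) {
  stopifnot(inherits(sky, "sky_condition"))
  d <- sky$diffuse_fraction
  beam_flux <- (1 - d) * sky$global_ppfd
  if (is.null(sun) || !isTRUE(sun$above_horizon)) beam_flux <- 0
  beam_dir <- NULL
  if (beam_flux > 0) beam_dir <- -sun_vector(sun)
  structure(list(beam_flux = beam_flux,
                 diffuse_flux = d * sky$global_ppfd,
                 beam_dir = beam_dir),
            class = "emitter_set")
}

# Assemble triangles + per-surface optics from a scene-like object.
scene_geometry <- function(scene, optics) {
  flat <- if (is.list(scene) && !is.null(scene$meshes)) scene
          else flatten_scene(scene)
  surfaces <- flat$surfaces
  nsurf <- nrow(surfaces)
  tri_list <- vector("list", nsurf)
  surf_of_tri <- vector("list", nsurf)
  for (i in seq_len(nsurf)) {
    m <- flat$meshes[[i]]
    v <- m$vertices
    tri_list[[i]] <- cbind(v[m$faces[, 1], , drop = FALSE],
                           v[m$faces[, 2], , drop = FALSE],
                           v[m$faces[, 3], , drop = FALSE])
    surf_of_tri[[i]] <- rep.int(i, nrow(m$faces))
  }
  if (is.null(surfaces$rho)) {
    surfaces$rho <- ifelse(surfaces$kind == "leaf", optics$reflectance,
                           optics$stem_reflectance)
    surfaces$tau <- ifelse(surfaces$kind == "leaf", optics$transmittance,
                           optics$stem_transmittance)
  }
  list(tri = do.call(rbind, tri_list),
       surf = unlist(surf_of_tri),
       surfaces = surfaces,
       center_plant_id = flat$center_plant_id)
}

#' Trace a scene and score per-leaf absorbed PPFD
#'
#' Runs the forward Monte Carlo tracer: rays from the source plane, scored
#' absorption at each hit, Lambertian reflection/transmission, termination
#' on escape or after `max_impacts`. Energy bookkeeping
#' (absorbed + escaped + truncated = emitted) holds to floating-point
#' accumulation error, and a fixed seed reproduces the map bit for bit.
#'
#' @param scene A `canopy_scene`, `plant_model`, or a flattened scene list
#'   (`meshes` + `surfaces`, as from [read_scene_obj()] plus a surface
#'   table).
#' @param sources An [make_sources()] emitter set.
#' @param optics An [optical_props()] set.
#' @param config A [trace_config()].
#' @return An `interception_map`: data frame with one row per surface
#'   (`surface_id`, `kind`, `plant`, `stem`, `node`, `leaf_id`, `area_m2`,
#'   `absorbed_umol_s`, `absorbed_umol_m2_s`, `mc_se` on the irradiance),
#'   with attributes `emitted`, `escaped`, `truncated`, `absorbed_total`,
#'   `n_rays`, `n_degenerate`.
#' @export
trace_scene <- function(scene, sources, optics = optical_props(),
                        config = trace_config()) {
  stopifnot(inherits(sources, "emitter_set"))
  geom <- scene_geometry(scene, optics)
  ntri <- if (is.null(geom$tri)) 0L else nrow(geom$tri)

  if (ntri > 0) {
    xr <- range(geom$tri[, c(1, 4, 7)])
    yr <- range(geom$tri[, c(2, 5, 8)])
    zr <- range(geom$tri[, c(3, 6, 9)])
  } else {
    xr <- yr <- c(-0.5, 0.5); zr <- c(0, 1)
  }
  height <- max(zr[2] - zr[1], 0.1)
  plane_z <- zr[2] + 0.25 * height + 0.05
  margin <- max(0.5, 1.5 * height)
  if (!is.null(sources$beam_dir)) {
    d <- sources$beam_dir
    drift <- (plane_z - zr[1]) * sqrt(d[1]^2 + d[2]^2) / abs(d[3])
    margin <- max(margin, drift + 0.25)
  }
  xmin <- xr[1] - margin; xmax <- xr[2] + margin
  ymin <- yr[1] - margin; ymax <- yr[2] + margin
  area_plane <- (xmax - xmin) * (ymax - ymin)

  beam_dir <- if (is.null(sources$beam_dir)) c(0, 0, -1) else sources$beam_dir
  res <- .trace_cpp(
    if (ntri > 0) geom$tri else matrix(numeric(0), 0, 9),
    as.integer(geom$surf),
    geom$surfaces$rho, geom$surfaces$tau,
    beam_dir,
    sources$beam_flux * area_plane,
    sources$diffuse_flux * area_plane,
    plane_z, xmin, xmax, ymin, ymax,
    config$n_rays, config$max_impacts, config$seed)

  out <- geom$surfaces
  out$absorbed_umol_s <- res$absorbed
  out$absorbed_umol_m2_s <- res$absorbed / out$area_m2
  # SE of the total flux Sum(d_i) over n per-ray deposits d_i is
  # sqrt(n * var(d)); expressed per unit leaf area alongside the irradiance
  n <- res$n_rays
  var_flux <- pmax(0, (res$sumsq - res$absorbed^2 / n) * n / max(n - 1, 1))
  out$mc_se <- sqrt(var_flux) / out$area_m2
  structure(out,
            emitted = res$emitted, escaped = res$escaped,
            truncated = res$truncated, absorbed_total = res$absorbed_total,
            n_rays = res$n_rays, n_direct = res$n_direct,
            n_degenerate = res$n_degenerate,
            center_plant_id = geom$center_plant_id,
            class = c("interception_map", "data.frame"))
}

#' Area-weighted mean absorbed irradiance per photosynthesis layer
#'
#' @param map A [trace_scene()] interception map.
#' @param assignment A layer assignment (see [assign_layers()]) mapping the
#'   detector plant's leaves to layers.
#' @param plant_id Which plant's leaves to average; defaults to the scene's
#'   center plant (or plant 1).
#' @return A data frame `layer`, `area_m2`, `absorbed_umol_m2_s`.
#' @export
layer_means <- function(map, assignment, plant_id = NULL) {
  if (is.null(plant_id)) {
    plant_id <- attr(map, "center_plant_id")
    if (is.null(plant_id) || is.na(plant_id)) plant_id <- 1L
  }
  leaves <- map[map$kind == "leaf" & map$plant == plant_id, , drop = FALSE]
  idx <- match(leaves$leaf_id, assignment$leaf_id)
  if (anyNA(idx)) stop("layer assignment does not cover every leaf")
  leaves$layer <- assignment$layer[idx]
  agg <- lapply(split(leaves, leaves$layer), function(g) {
    data.frame(layer = g$layer[1], area_m2 = sum(g$area_m2),
               absorbed_umol_m2_s =
                 sum(g$absorbed_umol_m2_s * g$area_m2) / sum(g$area_m2))
  })
  out <- do.call(rbind, agg)
  out[order(out$layer), , drop = FALSE]
}

#' Beer-Lambert exponential extinction profile
#'
#' Closed-form reference `I(LAI) = I0 exp(-k LAI)` used to check the ray
#' tracer in the turbid-medium limit; not part of the estimation chain.
#'
#' @param i0 Irradiance above the canopy.
#' @param k Extinction coefficient.
#' @param cumulative_lai Downward cumulative leaf area index.
#' @return Irradiance at depth.
#' @export
beer_lambert_profile <- function(i0, k, cumulative_lai) {
  stopifnot(i0 >= 0, k >= 0, all(cumulative_lai >= 0))
  i0 * exp(-k * cumulative_lai)
}
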