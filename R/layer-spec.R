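#' Leaf area from blade length and width
#'
#' Allometric regression for sweet pepper, `LA = 0.6034 L W + 0.0732` with
#' L, W in cm and LA in cm^2.
#'
#' @param length_cm Blade length (cm).
#' @param width_cm Blade width (cm).
#' @return Leaf area (cm^2).
#' @export
#' @examples
#' leaf_area_from_dims(10, 5)
leaf_area_from_dims <- function(length_cm, width_cm) {
  if (any(length_cm < 0) || any(width_cm < 0)) {
    stop("blade length and width must be non-negative")
  }
  0.6034 * length_cm * width_cm + 0.0732
}

#' Read a per-layer structural specification table
#'
#' The CSV must carry the columns `layer, leaf_area_cm2, petiole_cm,
#' droop_deg, n_leaves, stem_radius_mm, internode_cm`. The packaged default
#' transcribes the measured structure of a 3-month-old, two-stem,
#' V-trellised sweet pepper plant, tabulated at the odd node positions
#' 1, 3, ..., 15.
#'
#' @param path CSV path; defaults to the packaged table.
#' @return A data frame of class `layer_spec`.
#' @export
read_layer_spec <- function(path = system.file("extdata",
                                               "layer_structure.csv",
                                               package = "canopyray")) {
  spec <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("layer", "leaf_area_cm2", "petiole_cm", "droop_deg",
                "n_leaves", "stem_radius_mm", "internode_cm")
  missing <- setdiff(required, names(spec))
  if (length(missing)) {
    stop("layer spec is missing columns: ", paste(missing, collapse = ", "))
  }
  validate_layer_spec(spec)
  class(spec) <- c("layer_spec", "data.frame")
  spec
}

validate_layer_spec <- function(spec) {
  num_cols <- c("leaf_area_cm2", "petiole_cm", "stem_radius_mm",
                "internode_cm")
  for (col in num_cols) {
    if (any(spec[[col]] <= 0)) stop("column ", col, " must be positive")
  }
  if (any(spec$droop_deg < 0 | spec$droop_deg > 90)) {
    stop("droop_deg must lie in [0, 90]")
  }
  if (any(spec$n_leaves < 1)) stop("n_leaves must be >= 1")
  if (is.unsorted(spec$layer, strictly = TRUE)) {
    stop("layer indices must be strictly increasing")
  }
  invisible(spec)
}

#' Expand an odd-layer structural table to all 15 nodes
#'
#' The structural table records the odd node positions only; even nodes are
#' filled by linear interpolation of the continuous columns between the
#' bracketing odd nodes (odd nodes are reproduced exactly). The discrete
#' leaf count `n_leaves` is taken from the nearest tabulated layer (ties go
#' to the lower layer).
#'
#' @param spec A `layer_spec` data frame (see [read_layer_spec()]).
#' @param nodes Node indices to produce (default 1:15).
#' @return A data frame with one row per node.
#' @export
expand_layer_spec <- function(spec, nodes = 1:15) {
  validate_layer_spec(spec)
  lo <- min(nodes); hi <- max(nodes)
  if (min(spec$layer) > lo || max(spec$layer) < hi) {
    stop("layer spec must bracket nodes ", lo, "..", hi,
         " (covers ", min(spec$layer), "..", max(spec$layer), ")")
  }
  cont <- c("leaf_area_cm2", "petiole_cm", "droop_deg", "stem_radius_mm",
            "internode_cm")
  out <- data.frame(node = nodes)
  for (col in cont) {
    out[[col]] <- stats::approx(spec$layer, spec[[col]], xout = nodes)$y
  }
  nearest <- vapply(nodes, function(n) {
    d <- abs(spec$layer - n)
    spec$n_leaves[which.min(d)]  # which.min takes the lower layer on ties
  }, numeric(1))
  out$n_leaves <- nearest
  out
}
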