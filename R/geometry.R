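#' Read a geometry specification
#'
#' A geometry specification describes the two-dimensional vocal fold
#' cross-section: the outer boundary polygon, named layer polygons
#' (epithelium, superficial lamina propria, ligament; anything not covered
#' is body), the hemilaryngeal contact plane location, the anterior-posterior
#' depth used to convert widths to areas, and the glottal channel extent.
#'
#' @param path Path to a JSON geometry file.  The default is the packaged
#'   modified-M5 four-layer cross-section.
#' @return A list of class `vf_geometry_spec`.
#' @export
read_geometry_spec <- function(path = default_geometry_path()) {
  if (!file.exists(path)) {
    stop("geometry spec file not found: ", path, call. = FALSE)
  }
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec$outer <- as.matrix(spec$outer)
  spec$layers <- lapply(spec$layers, as.matrix)
  validate_geometry_spec(spec)
  class(spec) <- "vf_geometry_spec"
  spec
}

#' @rdname read_geometry_spec
#' @export
default_geometry_path <- function() {
  system.file("extdata", "m5_geometry.json", package = "vfbayes", mustWork = TRUE)
}

validate_geometry_spec <- function(spec) {
  if (is.null(spec$outer) || nrow(spec$outer) < 3) {
    stop("geometry error: outer polygon is degenerate", call. = FALSE)
  }
  if (abs(polygon_area(spec$outer)) < 1e-9) {
    stop("geometry error: outer polygon has zero area", call. = FALSE)
  }
  for (nm in names(spec$layers)) {
    if (nrow(spec$layers[[nm]]) < 3) {
      stop("geometry error: layer polygon '", nm, "' is degenerate", call. = FALSE)
    }
  }
  invisible(spec)
}

#' Construct a geometry spec from components
#'
#' Mainly used for small test geometries; production work uses the packaged
#' spec via [read_geometry_spec()].
#'
#' @param outer Outer boundary polygon, an n x 2 matrix of (x, z) in mm.
#' @param layers Named list of layer polygons (may be empty; every element
#'   then belongs to the body layer).
#' @param contact_plane_x x-coordinate of the hemilaryngeal contact plane (mm).
#' @param depth Anterior-posterior depth in mm used for width-area conversion.
#' @param z_in,z_out Inferior and superior ends of the glottal channel (mm).
#' @param fixed_boundaries Which boundary chains are clamped; subset of
#'   `"left"`, `"bottom"`, `"top"`.
#' @return A list of class `vf_geometry_spec`.
#' @export
geometry_spec <- function(outer, layers = list(), contact_plane_x,
                          depth = 14, z_in = -3.6, z_out = 0,
                          fixed_boundaries = c("left", "bottom")) {
  spec <- list(outer = as.matrix(outer),
               layers = lapply(layers, as.matrix),
               contact_plane_x = contact_plane_x, depth = depth,
               z_in = z_in, z_out = z_out,
               fixed_boundaries = fixed_boundaries)
  validate_geometry_spec(spec)
  class(spec) <- "vf_geometry_spec"
  spec
}

polygon_area <- function(p) {
  x <- p[, 1]; z <- p[, 2]
  0.5 * sum(x * z[c(2:length(z), 1)] - x[c(2:length(x), 1)] * z)
}

# x-interval covered by the domain at height z: intersect the outer polygon
# boundary with the horizontal line.  The domain must be a single interval
# at every z (z-monotone left and right chains).
row_interval <- function(outer, z, tol = 1e-9) {
  n <- nrow(outer)
  xs <- numeric(0)
  for (i in seq_len(n)) {
    a <- outer[i, ]; b <- outer[if (i == n) 1 else i + 1, ]
    if (abs(a[2] - z) < tol && abs(b[2] - z) < tol) {
      xs <- c(xs, a[1], b[1])            # horizontal edge on the line
    } else if ((a[2] - z) * (b[2] - z) <= tol &&
               abs(b[2] - a[2]) > tol) {
      s <- (z - a[2]) / (b[2] - a[2])
      if (s >= -tol && s <= 1 + tol) xs <- c(xs, a[1] + s * (b[1] - a[1]))
    }
  }
  if (length(xs) == 0) {
    stop("geometry error: no boundary intersection at z = ", z, call. = FALSE)
  }
  range(xs)
}

#' Build the layered triangulated cross-section
#'
#' Generates a conforming structured triangulation of the cross-section
#' described by a geometry spec: mesh rows follow the z-breakpoints of the
#' outer polygon (subdivided to the requested resolution), each row spans
#' the domain's x-interval at that height with a fixed column count, and
#' each quad cell is split along the diagonal that maximises the minimum
#' triangle angle.  Each element is assigned the layer of the polygon
#' containing its centroid (epithelium, then SLP, then ligament, else body).
#'
#' @param resolution Characteristic element size in mm (> 0).
#' @param spec A `vf_geometry_spec`; default is the packaged modified-M5
#'   cross-section.
#' @return An object of class `vf_mesh`: node coordinates (mm), triangle
#'   index triples (positively oriented), per-element layer labels, the
#'   ordered fluid-loaded surface `gamma_f` (inferior to superior), the
#'   fixed-boundary node set `gamma_fixed`, the contact plane location, and
#'   the anterior-posterior depth.
#' @export
build_m5_mesh <- function(resolution = 0.3, spec = read_geometry_spec()) {
  stopifnot(resolution > 0)
  outer <- spec$outer

  zb <- sort(unique(outer[, 2]))
  zs <- numeric(0)
  for (i in seq_len(length(zb) - 1)) {
    n <- max(1L, ceiling((zb[i + 1] - zb[i]) / resolution))
    zs <- c(zs, seq(zb[i], zb[i + 1], length.out = n + 1L)[-(n + 1L)])
  }
  zs <- c(zs, zb[length(zb)])

  iv <- t(vapply(zs, function(z) row_interval(outer, z), numeric(2)))
  widths <- iv[, 2] - iv[, 1]
  ncol_cells <- max(1L, ceiling(max(widths) / resolution))
  nxc <- ncol_cells + 1L
  nrows <- length(zs)

  nodes <- matrix(0, nrows * nxc, 2)
  for (j in seq_len(nrows)) {
    idx <- ((j - 1L) * nxc + 1L):(j * nxc)
    nodes[idx, 1] <- seq(iv[j, 1], iv[j, 2], length.out = nxc)
    nodes[idx, 2] <- zs[j]
  }
  node_id <- function(i, j) as.integer((j - 1L) * nxc + i)   # i: column, j: row

  tris <- matrix(0L, 2L * ncol_cells * (nrows - 1L), 3L)
  k <- 0L
  for (j in seq_len(nrows - 1L)) {
    for (i in seq_len(ncol_cells)) {
      a <- node_id(i, j);     b <- node_id(i + 1L, j)
      c2 <- node_id(i + 1L, j + 1L); d <- node_id(i, j + 1L)
      split1 <- list(c(a, b, c2), c(a, c2, d))   # diagonal a-c
      split2 <- list(c(a, b, d), c(b, c2, d))    # diagonal b-d
      q1 <- min(vapply(split1, function(t) tri_min_angle(nodes[t, ]), 1))
      q2 <- min(vapply(split2, function(t) tri_min_angle(nodes[t, ]), 1))
      pick <- if (q1 >= q2) split1 else split2
      tris[k + 1L, ] <- pick[[1]]; tris[k + 2L, ] <- pick[[2]]
      k <- k + 2L
    }
  }

  areas <- tri_signed_areas(nodes, tris)
  if (any(areas <= 0)) {
    flip <- which(areas < 0)
    tris[flip, c(2, 3)] <- tris[flip, c(3, 2)]
    areas <- abs(areas)
  }
  keep <- areas > 1e-12
  tris <- tris[keep, , drop = FALSE]

  centroids <- cbind(
    rowMeans(matrix(nodes[tris, 1], ncol = 3)),
    rowMeans(matrix(nodes[tris, 2], ncol = 3))
  )
  layer <- rep("body", nrow(tris))
  for (nm in rev(names(spec$layers))) {  # innermost band last in file order
    p <- spec$layers[[nm]]
    inside <- pracma::inpolygon(centroids[, 1], centroids[, 2],
                                p[, 1], p[, 2], boundary = TRUE)
    layer[inside] <- nm
  }
  for (nm in names(spec$layers)) {
    if (!any(layer == nm)) {
      stop("resolution error: layer '", nm,
           "' received no element at resolution ", resolution, call. = FALSE)
    }
  }

  gamma_f <- vapply(seq_len(nrows), function(j) node_id(nxc, j), integer(1))
  fixed <- integer(0)
  fb <- spec$fixed_boundaries %||% c("left", "bottom")
  if ("left" %in% fb)   fixed <- c(fixed, vapply(seq_len(nrows), function(j) node_id(1L, j), integer(1)))
  if ("bottom" %in% fb) fixed <- c(fixed, node_id(seq_len(nxc), 1L))
  if ("top" %in% fb)    fixed <- c(fixed, node_id(seq_len(nxc), nrows))
  gamma_fixed <- sort(unique(fixed))

  mesh <- structure(list(
    nodes = nodes, triangles = tris,
    layer = factor(layer, levels = union(c("body"), names(spec$layers))),
    gamma_f = gamma_f, gamma_fixed = gamma_fixed,
    contact_plane_x = spec$contact_plane_x, depth = spec$depth %||% 14,
    z_in = spec$z_in %||% -3.6, z_out = spec$z_out %||% 0,
    resolution = resolution, n_rows = nrows, n_cols = nxc
  ), class = "vf_mesh")
  mesh
}

`%||%` <- function(a, b) if (is.null(a)) b else a

tri_signed_areas <- function(nodes, tris) {
  x <- matrix(nodes[tris, 1], ncol = 3)
  z <- matrix(nodes[tris, 2], ncol = 3)
  0.5 * ((x[, 2] - x[, 1]) * (z[, 3] - z[, 1]) -
         (x[, 3] - x[, 1]) * (z[, 2] - z[, 1]))
}

tri_min_angle <- function(p) {
  v <- rbind(p[2, ] - p[1, ], p[3, ] - p[2, ], p[1, ] - p[3, ])
  l <- sqrt(rowSums(v^2))
  if (any(l == 0)) return(0)
  # law of cosines; angle at vertex i is between edges i-1 and i (mod 3)
  a <- acos(pmin(1, pmax(-1, c(
    sum(-v[3, ] * v[1, ]) / (l[3] * l[1]),
    sum(-v[1, ] * v[2, ]) / (l[1] * l[2]),
    sum(-v[2, ] * v[3, ]) / (l[2] * l[3])
  ))))
  min(a)
}

#' Mesh summaries
#'
#' `mesh_min_angle` returns the minimum interior angle over all elements in
#' degrees; `layer_areas` the summed element area per layer in mm^2.
#'
#' @param mesh A `vf_mesh`.
#' @export
mesh_min_angle <- function(mesh) {
  angs <- vapply(seq_len(nrow(mesh$triangles)), function(e) {
    tri_min_angle(mesh$nodes[mesh$triangles[e, ], ])
  }, numeric(1))
  min(angs) * 180 / pi
}

#' @rdname mesh_min_angle
#' @export
layer_areas <- function(mesh) {
  a <- abs(tri_signed_areas(mesh$nodes, mesh$triangles))
  tapply(a, mesh$layer, sum, default = 0)
}

#' @export
print.vf_mesh <- function(x, ...) {
  cat("<vf_mesh> ", nrow(x$nodes), " nodes, ", nrow(x$triangles),
      " triangles\n", sep = "")
  cat("  layers: ", paste(sprintf("%s (%d)", levels(x$layer),
                                  tabulate(x$layer, nbins = nlevels(x$layer))),
                          collapse = ", "), "\n", sep = "")
  cat("  contact plane x = ", x$contact_plane_x, " mm, depth = ",
      x$depth, " mm\n", sep = "")
  invisible(x)
}
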