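# Generates inst/extdata/m5_geometry.json: the shipped four-layer modified-M5
# cross-section (coordinates in mm, x medial-lateral, z inferior-superior,
# z = 0 at the glottal outlet).  Layer bands are inward offsets of the
# air-exposed surface chain.  Run from the package root:
#   Rscript tools/make_geometry.R

# Air-exposed surface chain, ordered inferior -> superior.  The medial flat
# segment sits 0.2 mm short of the contact plane (x = 8.4); a medial
# compression of 0.4 mm presses it into the plane.
chain <- rbind(
  c(4.30, -10.70),   # inferior-medial corner (meets the fixed base)
  c(5.80,  -5.60),   # subglottal slope
  c(7.40,  -3.60),   # glottal inlet (z_in)
  c(8.20,  -2.00),   # convergent entry
  c(8.20,  -0.90),   # medial flat segment (contact strip)
  c(8.05,  -0.40),   # divergent exit
  c(7.70,   0.00)    # glottal outlet (z_out), superior-medial corner
)

outer <- rbind(
  c(0.00,   0.00),   # superior-lateral corner
  c(0.00, -10.70),   # lateral wall (fixed)
  chain,             # bottom-medial corner up the air-exposed chain
  c(7.70,   0.00)
)
outer <- outer[!duplicated(outer), ]

densify <- function(pts, ds = 0.05) {
  out <- list()
  for (i in seq_len(nrow(pts) - 1)) {
    a <- pts[i, ]; b <- pts[i + 1, ]
    n <- max(2L, ceiling(sqrt(sum((b - a)^2)) / ds) + 1L)
    s <- seq(0, 1, length.out = n)
    seg <- cbind(a[1] + s * (b[1] - a[1]), a[2] + s * (b[2] - a[2]))
    if (i > 1) seg <- seg[-1, , drop = FALSE]
    out[[i]] <- seg
  }
  do.call(rbind, out)
}

# Averaged outward normals along a polyline (outward = away from the domain
# interior, i.e. rotate the inferior->superior tangent by -90 degrees).
outward_normals <- function(pts) {
  d <- diff(pts)
  len <- sqrt(rowSums(d^2))
  seg_n <- cbind(d[, 2], -d[, 1]) / len
  n <- rbind(seg_n[1, , drop = FALSE],
             (seg_n[-1, , drop = FALSE] + seg_n[-nrow(seg_n), , drop = FALSE]),
             seg_n[nrow(seg_n), , drop = FALSE])
  n / sqrt(rowSums(n^2))
}

offset_chain <- function(pts, d) pts - d * outward_normals(pts)

decimate <- function(pts, keep_every = 8L) {
  idx <- unique(c(seq(1, nrow(pts), by = keep_every), nrow(pts)))
  pts[idx, ]
}

band_polygon <- function(chain_dense, d_in, d_out) {
  inner <- decimate(offset_chain(chain_dense, d_out))
  outer_edge <- if (d_in == 0) decimate(chain_dense) else
    decimate(offset_chain(chain_dense, d_in))
  rbind(outer_edge, inner[rev(seq_len(nrow(inner))), ])
}

cd <- densify(chain)
layers <- list(
  epithelium = band_polygon(cd, 0.00, 0.35),
  slp        = band_polygon(cd, 0.35, 2.35),
  ligament   = band_polygon(cd, 2.35, 3.35)
)

as_list <- function(m) lapply(seq_len(nrow(m)), function(i) round(unname(m[i, ]), 4))

spec <- list(
  name = "modified-M5 four-layer hemilaryngeal cross-section (synthetic layout)",
  units = "mm",
  contact_plane_x = 8.4,
  depth = 14,
  z_in = -3.6,
  z_out = 0,
  outer = as_list(outer),
  layers = lapply(layers, as_list),
  fixed_boundaries = c("left", "bottom"),
  surface_chain = as_list(chain)
)

jsonlite::write_json(spec, "inst/extdata/m5_geometry.json",
                     auto_unbox = TRUE, digits = 6, pretty = TRUE)
cat("wrote inst/extdata/m5_geometry.json\n")
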