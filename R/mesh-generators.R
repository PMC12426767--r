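# Structured mesh generators for the two analytic benchmarks: a symmetric
# (crossed-diagonal) triangulation of the unit square, and a tetrahedral
# cylinder built by extruding a hexagonal-ring disk triangulation, optionally
# with graded near-wall boundary layers.

#' Structured symmetric triangulation of the unit square
#'
#' Each of the `n x n` squares is split into four triangles by both diagonals
#' (a "crossed" pattern, symmetric about both axes).  The four sides are
#' tagged `left` (1), `right` (2), `bottom` (3), `top` (4).
#'
#' @param n_per_side number of square subdivisions per side (>= 1).
#' @return a `tagged_mesh` with `4 * n^2` triangles.
#' @export
build_unit_square_mesh <- function(n_per_side) {
  n <- as.integer(n_per_side)
  if (is.na(n) || n < 1L) stop("n_per_side must be a positive integer")
  h <- 1 / n
  xy <- seq(0, 1, length.out = n + 1L)
  grid <- as.matrix(expand.grid(x = xy, y = xy))      # (n+1)^2, x fastest
  ctr <- as.matrix(expand.grid(x = xy[-1] - h / 2, y = xy[-1] - h / 2))
  vertices <- rbind(grid, ctr)
  gid <- function(i, j) (j - 1L) * (n + 1L) + i        # i,j in 1..n+1
  cid <- function(i, j) (n + 1L)^2 + (j - 1L) * n + i  # i,j in 1..n
  ii <- rep(seq_len(n), times = n)
  jj <- rep(seq_len(n), each = n)
  v00 <- gid(ii, jj); v10 <- gid(ii + 1L, jj)
  v01 <- gid(ii, jj + 1L); v11 <- gid(ii + 1L, jj + 1L)
  vc <- cid(ii, jj)
  cells <- rbind(cbind(v00, v10, vc), cbind(v10, v11, vc),
                 cbind(v11, v01, vc), cbind(v01, v00, vc))
  tagger <- function(centroid, normal) {
    tag <- integer(nrow(centroid))
    tag[centroid[, 1] < 1e-12] <- 1L
    tag[centroid[, 1] > 1 - 1e-12] <- 2L
    tag[centroid[, 2] < 1e-12] <- 3L
    tag[centroid[, 2] > 1 - 1e-12] <- 4L
    tag
  }
  tagged_mesh(vertices, cells,
              region_names = c("1" = "left", "2" = "right",
                               "3" = "bottom", "4" = "top"),
              facet_tagger = tagger)
}

#' Near-wall boundary-layer specification
#'
#' Prismatic layers graded towards the wall: the layer adjacent to the wall
#' has height `first_layer_fraction` of the surface edge length, and each
#' layer inward grows by `growth_ratio`.
#'
#' @param n_layers number of layers (>= 1); default 4.
#' @param first_layer_fraction wall-adjacent layer height as a fraction of the
#'   surface edge length; default 0.1.
#' @param growth_ratio layer-to-layer growth factor (>= 1); default 1.1.
#' @export
boundary_layer_spec <- function(n_layers = 4L, first_layer_fraction = 0.1,
                                growth_ratio = 1.1) {
  n_layers <- as.integer(n_layers)
  if (is.na(n_layers) || n_layers < 1L) stop("n_layers must be >= 1")
  if (!(first_layer_fraction > 0 && first_layer_fraction < 1)) {
    stop("first_layer_fraction must lie in (0, 1)")
  }
  if (growth_ratio < 1) stop("growth_ratio must be >= 1")
  structure(list(n_layers = n_layers,
                 first_layer_fraction = first_layer_fraction,
                 growth_ratio = growth_ratio), class = "boundary_layer_spec")
}

# layer heights from the wall inward, in metres
bl_heights <- function(bl, edge_length) {
  bl$first_layer_fraction * edge_length * bl$growth_ratio^(seq_len(bl$n_layers) - 1)
}

#' Tetrahedral mesh of an axis-aligned cylinder
#'
#' The cylinder has radius `radius`, axis along z, and spans `z in [0, length]`.
#' The cross-section is a hexagonal-ring disk triangulation with target edge
#' length `edge_length`, extruded in z and split into tetrahedra with a
#' globally consistent diagonal rule.  Regions: `inlet` (1, z = 0), `outlet`
#' (2, z = length), `wall` (3, lateral surface).  With a
#' [boundary_layer_spec()], the outermost rings are replaced by graded
#' near-wall layers while the core keeps the uniform edge length.
#'
#' @param radius,length cylinder radius and length (m).
#' @param edge_length target edge length (m), must be `< radius`.
#' @param bl optional [boundary_layer_spec()].
#' @return a `tagged_mesh`.
#' @export
build_cylinder_mesh <- function(radius, length, edge_length, bl = NULL) {
  if (!(radius > 0 && length > 0 && edge_length > 0)) {
    stop("radius, length and edge_length must be positive")
  }
  if (edge_length >= radius) stop("edge_length must be smaller than radius")
  if (!is.null(bl) && !inherits(bl, "boundary_layer_spec")) {
    stop("bl must be a boundary_layer_spec or NULL")
  }
  disk <- disk_triangulation(radius, edge_length, bl)
  nz <- max(1L, round(length / edge_length))
  mesh3 <- extrude_triangulation(disk, length, nz)
  tol <- 1e-9 * max(radius, length)
  tagger <- function(centroid, normal) {
    tag <- rep(3L, nrow(centroid))
    tag[centroid[, 3] < tol] <- 1L
    tag[centroid[, 3] > length - tol] <- 2L
    tag
  }
  tagged_mesh(mesh3$vertices, mesh3$cells,
              region_names = c("1" = "inlet", "2" = "outlet", "3" = "wall"),
              facet_tagger = tagger)
}

# Hexagonal-ring triangulation of a disk of given radius.  Ring j carries
# 6*j points; radii are uniform, except that with a boundary-layer spec the
# outermost rings follow the graded layer heights (wall-finest first).
disk_triangulation <- function(radius, edge_length, bl = NULL) {
  if (is.null(bl)) {
    m <- max(2L, round(radius / edge_length))
    radii <- radius * seq_len(m) / m
    counts <- 6L * seq_len(m)
  } else {
    hts <- bl_heights(bl, edge_length)          # wall-adjacent first
    t_bl <- sum(hts)
    if (t_bl >= radius) stop("boundary layers thicker than radius; reduce edge_length")
    r_core <- radius - t_bl
    m <- max(2L, round(r_core / edge_length))
    radii_core <- r_core * seq_len(m) / m
    radii_bl <- r_core + cumsum(rev(hts))       # inward->outward
    radii <- c(radii_core, radii_bl)
    counts <- c(6L * seq_len(m), rep(6L * m, bl$n_layers))
  }
  nrings <- length(radii)
  verts <- matrix(0, 1 + sum(counts), 2)
  idx0 <- 1L + c(0L, cumsum(counts))            # start offset of each ring
  ang <- vector("list", nrings)
  for (j in seq_len(nrings)) {
    a <- 2 * pi * (seq_len(counts[j]) - 1L) / counts[j]
    ang[[j]] <- a
    verts[idx0[j] + seq_len(counts[j]), ] <- radii[j] * cbind(cos(a), sin(a))
  }
  cells <- NULL
  # center fan
  first <- idx0[1] + seq_len(counts[1])
  cells <- cbind(1L, first, c(first[-1], first[1]))
  for (j in 2:nrings) {
    inner <- idx0[j - 1] + seq_len(counts[j - 1])
    outer <- idx0[j] + seq_len(counts[j])
    cells <- rbind(cells, zip_rings(inner, ang[[j - 1]], outer, ang[[j]]))
  }
  list(vertices = verts, cells = cells)
}

# Triangulate the annulus between two concentric closed rings of points by an
# angular merge (a "zip"): advance along whichever ring has the smaller next
# angle.  Produces length(inner) + length(outer) triangles.
zip_rings <- function(inner, ang_in, outer, ang_out) {
  ni <- length(inner); no <- length(outer)
  tri <- matrix(0L, ni + no, 3)
  i <- 1L; j <- 1L; k <- 1L
  next_in <- function(i) if (i < ni) ang_in[i + 1] else ang_in[1] + 2 * pi
  next_out <- function(j) if (j < no) ang_out[j + 1] else ang_out[1] + 2 * pi
  while (i <= ni || j <= no) {
    adv_inner <- if (i > ni) FALSE else if (j > no) TRUE else
      next_in(i) <= next_out(j)
    if (adv_inner) {
      i2 <- if (i < ni) i + 1L else 1L
      tri[k, ] <- c(inner[i], inner[i2], outer[if (j <= no) j else 1L])
      i <- i + 1L
    } else {
      j2 <- if (j < no) j + 1L else 1L
      tri[k, ] <- c(inner[if (i <= ni) i else 1L], outer[j2], outer[j])
      j <- j + 1L
    }
    k <- k + 1L
  }
  tri
}

# Extrude a 2D triangulation along z into nz prism layers, splitting each
# prism into three tetrahedra with diagonals chosen from the smaller global
# bottom-vertex index (guarantees conforming faces between neighbours).
extrude_triangulation <- function(disk, length, nz) {
  nvd <- nrow(disk$vertices)
  z <- seq(0, length, length.out = nz + 1L)
  vertices <- cbind(disk$vertices[rep(seq_len(nvd), nz + 1L), , drop = FALSE],
                    rep(z, each = nvd))
  tris <- disk$cells
  cells <- matrix(0L, nrow(tris) * nz * 3L, 4)
  k <- 0L
  for (l in seq_len(nz)) {
    off_b <- (l - 1L) * nvd
    srt <- t(apply(tris, 1L, sort))              # v0 < v1 < v2 (disk ids)
    b0 <- srt[, 1] + off_b; b1 <- srt[, 2] + off_b; b2 <- srt[, 3] + off_b
    t0 <- b0 + nvd; t1 <- b1 + nvd; t2 <- b2 + nvd
    n <- nrow(srt)
    cells[k + seq_len(n), ] <- cbind(b0, b1, b2, t2)
    cells[k + n + seq_len(n), ] <- cbind(b0, b1, t2, t1)
    cells[k + 2L * n + seq_len(n), ] <- cbind(b0, t1, t2, t0)
    k <- k + 3L * n
  }
  list(vertices = vertices, cells = cells)
}
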