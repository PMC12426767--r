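# Tagged simplicial meshes: the container every solver and WSS evaluator
# consumes.  A tagged_mesh stores vertices, positively oriented cells, the
# boundary facets with exactly one region tag each, per-cell circumdiameters
# h_K, and the facet connectivity needed for interior-penalty stabilization
# and boundary assembly.

#' Construct a tagged simplicial mesh
#'
#' @param vertices numeric matrix (n_vertices x dim) of coordinates in metres.
#' @param cells integer matrix (n_cells x dim+1) of vertex indices (1-based).
#'   Cells are reoriented to positive volume if needed.
#' @param region_names named character vector mapping region ids (names) to
#'   labels, e.g. `c("1" = "inlet", "2" = "outlet", "3" = "wall")`.
#' @param facet_tagger function(centroids, normals) returning an integer tag
#'   per boundary facet, or `NULL` if `boundary_tags` is given.
#' @param boundary_tags optional list with `facets` (matrix of vertex indices)
#'   and `tags` (integer vector), e.g. as read from a mesh file.
#' @return object of class `tagged_mesh`.
#' @export
tagged_mesh <- function(vertices, cells, region_names, facet_tagger = NULL,
                        boundary_tags = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  cells <- as.matrix(cells)
  storage.mode(cells) <- "integer"
  dim <- ncol(vertices)
  stopifnot(dim %in% c(2L, 3L), ncol(cells) == dim + 1L)

  cells <- orient_cells(vertices, cells)
  conn <- facet_connectivity(cells, dim)

  bf <- conn$boundary_facets
  geo <- boundary_facet_geometry(vertices, cells, bf, conn$boundary_cell,
                                 conn$boundary_local)
  if (!is.null(boundary_tags)) {
    key_mesh <- facet_keys(bf, nrow(vertices))
    key_in <- facet_keys(as.matrix(boundary_tags$facets), nrow(vertices))
    idx <- match(key_mesh, key_in)
    if (anyNA(idx)) {
      stop("untagged boundary: ", sum(is.na(idx)),
           " boundary facet(s) carry no region tag")
    }
    tags <- as.integer(boundary_tags$tags[idx])
  } else if (!is.null(facet_tagger)) {
    tags <- as.integer(facet_tagger(geo$centroid, geo$normal))
    if (anyNA(tags)) stop("untagged boundary: facet_tagger returned NA")
  } else {
    stop("untagged boundary: supply facet_tagger or boundary_tags")
  }
  if (!all(as.character(tags) %in% names(region_names))) {
    stop("facet tags outside region_names: ",
         paste(setdiff(unique(tags), as.integer(names(region_names))),
               collapse = ", "))
  }

  h <- cell_circumdiameter(vertices, cells)
  if (any(!is.finite(h)) || any(h <= 0)) {
    stop("degenerate cell: nonpositive circumdiameter (check 'cells')")
  }

  structure(list(
    dim = dim, vertices = vertices, cells = cells,
    region_names = region_names,
    boundary_facets = bf, facet_tags = tags,
    boundary_cell = conn$boundary_cell, boundary_local = conn$boundary_local,
    boundary_measure = geo$measure, boundary_normal = geo$normal,
    boundary_centroid = geo$centroid,
    interior_facets = conn$interior_facets,
    interior_cells = conn$interior_cells,
    cell_h = h
  ), class = "tagged_mesh")
}

#' @export
print.tagged_mesh <- function(x, ...) {
  cat(sprintf("<tagged_mesh> dim %d: %d vertices, %d cells, %d boundary facets\n",
              x$dim, nrow(x$vertices), nrow(x$cells), nrow(x$boundary_facets)))
  cat("  h_K in [", format(min(x$cell_h), digits = 4), ", ",
      format(max(x$cell_h), digits = 4), "]\n", sep = "")
  tab <- table(x$facet_tags)
  for (id in names(tab)) {
    cat(sprintf("  region %s (%s): %d facets, measure %.6g\n", id,
                x$region_names[[id]], tab[[id]], region_area(x, as.integer(id))))
  }
  invisible(x)
}

# reorder cell vertices so all signed volumes are positive
orient_cells <- function(vertices, cells) {
  vol <- signed_volume(vertices, cells)
  neg <- which(vol < 0)
  if (length(neg)) {
    tmp <- cells[neg, 2L]
    cells[neg, 2L] <- cells[neg, 3L]
    cells[neg, 3L] <- tmp
  }
  cells
}

signed_volume <- function(vertices, cells) {
  d <- ncol(vertices)
  p0 <- vertices[cells[, 1], , drop = FALSE]
  e1 <- vertices[cells[, 2], , drop = FALSE] - p0
  e2 <- vertices[cells[, 3], , drop = FALSE] - p0
  if (d == 2L) {
    (e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]) / 2
  } else {
    e3 <- vertices[cells[, 4], , drop = FALSE] - p0
    (e1[, 1] * (e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]) -
     e1[, 2] * (e2[, 1] * e3[, 3] - e2[, 3] * e3[, 1]) +
     e1[, 3] * (e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1])) / 6
  }
}

# integer keys identifying a facet independently of vertex order
facet_keys <- function(facets, nv) {
  M <- as.numeric(nv + 1)
  if (ncol(facets) == 2L) {
    lo <- pmin(facets[, 1], facets[, 2])
    hi <- pmax(facets[, 1], facets[, 2])
    lo + M * hi
  } else {
    a <- facets[, 1]; b <- facets[, 2]; c <- facets[, 3]
    lo <- pmin(a, b, c)
    hi <- pmax(a, b, c)
    mid <- as.numeric(a) + as.numeric(b) + as.numeric(c) - lo - hi
    lo + M * (mid + M * hi)
  }
}

# classify all cell facets into interior (shared) and boundary (unshared)
facet_connectivity <- function(cells, dim) {
  lf <- if (dim == 2L) tri_facets else tet_facets
  nlf <- nrow(lf)
  nc <- nrow(cells)
  all_facets <- do.call(rbind, lapply(seq_len(nlf), function(f) {
    cells[, lf[f, ], drop = FALSE]
  }))
  cell_of <- rep(seq_len(nc), times = nlf)
  local_of <- rep(seq_len(nlf), each = nc)
  nv <- max(cells)
  key <- facet_keys(all_facets, nv)
  o <- order(key)
  key_s <- key[o]
  n <- length(key_s)
  same_next <- c(key_s[-n] == key_s[-1L], FALSE)
  same_prev <- c(FALSE, same_next[-n])
  is_int_first <- same_next & !same_prev
  first <- o[is_int_first]
  second <- o[which(is_int_first) + 1L]
  single <- o[!same_next & !same_prev]
  list(
    boundary_facets = all_facets[single, , drop = FALSE],
    boundary_cell = cell_of[single],
    boundary_local = local_of[single],
    interior_facets = all_facets[first, , drop = FALSE],
    interior_cells = cbind(cell_of[first], cell_of[second])
  )
}

# measure, outward unit normal and centroid of each boundary facet
boundary_facet_geometry <- function(vertices, cells, facets, bcell, blocal) {
  d <- ncol(vertices)
  p1 <- vertices[facets[, 1], , drop = FALSE]
  p2 <- vertices[facets[, 2], , drop = FALSE]
  if (d == 2L) {
    t <- p2 - p1
    len <- sqrt(rowSums(t^2))
    normal <- cbind(t[, 2], -t[, 1]) / len
    centroid <- (p1 + p2) / 2
    measure <- len
  } else {
    p3 <- vertices[facets[, 3], , drop = FALSE]
    e1 <- p2 - p1; e2 <- p3 - p1
    cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    nrm <- sqrt(rowSums(cr^2))
    normal <- cr / nrm
    centroid <- (p1 + p2 + p3) / 3
    measure <- nrm / 2
  }
  # orient outward: away from the opposite vertex of the adjacent cell
  opp <- cells[cbind(bcell, blocal)]
  tovert <- centroid - vertices[opp, , drop = FALSE]
  flip <- rowSums(normal * tovert) < 0
  normal[flip, ] <- -normal[flip, ]
  list(measure = measure, normal = normal, centroid = centroid)
}

# circumdiameter h_K: diameter of the circumscribed circle/sphere
cell_circumdiameter <- function(vertices, cells) {
  d <- ncol(vertices)
  if (d == 2L) {
    a <- sqrt(rowSums((vertices[cells[, 2], , drop = FALSE] -
                         vertices[cells[, 3], , drop = FALSE])^2))
    b <- sqrt(rowSums((vertices[cells[, 1], , drop = FALSE] -
                         vertices[cells[, 3], , drop = FALSE])^2))
    cc <- sqrt(rowSums((vertices[cells[, 1], , drop = FALSE] -
                          vertices[cells[, 2], , drop = FALSE])^2))
    area <- abs(signed_volume(vertices, cells))
    a * b * cc / (2 * area)
  } else {
    p0 <- vertices[cells[, 1], , drop = FALSE]
    r1 <- vertices[cells[, 2], , drop = FALSE] - p0
    r2 <- vertices[cells[, 3], , drop = FALSE] - p0
    r3 <- vertices[cells[, 4], , drop = FALSE] - p0
    # solve 2 R x = b with R rows r1,r2,r3 via adjugate
    bvec <- cbind(rowSums(r1^2), rowSums(r2^2), rowSums(r3^2))
    cr23 <- cross3(r2, r3); cr31 <- cross3(r3, r1); cr12 <- cross3(r1, r2)
    det <- rowSums(r1 * cr23)
    cx <- (bvec[, 1] * cr23[, 1] + bvec[, 2] * cr31[, 1] + bvec[, 3] * cr12[, 1]) / (2 * det)
    cy <- (bvec[, 1] * cr23[, 2] + bvec[, 2] * cr31[, 2] + bvec[, 3] * cr12[, 2]) / (2 * det)
    cz <- (bvec[, 1] * cr23[, 3] + bvec[, 2] * cr31[, 3] + bvec[, 3] * cr12[, 3]) / (2 * det)
    2 * sqrt(cx^2 + cy^2 + cz^2)
  }
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Measure of a tagged boundary region
#'
#' Sums the facet measures (length in 2D, area in 3D) of all boundary facets
#' carrying the given tag; exact for affine facets.
#'
#' @param mesh a `tagged_mesh`.
#' @param tag integer region id or region label.
#' @return total measure (m or m^2).
#' @export
region_area <- function(mesh, tag) {
  tag <- resolve_tag(mesh, tag)
  sum(mesh$boundary_measure[mesh$facet_tags == tag])
}

# accept either a region id or its label
resolve_tag <- function(mesh, tag) {
  if (is.character(tag)) {
    id <- names(mesh$region_names)[match(tag, mesh$region_names)]
    if (is.na(id)) {
      stop("unknown region '", tag, "'; available: ",
           paste(sprintf("%s=%s", names(mesh$region_names), mesh$region_names),
                 collapse = ", "))
    }
    return(as.integer(id))
  }
  tag <- as.integer(tag)
  if (!as.character(tag) %in% names(mesh$region_names)) {
    stop("unknown region id ", tag, "; available: ",
         paste(sprintf("%s=%s", names(mesh$region_names), mesh$region_names),
               collapse = ", "))
  }
  tag
}

resolve_tags <- function(mesh, tags) vapply(tags, resolve_tag, 1L, mesh = mesh)

#' Split a tagged boundary region by a spatial predicate
#'
#' Facets of `tag` whose centroids satisfy `predicate` are moved to a new
#' region.  Useful for carving a dome / parent-artery decomposition out of a
#' single wall tag.
#'
#' @param mesh a `tagged_mesh`.
#' @param tag region to split (id or label).
#' @param predicate function of a centroid matrix returning logical.
#' @param new_name label of the new region.
#' @return a new `tagged_mesh` with one additional region.
#' @export
split_region <- function(mesh, tag, predicate, new_name) {
  tag <- resolve_tag(mesh, tag)
  sel <- mesh$facet_tags == tag & predicate(mesh$boundary_centroid)
  new_id <- max(as.integer(names(mesh$region_names))) + 1L
  mesh$facet_tags[sel] <- new_id
  rn <- mesh$region_names
  rn[[as.character(new_id)]] <- new_name
  mesh$region_names <- rn
  mesh
}
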