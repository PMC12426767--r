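# Mesh file I/O: MSH 4.1 (ASCII) and XDMF (XML with inline data) round
# trips, with facet region tags, plus a VTU exporter for visual inspection.
# Region names come from the file where possible and can be overridden by a
# YAML sidecar mapping integer tags to labels.

#' Read a tagged simplicial mesh from MSH 4.1 or XDMF
#'
#' The boundary facet tags are taken from the file (physical surface tags in
#' MSH, a facet-grid attribute in XDMF).  `region_map` (or a YAML sidecar
#' `<path>.regions.yaml` with a `regions:` mapping) assigns labels to the
#' integer tags.
#'
#' @param path file path.
#' @param format "msh" or "xdmf"; guessed from the extension by default.
#' @param region_map named character vector (names = integer tags) or NULL.
#' @return a `tagged_mesh`.
#' @export
read_tagged_mesh <- function(path, format = NULL, region_map = NULL) {
  if (!file.exists(path)) stop("mesh file not found: ", path)
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     msh = "msh", xdmf = "xdmf", xmf = "xdmf",
                     stop("unknown mesh format for '", path,
                          "'; use format = \"msh\" or \"xdmf\""))
  }
  raw <- switch(format,
                msh = read_msh41(path),
                xdmf = read_xdmf(path),
                stop("unknown format '", format, "'"))
  if (is.null(raw$facets) || nrow(raw$facets) == 0L) {
    stop("untagged boundary: '", path, "' contains no tagged facet data")
  }
  sidecar <- paste0(path, ".regions.yaml")
  if (is.null(region_map) && file.exists(sidecar)) {
    y <- yaml::read_yaml(sidecar)
    region_map <- unlist(y$regions)
    names(region_map) <- names(y$regions)
  }
  tags_present <- sort(unique(raw$tags))
  if (is.null(region_map)) {
    region_map <- stats::setNames(paste0("region_", tags_present),
                                  as.character(tags_present))
  }
  missing <- setdiff(as.character(tags_present), names(region_map))
  if (length(missing)) {
    stop("region_map lacks labels for tags: ", paste(missing, collapse = ", "))
  }
  tagged_mesh(raw$vertices, raw$cells, region_names = region_map,
              boundary_tags = list(facets = raw$facets, tags = raw$tags))
}

#' Write a tagged mesh to MSH 4.1, XDMF or VTU
#'
#' @param mesh a `tagged_mesh`.
#' @param path output file; the extension selects the format.
#' @param region_sidecar also write `<path>.regions.yaml` with the region
#'   name map (default TRUE for msh/xdmf).
#' @export
write_tagged_mesh <- function(mesh, path, region_sidecar = TRUE) {
  fmt <- tolower(tools::file_ext(path))
  switch(fmt,
         msh = write_msh41(mesh, path),
         xdmf = write_xdmf(mesh, path),
         vtu = write_vtu(mesh, path),
         stop("unknown mesh format '", fmt, "'"))
  if (region_sidecar && fmt %in% c("msh", "xdmf")) {
    yaml::write_yaml(list(regions = as.list(mesh$region_names)),
                     paste0(path, ".regions.yaml"))
  }
  invisible(path)
}

# ---- MSH 4.1 --------------------------------------------------------------

write_msh41 <- function(mesh, path) {
  d <- mesh$dim
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(c(...), con)
  w("$MeshFormat", "4.1 0 8", "$EndMeshFormat")
  ids <- as.integer(names(mesh$region_names))
  w("$PhysicalNames", as.character(length(ids) + 1L))
  for (k in seq_along(ids)) {
    w(sprintf("%d %d \"%s\"", d - 1L, ids[k], mesh$region_names[k]))
  }
  vol_tag <- max(ids) + 1L
  w(sprintf("%d %d \"domain\"", d, vol_tag), "$EndPhysicalNames")
  # entities: one (d-1)-dim entity per region, one d-dim entity
  nsurf <- length(ids)
  bb <- apply(mesh$vertices, 2, range)
  bstr <- paste(c(bb[1, ], if (d == 2L) 0, bb[2, ], if (d == 2L) 0),
                collapse = " ")
  w("$Entities",
    paste(0L, if (d == 3L) 0L else nsurf, if (d == 3L) nsurf else 1L,
          if (d == 3L) 1L else 0L))
  for (k in seq_along(ids)) {
    w(sprintf("%d %s 1 %d 0", ids[k], bstr, ids[k]))
  }
  w(sprintf("%d %s 1 %d 0", vol_tag, bstr, vol_tag))
  w("$EndEntities")
  nv <- nrow(mesh$vertices)
  w("$Nodes", sprintf("1 %d 1 %d", nv, nv),
    sprintf("%d %d 0 %d", d, vol_tag, nv),
    as.character(seq_len(nv)))
  coords <- cbind(mesh$vertices, if (d == 2L) 0)
  w(apply(coords, 1, function(r) paste(format(r, digits = 17), collapse = " ")))
  w("$EndNodes")
  nb <- nrow(mesh$boundary_facets)
  nc <- nrow(mesh$cells)
  ftype <- if (d == 2L) 1L else 2L   # line / triangle
  ctype <- if (d == 2L) 2L else 4L   # triangle / tetrahedron
  w("$Elements", sprintf("%d %d 1 %d", nsurf + 1L, nb + nc, nb + nc))
  eid <- 0L
  for (k in seq_along(ids)) {
    sel <- which(mesh$facet_tags == ids[k])
    w(sprintf("%d %d %d %d", d - 1L, ids[k], ftype, length(sel)))
    if (length(sel)) {
      rows <- cbind(eid + seq_along(sel),
                    mesh$boundary_facets[sel, , drop = FALSE])
      w(apply(rows, 1, paste, collapse = " "))
      eid <- eid + length(sel)
    }
  }
  w(sprintf("%d %d %d %d", d, vol_tag, ctype, nc))
  rows <- cbind(eid + seq_len(nc), mesh$cells)
  w(apply(rows, 1, paste, collapse = " "))
  w("$EndElements")
  invisible(path)
}

# minimal MSH 4.1 ASCII reader (entity blocks as written above or by gmsh)
read_msh41 <- function(path) {
  lines <- readLines(path)
  sec <- function(name) {
    i0 <- match(paste0("$", name), lines)
    i1 <- match(paste0("$End", name), lines)
    if (is.na(i0) || is.na(i1)) return(NULL)
    lines[(i0 + 1L):(i1 - 1L)]
  }
  fmt <- sec("MeshFormat")
  if (is.null(fmt) || !startsWith(fmt[1], "4.1")) {
    stop("unsupported MSH version (need 4.1 ASCII)")
  }
  num <- function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]])
  # entity -> physical tag maps per dimension
  ent <- sec("Entities")
  phys <- list()   # phys[[dim+1]][entity] = physical tag
  if (!is.null(ent)) {
    cnt <- num(ent[1])
    row <- 2L
    for (dd in 0:3) {
      n <- cnt[dd + 1]
      if (n == 0) next
      m <- new.env()
      for (k in seq_len(n)) {
        v <- num(ent[row]); row <- row + 1L
        # tag, bbox (6 floats for dim>0, 3 for points), numPhys, phys...
        nbox <- if (dd == 0L) 3L else 6L
        nph <- v[nbox + 2L]
        if (!is.na(nph) && nph >= 1) {
          assign(as.character(as.integer(v[1])),
                 as.integer(v[nbox + 3L]), envir = m)
        }
      }
      phys[[dd + 1L]] <- m
    }
  }
  nd <- sec("Nodes")
  hd <- num(nd[1])
  nblocks <- hd[1]
  row <- 2L
  ids <- integer(0); coords <- NULL
  for (b in seq_len(nblocks)) {
    bh <- num(nd[row]); row <- row + 1L
    nn <- bh[4]
    if (nn > 0) {
      ids <- c(ids, as.integer(nd[row:(row + nn - 1L)]))
      row <- row + nn
      cc <- t(vapply(nd[row:(row + nn - 1L)], num, numeric(3), USE.NAMES = FALSE))
      coords <- rbind(coords, cc)
      row <- row + nn
    }
  }
  remap <- integer(max(ids)); remap[ids] <- seq_along(ids)
  el <- sec("Elements")
  hd <- num(el[1])
  row <- 2L
  tets <- NULL; tris <- NULL; tri_tags <- integer(0)
  lins <- NULL; lin_tags <- integer(0)
  for (b in seq_len(hd[1])) {
    bh <- num(el[row]); row <- row + 1L
    edim <- bh[1]; etag <- as.integer(bh[2]); etype <- bh[3]; ne <- bh[4]
    if (ne == 0) next
    dat <- t(vapply(el[row:(row + ne - 1L)], num,
                    numeric(length(num(el[row]))), USE.NAMES = FALSE))
    row <- row + ne
    conn <- matrix(remap[as.integer(dat[, -1L, drop = FALSE])], nrow = ne)
    ptag <- etag
    if (length(phys) >= edim + 1L && !is.null(phys[[edim + 1L]])) {
      hit <- mget(as.character(etag), envir = phys[[edim + 1L]],
                  ifnotfound = list(NULL))[[1]]
      if (!is.null(hit)) ptag <- hit
    }
    if (etype == 4) {
      tets <- rbind(tets, conn)
    } else if (etype == 2) {
      tris <- rbind(tris, conn); tri_tags <- c(tri_tags, rep(ptag, ne))
    } else if (etype == 1) {
      lins <- rbind(lins, conn); lin_tags <- c(lin_tags, rep(ptag, ne))
    }
  }
  if (!is.null(tets)) {          # 3D mesh: triangles are tagged facets
    cells <- tets; facets <- tris; tags <- tri_tags; dim_mesh <- 3L
  } else if (!is.null(tris)) {   # 2D mesh: lines are tagged facets
    cells <- tris; facets <- lins; tags <- lin_tags; dim_mesh <- 2L
  } else stop("no volume cells found in '", path, "'")
  vertices <- coords[, seq_len(dim_mesh), drop = FALSE]
  list(vertices = vertices, cells = cells, facets = facets, tags = tags)
}

# ---- XDMF (XML, inline ASCII data) ---------------------------------------

write_xdmf <- function(mesh, path) {
  d <- mesh$dim
  topo <- if (d == 2L) "Triangle" else "Tetrahedron"
  ftopo <- if (d == 2L) "Polyline" else "Triangle"
  geom <- if (d == 2L) "XY" else "XYZ"
  fmt_block <- function(m) {
    paste(apply(m, 1, paste, collapse = " "), collapse = "\n")
  }
  cells0 <- mesh$cells - 1L
  facets0 <- mesh$boundary_facets - 1L
  npl <- if (d == 2L) ' NodesPerElement="2"' else ""
  xml <- paste0(
    '<?xml version="1.0"?>\n<Xdmf Version="3.0">\n <Domain>\n',
    '  <Grid Name="mesh">\n',
    sprintf('   <Topology TopologyType="%s" NumberOfElements="%d">\n', topo,
            nrow(cells0)),
    sprintf('    <DataItem Dimensions="%d %d" Format="XML">\n', nrow(cells0),
            ncol(cells0)),
    fmt_block(cells0), "\n    </DataItem>\n   </Topology>\n",
    sprintf('   <Geometry GeometryType="%s">\n', geom),
    sprintf('    <DataItem Dimensions="%d %d" Format="XML">\n',
            nrow(mesh$vertices), d),
    fmt_block(signif(mesh$vertices, 17)), "\n    </DataItem>\n   </Geometry>\n",
    "  </Grid>\n",
    '  <Grid Name="facet_tags">\n',
    sprintf('   <Topology TopologyType="%s"%s NumberOfElements="%d">\n',
            ftopo, npl, nrow(facets0)),
    sprintf('    <DataItem Dimensions="%d %d" Format="XML">\n', nrow(facets0),
            ncol(facets0)),
    fmt_block(facets0), "\n    </DataItem>\n   </Topology>\n",
    sprintf('   <Geometry Reference="XML">/Xdmf/Domain/Grid[@Name=&quot;mesh&quot;]/Geometry</Geometry>\n'),
    '   <Attribute Name="tags" Center="Cell">\n',
    sprintf('    <DataItem Dimensions="%d" Format="XML">\n', nrow(facets0)),
    paste(mesh$facet_tags, collapse = " "),
    "\n    </DataItem>\n   </Attribute>\n  </Grid>\n </Domain>\n</Xdmf>\n")
  writeLines(xml, path)
  invisible(path)
}

read_xdmf <- function(path) {
  doc <- xml2::read_xml(path)
  grids <- xml2::xml_find_all(doc, ".//Grid")
  if (!length(grids)) stop("no <Grid> in XDMF file")
  parse_item <- function(node) {
    txt <- xml2::xml_text(node)
    scan(text = txt, quiet = TRUE)
  }
  mesh_grid <- grids[[1]]
  topo <- xml2::xml_find_first(mesh_grid, "./Topology")
  geom <- xml2::xml_find_first(mesh_grid, "./Geometry")
  gdim <- as.integer(strsplit(xml2::xml_attr(
    xml2::xml_find_first(geom, "./DataItem"), "Dimensions"), "\\s+")[[1]])
  verts <- matrix(parse_item(xml2::xml_find_first(geom, "./DataItem")),
                  nrow = gdim[1], byrow = TRUE)
  cdim <- as.integer(strsplit(xml2::xml_attr(
    xml2::xml_find_first(topo, "./DataItem"), "Dimensions"), "\\s+")[[1]])
  cells <- matrix(as.integer(parse_item(xml2::xml_find_first(topo, "./DataItem"))),
                  nrow = cdim[1], byrow = TRUE) + 1L
  facets <- NULL; tags <- NULL
  if (length(grids) >= 2L) {
    fg <- grids[[2]]
    ft <- xml2::xml_find_first(fg, "./Topology")
    fdim <- as.integer(strsplit(xml2::xml_attr(
      xml2::xml_find_first(ft, "./DataItem"), "Dimensions"), "\\s+")[[1]])
    facets <- matrix(as.integer(parse_item(xml2::xml_find_first(ft, "./DataItem"))),
                     nrow = fdim[1], byrow = TRUE) + 1L
    att <- xml2::xml_find_first(fg, "./Attribute/DataItem")
    if (!inherits(att, "xml_missing")) {
      tags <- as.integer(parse_item(att))
    }
  }
  list(vertices = verts, cells = cells, facets = facets, tags = tags)
}

# ---- VTU ------------------------------------------------------------------

#' Export a mesh (optionally with nodal fields) to ASCII VTU
#'
#' @param mesh a `tagged_mesh`.
#' @param path output .vtu path.
#' @param point_data named list of per-vertex vectors/matrices.
#' @export
write_vtu <- function(mesh, path, point_data = list()) {
  d <- mesh$dim
  nv <- nrow(mesh$vertices); nc <- nrow(mesh$cells)
  coords <- cbind(mesh$vertices, if (d == 2L) 0)
  ctype <- if (d == 2L) 5L else 10L
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(c(...), con)
  w('<?xml version="1.0"?>',
    '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">',
    ' <UnstructuredGrid>',
    sprintf('  <Piece NumberOfPoints="%d" NumberOfCells="%d">', nv, nc),
    '   <Points>',
    '    <DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  w(apply(coords, 1, paste, collapse = " "))
  w('    </DataArray>', '   </Points>', '   <Cells>',
    '    <DataArray type="Int32" Name="connectivity" format="ascii">')
  w(apply(mesh$cells - 1L, 1, paste, collapse = " "))
  w('    </DataArray>',
    '    <DataArray type="Int32" Name="offsets" format="ascii">',
    paste(seq_len(nc) * (d + 1L), collapse = " "),
    '    </DataArray>',
    '    <DataArray type="UInt8" Name="types" format="ascii">',
    paste(rep(ctype, nc), collapse = " "),
    '    </DataArray>', '   </Cells>')
  if (length(point_data)) {
    w('   <PointData>')
    for (nm in names(point_data)) {
      v <- as.matrix(point_data[[nm]])
      if (nrow(v) != nv) stop("point_data '", nm, "' has wrong length")
      if (ncol(v) == 2L) v <- cbind(v, 0)
      w(sprintf('    <DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">',
                nm, ncol(v)))
      w(apply(v, 1, paste, collapse = " "))
      w('    </DataArray>')
    }
    w('   </PointData>')
  }
  w('  </Piece>', ' </UnstructuredGrid>', '</VTKFile>')
  invisible(path)
}

#' Export a WSS field to CSV (facet id, centroid, nodal magnitudes)
#'
#' @param wf a `wss_field`.
#' @param path output .csv path.
#' @export
write_wss_csv <- function(wf, path) {
  mesh <- wf$mesh
  cen <- mesh$boundary_centroid[wf$facet_sel, , drop = FALSE]
  mag <- sqrt(apply(wf$facet_vals^2, c(1, 2), sum))
  df <- data.frame(facet = wf$facet_sel, cen)
  names(df) <- c("facet", paste0("x", seq_len(mesh$dim)))
  df$tag <- mesh$facet_tags[wf$facet_sel]
  for (k in seq_len(ncol(mag))) df[[paste0("mag_node", k)]] <- mag[, k]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
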