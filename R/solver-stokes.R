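# Monolithic Stokes solver: mixed P2/P1 or stabilized P1/P1 discretizations,
# strong or non-symmetric Nitsche Dirichlet enforcement, CIP stabilization,
# direct sparse factorization.

# expand a scalar sparse matrix into the (a,b) component block of the
# node-major interleaved vector system
vector_block <- function(S, a, b, d) {
  T <- methods::as(S, "TsparseMatrix")
  Matrix::sparseMatrix(i = d * T@i + a, j = d * T@j + b, x = T@x,
                       dims = c(nrow(S) * d, ncol(S) * d))
}

# scalar-matrix columns mapped into vector columns of component b
vector_cols <- function(S, b, d) {
  T <- methods::as(S, "TsparseMatrix")
  Matrix::sparseMatrix(i = T@i + 1L, j = d * T@j + b, x = T@x,
                       dims = c(nrow(S), ncol(S) * d))
}

# Nitsche boundary contributions over the selected facets.
# Returns sparse blocks (vector x vector, vector x pressure, pressure x
# vector) and the right-hand-side vectors carrying v_bc.
assemble_nitsche <- function(space_v, space_p, facet_sel, geo, nu, beta,
                             stress_form, vbc_fun, qdeg) {
  d <- space_v$dim
  bbv <- boundary_basis(space_v, facet_sel, qdeg, geo)
  bbp <- boundary_basis(space_p, facet_sel, qdeg, geo)
  nf <- bbv$nf; nq <- bbv$nq
  qsum <- function(x) rowSums(matrix(x, nf, nq))
  w <- as.vector(bbv$w)
  nrm <- rep_facet(bbv$normal, nq)
  hf <- rep.int(bbv$h, nq)
  vbc <- as.matrix(vbc_fun(bbv$xq))
  nbv <- bbv$nb; nbp <- bbp$nb
  ndv <- space_v$ndof * d
  trVV <- trip_new(); trVP <- trip_new(); trQV <- trip_new()
  rhs_v <- numeric(ndv); rhs_p <- numeric(space_p$ndof)
  gn <- lapply(seq_len(nbv), function(i) {
    acc <- 0
    for (b in seq_len(d)) acc <- acc + bbv$gphys[[i]][, b] * nrm[, b]
    acc
  })
  for (i in seq_len(nbv)) {
    for (j in seq_len(nbv)) {
      # component-diagonal pieces: -consistency + transpose + penalty
      diagv <- qsum(w * (nu * (-bbv$val[i, ] * gn[[j]] +
                                 bbv$val[j, ] * gn[[i]]) +
                           beta * nu / hf * bbv$val[i, ] * bbv$val[j, ]))
      for (a in seq_len(d)) {
        trVV <- trip_add(trVV, vdof(bbv$dofs[, i], a, d),
                         vdof(bbv$dofs[, j], a, d), diagv)
      }
      if (stress_form == "symmetric") {
        for (a in seq_len(d)) for (b in seq_len(d)) {
          val <- qsum(w * nu * (-bbv$val[i, ] * bbv$gphys[[j]][, a] * nrm[, b] +
                                  bbv$val[j, ] * bbv$gphys[[i]][, b] * nrm[, a]))
          trVV <- trip_add(trVV, vdof(bbv$dofs[, i], a, d),
                           vdof(bbv$dofs[, j], b, d), val)
        }
      }
    }
    # rhs from v_bc (transpose-consistency + penalty)
    for (a in seq_len(d)) {
      r <- w * (nu * gn[[i]] + beta * nu / hf * bbv$val[i, ]) * vbc[, a]
      if (stress_form == "symmetric") {
        for (b in seq_len(d)) {
          r <- r + w * nu * bbv$gphys[[i]][, b] * nrm[, a] * vbc[, b]
        }
      }
      rhs_v <- rhs_v + vec_accumulate(vdof(bbv$dofs[, i], a, d), qsum(r), ndv)
    }
  }
  for (i in seq_len(nbp)) {
    for (j in seq_len(nbv)) {
      for (a in seq_len(d)) {
        # pressure into momentum: + int p n_a phi_i  (test j? see below)
        val_vp <- qsum(w * bbp$val[i, ] * nrm[, a] * bbv$val[j, ])
        trVP <- trip_add(trVP, vdof(bbv$dofs[, j], a, d), bbp$dofs[, i], val_vp)
        # q against v: - int q n_a phi_j
        trQV <- trip_add(trQV, bbp$dofs[, i], vdof(bbv$dofs[, j], a, d), -val_vp)
      }
    }
    nv_bc <- rowSums(nrm * vbc)
    rhs_p <- rhs_p - vec_accumulate(bbp$dofs[, i], qsum(w * bbp$val[i, ] * nv_bc),
                                    space_p$ndof)
  }
  list(VV = trip_mat(trVV, ndv, ndv),
       VP = trip_mat(trVP, ndv, space_p$ndof),
       QV = trip_mat(trQV, space_p$ndof, ndv),
       rhs_v = rhs_v, rhs_p = rhs_p)
}

# CIP stabilization matrices for the P1/P1 pair (Stokes flavour):
# S_p penalizes jumps of n.grad p, S_v jumps of div v, both weighted by
# 1/2 * gamma * h_K^(s+1) per adjacent cell with the per-cell s-rule.
assemble_cip <- function(space_v, space_p, geo, weights, nu) {
  mesh <- space_v$mesh
  ifg <- interior_facet_geometry(mesh)
  sfun <- function(h) ifelse(nu >= h, 2, 1)
  wgt <- 0.5 * (ifg$h1^(sfun(ifg$h1) + 1) + ifg$h2^(sfun(ifg$h2) + 1)) *
    ifg$measure
  Gp <- facet_jump_matrix(space_p, geo, ifg, "ngradp")
  Gv <- facet_jump_matrix(space_v, geo, ifg, "div")
  Wp <- weights$gamma_p * wgt
  Wv <- weights$gamma_v * wgt
  list(Sp = Matrix::crossprod(Gp, Wp * Gp),
       Sv = Matrix::crossprod(Gv, Wv * Gv),
       Gp = Gp, Gv = Gv, Wp = Wp, Wv = Wv, style = "cip")
}

# Interior-penalty stabilization (Navier-Stokes flavour, h^2-scaled full
# gradient jumps plus a convective (v.n)^2-weighted term).
assemble_interior_penalty <- function(space_v, space_p, geo, weights,
                                      vn2_int = NULL) {
  mesh <- space_v$mesh
  d <- mesh$dim
  ifg <- interior_facet_geometry(mesh)
  h2 <- ifg$h1^2 + ifg$h2^2
  Gb <- facet_jump_matrix(space_p, geo, ifg, "gradb")  # P1 scalar grads
  base <- h2 * ifg$measure
  Sp_s <- 0; Sv_s <- 0
  for (b in seq_len(d)) {
    Sp_s <- Sp_s + Matrix::crossprod(Gb[[b]], (weights$alpha_p * base) * Gb[[b]])
    wv <- weights$alpha_v * base
    if (!is.null(vn2_int)) wv <- wv + weights$alpha_i * h2 * vn2_int
    Sv_s <- Sv_s + Matrix::crossprod(Gb[[b]], wv * Gb[[b]])
  }
  Sv <- 0
  for (a in seq_len(d)) Sv <- Sv + vector_block(Sv_s, a, a, d)
  list(Sp = Sp_s, Sv = Sv, Gb = Gb, ifg = ifg, style = "interior_penalty")
}

# facet integrals of (v.n)^2 over interior facets for the alpha_i term
interior_vn2 <- function(space_v, vcoefs, ifg) {
  mesh <- space_v$mesh
  d <- mesh$dim
  f <- mesh$interior_facets
  rule <- simplex_quadrature(d - 1L, 2L)
  refmeas <- if (d == 2L) 1 else 0.5
  nq <- nrow(rule$points)
  acc <- 0
  for (q in seq_len(nq)) {
    if (d == 2L) {
      t <- rule$points[q, 1]; lam <- cbind(1 - t, t)
    } else {
      s <- rule$points[q, 1]; t <- rule$points[q, 2]
      lam <- cbind(1 - s - t, s, t)
    }
    vn <- 0
    for (a in seq_len(d)) {
      va <- 0
      for (k in seq_len(ncol(f))) va <- va + lam[, k] * vcoefs[f[, k], a]
      vn <- vn + va * ifg$normal[, a]
    }
    acc <- acc + rule$weights[q] / refmeas * vn^2
  }
  acc * ifg$measure
}

# facets belonging to regions of a given enforcement kind
facets_of_kinds <- function(mesh, bcs, kinds) {
  tags <- names(bcs$regions)[vapply(bcs$regions, function(r) r$kind %in% kinds,
                                    TRUE)]
  if (!length(tags)) return(integer(0))
  which(mesh$facet_tags %in% resolve_tags(mesh, tags))
}

zero_fun <- function(d) function(x) matrix(0, nrow(x), d)

# strong velocity constraints: returns vector-dof indices and values
strong_constraints <- function(space_v, bcs) {
  mesh <- space_v$mesh
  d <- mesh$dim
  idx <- integer(0); val <- numeric(0)
  for (tag in names(bcs$regions)) {
    r <- bcs$regions[[tag]]
    if (r$kind == "dirichlet_strong") {
      sd <- boundary_scalar_dofs(space_v, tag)
      vb <- as.matrix(r$value(space_v$nodes[sd, , drop = FALSE]))
      for (a in seq_len(d)) {
        idx <- c(idx, vdof(sd, a, d)); val <- c(val, vb[, a])
      }
    } else if (r$kind == "zero_tangential_velocity") {
      sd <- boundary_scalar_dofs(space_v, tag)
      for (a in seq_len(d - 1L)) {
        idx <- c(idx, vdof(sd, a, d)); val <- c(val, numeric(length(sd)))
      }
    }
  }
  # later entries win on duplicates (e.g. wall no-slip over inlet profile):
  # keep the FIRST occurrence; callers order regions wall-last if they want
  # wall values to dominate shared dofs.  We keep it simple: last wins.
  if (length(idx)) {
    keep <- !duplicated(idx, fromLast = TRUE)
    idx <- idx[keep]; val <- val[keep]
  }
  list(idx = idx, val = val)
}

# replace rows of M by identity and rhs by the constrained values
apply_strong <- function(M, rhs, idx, val) {
  if (!length(idx)) return(list(M = M, rhs = rhs))
  n <- nrow(M)
  keepdiag <- rep(1, n); keepdiag[idx] <- 0
  D <- Matrix::Diagonal(n, keepdiag)
  M <- D %*% M + Matrix::sparseMatrix(i = idx, j = idx, x = rep(1, length(idx)),
                                      dims = dim(M))
  rhs[idx] <- val
  list(M = M, rhs = rhs)
}

#' Solve the stationary Stokes problem
#'
#' Discrete weak solution with the configured element pair, stress form,
#' stabilization and Dirichlet enforcement.  With Dirichlet conditions on the
#' whole boundary the pressure is gauged to zero mean via a scalar Lagrange
#' multiplier.
#'
#' @param mesh a `tagged_mesh`.
#' @param props a [fluid_properties()].
#' @param config a [discretization_config()].
#' @param bcs a [bc_spec()]; every tagged region must appear.
#' @return a `flow_solution` (velocity/pressure coefficients plus metadata).
#' @export
solve_stokes <- function(mesh, props, config, bcs) {
  sys <- build_stokes_system(mesh, props, config, bcs)
  rhs <- sys$rhs
  M <- sys$M
  ap <- apply_strong(M, rhs, sys$strong$idx, sys$strong$val)
  sol <- as.numeric(sparse_solve(ap$M, ap$rhs))
  finish_solution(sys, sol, mesh, props, config, bcs)
}

finish_solution <- function(sys, sol, mesh, props, config, bcs) {
  d <- mesh$dim
  nvd <- sys$space_v$ndof * d
  v <- matrix(sol[seq_len(nvd)], ncol = d, byrow = TRUE)
  p <- sol[nvd + seq_len(sys$space_p$ndof)]
  structure(list(mesh = mesh, space_v = sys$space_v, space_p = sys$space_p,
                 v = v, p = p, props = props, config = config, bcs = bcs,
                 stab = sys$stab, geo = sys$geo, gauge = sys$gauge,
                 nitsche_facets = sys$nitsche_facets, qdeg_facet = sys$qdeg_facet,
                 problem = "stokes", dudt = NULL, ip_vn2 = NULL),
            class = "flow_solution")
}

#' @export
print.flow_solution <- function(x, ...) {
  cat(sprintf("<flow_solution> %s, %s enforcement, %d velocity + %d pressure dofs\n",
              x$config$element_pair, x$config$enforcement,
              nrow(x$v) * x$mesh$dim, length(x$p)))
  invisible(x)
}

# Assemble the (unconstrained) Stokes operator and right-hand side.
build_stokes_system <- function(mesh, props, config, bcs) {
  d <- mesh$dim
  nu <- props$nu
  degv <- element_degree(config$element_pair)
  space_v <- fe_space(mesh, degv)
  space_p <- fe_space(mesh, 1L)
  geo <- cell_geometry(mesh)
  qdeg_facet <- 2L * degv + 1L

  Ks <- assemble_scalar_stiffness(space_v, geo)
  A <- 0
  for (a in seq_len(d)) A <- A + vector_block(nu * Ks, a, a, d)
  if (config$stress_form == "symmetric") {
    for (a in seq_len(d)) for (b in seq_len(d)) {
      A <- A + vector_block(nu * assemble_grad_cross(space_v, geo, a, b), a, b, d)
    }
  }
  Bl <- assemble_div(space_v, space_p, geo)
  B <- 0
  for (a in seq_len(d)) B <- B + vector_cols(Bl[[a]], a, d)

  stab <- NULL
  Sp <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                             dims = c(space_p$ndof, space_p$ndof))
  if (config$element_pair == "P1P1_stabilized") {
    if (config$cip_style == "cip") {
      stab <- assemble_cip(space_v, space_p, geo, config$stabilization, nu)
    } else {
      stab <- assemble_interior_penalty(space_v, space_p, geo,
                                        config$stabilization)
    }
    A <- A + stab$Sv
    Sp <- stab$Sp
  }

  ndv <- space_v$ndof * d
  rhs_v <- numeric(ndv)
  rhs_p <- numeric(space_p$ndof)
  if (!is.null(bcs$f)) rhs_v <- rhs_v + assemble_source(space_v, geo, bcs$f)

  nitsche_facets <- facets_of_kinds(mesh, bcs, "dirichlet_nitsche")
  NVP <- NULL
  if (length(nitsche_facets)) {
    if (config$enforcement != "nitsche") {
      stop("bc_spec contains dirichlet_nitsche regions but enforcement is strong")
    }
    # assemble per region so each can carry its own value function
    for (tag in names(bcs$regions)) {
      r <- bcs$regions[[tag]]
      if (r$kind != "dirichlet_nitsche") next
      fs <- which(mesh$facet_tags == resolve_tag(mesh, tag))
      vbc <- if (is.null(r$value)) zero_fun(d) else r$value
      nit <- assemble_nitsche(space_v, space_p, fs, geo, nu, config$beta,
                              config$stress_form, vbc, qdeg_facet)
      A <- A + nit$VV
      NVP <- if (is.null(NVP)) nit$VP else NVP + nit$VP
      B <- B + nit$QV
      rhs_v <- rhs_v + nit$rhs_v
      rhs_p <- rhs_p + nit$rhs_p
    }
  }
  # traction (Neumann) data
  for (tag in names(bcs$regions)) {
    r <- bcs$regions[[tag]]
    if (r$kind == "traction" && !is.null(r$value)) {
      fs <- which(mesh$facet_tags == resolve_tag(mesh, tag))
      rhs_v <- rhs_v + assemble_boundary_load(space_v, fs, geo, r$value,
                                              qdeg_facet)
    }
  }

  # momentum pressure block: -int p div w  (+ Nitsche p n.w)
  PB <- -Matrix::t(Bl_to_vec(Bl, d))
  if (!is.null(NVP)) PB <- PB + NVP

  gauge <- !any(vapply(bcs$regions, function(r)
    r$kind %in% c("do_nothing", "traction", "zero_tangential_velocity"), TRUE))
  spz <- function(nr, nc) {
    Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                         dims = c(nr, nc))
  }
  if (gauge) {
    mvec <- assemble_unit_load(space_p, geo)
    mcol <- Matrix::sparseMatrix(i = seq_along(mvec), j = rep(1L, length(mvec)),
                                 x = mvec, dims = c(length(mvec), 1L))
    M <- rbind(
      cbind(A, PB, spz(ndv, 1L)),
      cbind(B, Sp, mcol),
      cbind(spz(1L, ndv), Matrix::t(mcol), spz(1L, 1L))
    )
    rhs <- c(rhs_v, rhs_p, 0)
  } else {
    M <- rbind(cbind(A, PB), cbind(B, Sp))
    rhs <- c(rhs_v, rhs_p)
  }
  strong <- strong_constraints(space_v, bcs)
  list(M = methods::as(M, "CsparseMatrix"), rhs = rhs, A = A, B = B, PB = PB,
       Sp = Sp, space_v = space_v,
       space_p = space_p, geo = geo, stab = stab, gauge = gauge,
       strong = strong, nitsche_facets = nitsche_facets,
       qdeg_facet = qdeg_facet, ndv = ndv)
}

# stack the divergence component matrices into vector columns
Bl_to_vec <- function(Bl, d) {
  B <- 0
  for (a in seq_len(d)) B <- B + vector_cols(Bl[[a]], a, d)
  B
}

# boundary load int g . phi over selected facets
assemble_boundary_load <- function(space_v, facet_sel, geo, gfun, qdeg) {
  d <- space_v$dim
  bb <- boundary_basis(space_v, facet_sel, qdeg, geo)
  g <- as.matrix(gfun(bb$xq))
  w <- as.vector(bb$w)
  qsum <- function(x) rowSums(matrix(x, bb$nf, bb$nq))
  rhs <- numeric(space_v$ndof * d)
  for (i in seq_len(bb$nb)) for (a in seq_len(d)) {
    rhs <- rhs + vec_accumulate(vdof(bb$dofs[, i], a, d),
                                qsum(w * bb$val[i, ] * g[, a]),
                                space_v$ndof * d)
  }
  rhs
}
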