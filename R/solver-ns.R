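# Steady-state Navier-Stokes by BDF2 pseudo-time marching: start from rest,
# ramp the inflow linearly over the configured duration, advance with
# variable-step BDF2 and Newton's method, grow the step when Newton is easy
# and shrink it on divergence, and stop when the L2 norm of the discrete
# time derivative falls below the steady-state tolerance.

# convection blocks linearized at ubar:
#  C1 (component-diagonal): int phi_i (grad phi_j . ubar)
#  C2 (coupled):            int phi_i phi_j d_b ubar_a
#  resid:                   int (grad u) u . (phi_i e_a) at u = ubar
assemble_convection <- function(space_v, geo, ubar, rho) {
  d <- space_v$dim
  nb <- space_v$nb
  deg <- 3L * space_v$degree - 1L
  quad <- simplex_quadrature(d, deg)
  rb <- ref_basis(d, space_v$degree, quad$points)
  fu <- fe_function(space_v, ubar)
  ev <- eval_on_cells(fu, quad, geo, gradients = TRUE)
  tr1 <- trip_new(); tr2 <- trip_new()
  resid <- numeric(space_v$ndof * d)
  for (q in seq_len(nrow(quad$points))) {
    wq <- quad$weights[q] * geo$detJ * rho
    pg <- phys_grads_at(geo, rb$grad[, , q, drop = TRUE], nb, d)
    uq <- ev$vals[[q]]
    gq <- ev$grads[[q]]
    # conv_a = (grad u) u |_a = sum_b d_b u_a u_b
    conv <- matrix(0, length(wq), d)
    for (a in seq_len(d)) {
      acc <- 0
      for (b in seq_len(d)) acc <- acc + gq[[a]][, b] * uq[, b]
      conv[, a] <- acc
    }
    for (i in seq_len(nb)) {
      vi <- rb$val[i, q]
      for (j in seq_len(nb)) {
        gradj_u <- 0
        for (b in seq_len(d)) gradj_u <- gradj_u + pg[[j]][, b] * uq[, b]
        val1 <- wq * vi * gradj_u
        for (a in seq_len(d)) {
          tr1 <- trip_add(tr1, vdof(space_v$cell_dofs[, i], a, d),
                          vdof(space_v$cell_dofs[, j], a, d), val1)
        }
        for (a in seq_len(d)) for (b in seq_len(d)) {
          tr2 <- trip_add(tr2, vdof(space_v$cell_dofs[, i], a, d),
                          vdof(space_v$cell_dofs[, j], b, d),
                          wq * vi * rb$val[j, q] * gq[[a]][, b])
        }
      }
      for (a in seq_len(d)) {
        resid <- resid + vec_accumulate(vdof(space_v$cell_dofs[, i], a, d),
                                        wq * vi * conv[, a],
                                        space_v$ndof * d)
      }
    }
  }
  ndv <- space_v$ndof * d
  list(C1 = trip_mat(tr1, ndv, ndv), C2 = trip_mat(tr2, ndv, ndv),
       resid = resid)
}

#' Solve steady Navier-Stokes by BDF2 pseudo-time marching
#'
#' Starts from rest, ramps the Dirichlet inflow linearly over
#' `config$pseudo_time$ramp_duration`, and marches with variable-step BDF2
#' and Newton iterations until the L2 norm of the discrete time derivative
#' drops below `steady_tol` (or `end_time` is reached).  The time step grows
#' by 1.5x after fast Newton convergence and halves on divergence, clipped to
#' `[dt_min, dt_max]`.
#'
#' @inheritParams solve_stokes
#' @param verbose print per-step diagnostics.
#' @return a `flow_solution` with `problem = "navier_stokes"`, the terminal
#'   BDF2 time-derivative coefficients in `$dudt`, and the dt history in
#'   `$history`.
#' @export
solve_navier_stokes_steady <- function(mesh, props, config, bcs,
                                       verbose = FALSE) {
  if (config$element_pair == "P1P1_stabilized" &&
      config$cip_style != "interior_penalty") {
    # the Navier-Stokes runs use the interior-penalty stabilization
    config$cip_style <- "interior_penalty"
  }
  sys <- build_stokes_system(mesh, props, config, bcs)
  d <- mesh$dim
  ndv <- sys$ndv
  npd <- sys$space_p$ndof
  ntot <- length(sys$rhs)
  rho <- props$rho
  pt <- config$pseudo_time

  Ms <- assemble_scalar_mass(sys$space_v, sys$geo)
  Mv <- 0
  for (a in seq_len(d)) Mv <- Mv + vector_block(Ms, a, a, d)

  u <- numeric(ndv); u1 <- numeric(ndv); u2 <- numeric(ndv)
  p <- numeric(npd)
  t <- 0; dt <- pt$dt_min; dt_prev <- NA
  history <- list()
  step <- 0L
  dudt <- NULL
  vn2 <- NULL
  ifg <- if (!is.null(sys$stab) && sys$stab$style == "interior_penalty") {
    sys$stab$ifg
  } else NULL

  strong_idx <- sys$strong$idx
  repeat {
    step <- step + 1L
    accepted <- FALSE
    while (!accepted) {
      tn <- t + dt
      ramp <- if (pt$ramp_duration > 0) min(tn / pt$ramp_duration, 1) else 1
      if (is.na(dt_prev)) {          # first step: backward Euler
        a0 <- 1 / dt; a1 <- -1 / dt; a2 <- 0
      } else {                       # variable-step BDF2
        r <- dt / dt_prev
        a0 <- (1 + 2 * r) / (dt * (1 + r))
        a1 <- -(1 + r) / dt
        a2 <- r^2 / (dt * (1 + r))
      }
      # interior-penalty convective weight, lagged at the previous state
      Sv_extra <- NULL
      if (!is.null(ifg)) {
        um <- matrix(u1, ncol = d, byrow = TRUE)
        vn2 <- interior_vn2(sys$space_v, um, ifg)
        al <- config$stabilization$alpha_i
        h2 <- ifg$h1^2 + ifg$h2^2
        Sv_s <- 0
        for (b in seq_len(d)) {
          Sv_s <- Sv_s + Matrix::crossprod(sys$stab$Gb[[b]],
                                           (al * h2 * vn2) * sys$stab$Gb[[b]])
        }
        Sv_extra <- 0
        for (a in seq_len(d)) Sv_extra <- Sv_extra + vector_block(Sv_s, a, a, d)
      }
      un <- u; pn <- p
      converged <- FALSE; diverged <- FALSE
      res0 <- NA
      for (newton in seq_len(12L)) {
        cv <- assemble_convection(sys$space_v, sys$geo,
                                  matrix(un, ncol = d, byrow = TRUE), rho)
        Avv <- sys$A + rho * a0 * Mv + cv$C1 + cv$C2
        if (!is.null(Sv_extra)) Avv <- Avv + Sv_extra
        # residual (momentum, continuity)
        Fm <- as.numeric(sys$A %*% un) + as.numeric(sys$PB %*% pn) +
          rho * as.numeric(Mv %*% (a0 * un + a1 * u1 + a2 * u2)) +
          cv$resid - ramp * sys$rhs[seq_len(ndv)]
        if (!is.null(Sv_extra)) Fm <- Fm + as.numeric(Sv_extra %*% un)
        Fc <- as.numeric(sys$B %*% un) + as.numeric(sys$Sp %*% pn) -
          ramp * sys$rhs[ndv + seq_len(npd)]
        Fv <- c(Fm, Fc)
        if (sys$gauge) Fv <- c(Fv, 0)
        if (length(strong_idx)) {
          Fv[strong_idx] <- un[strong_idx] - ramp * sys$strong$val
        }
        rn <- sqrt(sum(Fv^2))
        if (newton == 1L) res0 <- rn
        if (rn < 1e-10 || rn < 1e-8 * res0) { converged <- TRUE; break }
        if (rn > 1e3 * res0 || !is.finite(rn)) { diverged <- TRUE; break }
        J <- rbind(cbind(Avv, sys$PB), cbind(sys$B, sys$Sp))
        if (sys$gauge) {
          mcol <- Matrix::sparseMatrix(
            i = ndv + seq_len(npd), j = rep(1L, npd),
            x = assemble_unit_load(sys$space_p, sys$geo),
            dims = c(ndv + npd, 1L))
          J <- rbind(cbind(J, mcol),
                     cbind(Matrix::t(mcol), Matrix::sparseMatrix(
                       i = integer(0), j = integer(0), x = numeric(0),
                       dims = c(1L, 1L))))
        }
        apj <- apply_strong(J, -Fv, strong_idx, numeric(length(strong_idx)))
        delta <- as.numeric(sparse_solve(apj$M, apj$rhs))
        un <- un + delta[seq_len(ndv)]
        pn <- pn + delta[ndv + seq_len(npd)]
      }
      if (converged) {
        accepted <- TRUE
      } else {
        if (dt <= pt$dt_min * (1 + 1e-12)) {
          stop("Newton diverged at dt_min; cannot advance pseudo-time")
        }
        dt <- max(pt$dt_min, dt / 2)
      }
      if (accepted) {
        dudt_c <- a0 * un + a1 * u1 + a2 * u2
        dudt_norm <- sqrt(abs(sum(dudt_c * as.numeric(Mv %*% dudt_c))))
        history[[length(history) + 1L]] <-
          data.frame(step = step, t = tn, dt = dt, newton = newton,
                     dudt = dudt_norm)
        if (verbose) {
          message(sprintf("step %d: t=%.3g dt=%.3g newton=%d |du/dt|=%.3e",
                          step, tn, dt, newton, dudt_norm))
        }
        u2 <- u1; u1 <- un; u <- un; p <- pn
        dt_prev <- dt; t <- tn
        dudt <- dudt_c
        if (newton <= 4L) dt <- min(pt$dt_max, dt * 1.5)
        if ((ramp >= 1 && dudt_norm < pt$steady_tol) || t >= pt$end_time) {
          sol <- finish_solution(sys, c(u, p, if (sys$gauge) 0), mesh, props,
                                 config, bcs)
          sol$problem <- "navier_stokes"
          sol$dudt <- matrix(dudt, ncol = d, byrow = TRUE)
          sol$ip_vn2 <- vn2
          sol$history <- do.call(rbind, history)
          sol$steady <- dudt_norm < pt$steady_tol
          return(sol)
        }
      }
    }
  }
}
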