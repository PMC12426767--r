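# Linear solve dispatcher.  Primary path: Ruiz-equilibrated ILUT-BiCGSTAB
# (Eigen), which handles the saddle-point systems of this package in near
# linear time.  Fallbacks: statically pivoted sparse LU with iterative
# refinement, then partial-pivoted LU, then Matrix::solve when the compiled
# kernels are unavailable.

sparse_solve <- function(M, b) {
  M <- methods::as(M, "CsparseMatrix")
  b <- as.matrix(b)
  use_eigen <- tryCatch(wss_have_eigen(), error = function(e) FALSE)
  if (!use_eigen) {
    return(as.matrix(Matrix::solve(M, b)))
  }
  eq <- ruiz_equilibrate(M)
  bs <- eq$dl * b
  tol_ok <- function(sol) !is.null(sol) && attr(sol, "rel_resid") < 1e-10
  sol <- tryCatch(
    wss_bicgstab_ilut(nrow(eq$M), eq$M@p, eq$M@i, eq$M@x, bs,
                      droptol = 1e-4, fillfactor = 40,
                      tol = 1e-13, maxit = 4000),
    error = function(e) NULL)
  if (!tol_ok(sol)) {
    eps0 <- 1e-9
    for (thresh in c(0, 1e-2, 1)) {
      sol <- tryCatch(
        wss_sparse_lu_solve(nrow(eq$M), eq$M@p, eq$M@i, eq$M@x, bs,
                            thresh, eps0),
        error = function(e) NULL)
      if (tol_ok(sol)) break
    }
  }
  if (is.null(sol)) stop("linear solve failed (singular system?)")
  eq$dr * sol
}

# Ruiz equilibration (three sweeps, 2-norm variant): scales rows and columns
# towards comparable magnitude so that incomplete factorizations and static
# pivoting behave on systems whose blocks span many orders of magnitude.
ruiz_equilibrate <- function(M) {
  dl <- rep(1, nrow(M)); dr <- rep(1, ncol(M))
  Ms <- M
  for (k in 1:3) {
    rn <- sqrt(sqrt(Matrix::rowSums(Ms^2)))
    dlk <- 1 / pmax(rn, 1e-150)
    Ms <- Matrix::Diagonal(x = dlk) %*% Ms
    cn <- sqrt(sqrt(Matrix::colSums(Ms^2)))
    drk <- 1 / pmax(cn, 1e-150)
    Ms <- Ms %*% Matrix::Diagonal(x = drk)
    dl <- dl * dlk; dr <- dr * drk
  }
  list(M = methods::as(Ms, "CsparseMatrix"), dl = dl, dr = dr)
}
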