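// Direct sparse LU solve (Eigen SparseLU with COLAMD ordering) for the
// saddle-point systems assembled in R.  Compiled against the system Eigen
// headers when present; wss_have_eigen() lets the R side fall back to
// Matrix::solve otherwise.

#include <Rcpp.h>
#ifdef HAVE_EIGEN
#include <Eigen/Sparse>
#include <Eigen/SparseLU>
#endif

using namespace Rcpp;

// [[Rcpp::export]]
bool wss_have_eigen() {
#ifdef HAVE_EIGEN
  return true;
#else
  return false;
#endif
}

// Solve A x = b for a square CSC matrix given by (p, i, x) slots; b may have
// several columns.  pivot_thresh controls SparseLU threshold pivoting: 0
// keeps diagonal pivots (static pivoting, minimal fill -- the caller
// equilibrates and iteratively refines), 1 is full partial pivoting.
// [[Rcpp::export]]
NumericMatrix wss_sparse_lu_solve(int n, IntegerVector p, IntegerVector i,
                                  NumericVector x, NumericMatrix b,
                                  double pivot_thresh = 0.0,
                                  double diag_eps = 0.0) {
#ifdef HAVE_EIGEN
  Eigen::Map<const Eigen::SparseMatrix<double> > A(n, n, x.size(), p.begin(),
                                                   i.begin(), x.begin());
  Eigen::SparseMatrix<double> Ac(A);
  // statically pivoted LU needs nonzero diagonal pivots: perturb small
  // diagonal entries for the factorization only; residuals below use the
  // unperturbed matrix, so iterative refinement removes the perturbation.
  Eigen::SparseMatrix<double> Af(Ac);
  if (diag_eps > 0.0) {
    Eigen::SparseMatrix<double> E(n, n);
    std::vector<Eigen::Triplet<double> > tr;
    for (int c = 0; c < n; ++c) {
      double dv = Ac.coeff(c, c);
      if (std::abs(dv) < diag_eps) tr.push_back(
          Eigen::Triplet<double>(c, c, diag_eps));
    }
    E.setFromTriplets(tr.begin(), tr.end());
    Af = Ac + E;
  }
  Eigen::SparseLU<Eigen::SparseMatrix<double>, Eigen::COLAMDOrdering<int> > lu;
  lu.setPivotThreshold(pivot_thresh);
  lu.analyzePattern(Af);
  lu.factorize(Af);
  if (lu.info() != Eigen::Success) {
    stop("sparse LU factorization failed (singular system?)");
  }
  NumericMatrix out(n, b.ncol());
  double worst = 0.0;
  for (int k = 0; k < b.ncol(); ++k) {
    Eigen::Map<const Eigen::VectorXd> bk(&b(0, k), n);
    Eigen::VectorXd xk = lu.solve(bk);
    if (lu.info() != Eigen::Success) stop("sparse LU solve failed");
    // iterative refinement (static pivoting can lose a few digits)
    double bnorm = bk.cwiseAbs().maxCoeff();
    double rel = 1.0;
    for (int it = 0; it < 6; ++it) {
      Eigen::VectorXd r = bk - Ac * xk;
      rel = (bnorm > 0) ? r.cwiseAbs().maxCoeff() / bnorm
                        : r.cwiseAbs().maxCoeff();
      if (rel < 1e-12) break;
      Eigen::VectorXd dx = lu.solve(r);
      if (lu.info() != Eigen::Success) break;
      xk += dx;
    }
    if (rel > worst) worst = rel;
    std::copy(xk.data(), xk.data() + n, &out(0, k));
  }
  out.attr("rel_resid") = worst;
  return out;
#else
  stop("compiled without Eigen support");
#endif
}

#ifdef HAVE_EIGEN
#include <Eigen/IterativeLinearSolvers>
#endif

// ILUT-preconditioned BiCGSTAB on the (equilibrated) system.
// [[Rcpp::export]]
NumericMatrix wss_bicgstab_ilut(int n, IntegerVector p, IntegerVector i,
                                NumericVector x, NumericMatrix b,
                                double droptol = 1e-4, int fillfactor = 30,
                                double tol = 1e-12, int maxit = 2000) {
#ifdef HAVE_EIGEN
  Eigen::Map<const Eigen::SparseMatrix<double> > A(n, n, x.size(), p.begin(),
                                                   i.begin(), x.begin());
  Eigen::SparseMatrix<double> Ac(A);
  Eigen::BiCGSTAB<Eigen::SparseMatrix<double>,
                  Eigen::IncompleteLUT<double> > solver;
  solver.preconditioner().setDroptol(droptol);
  solver.preconditioner().setFillfactor(fillfactor);
  solver.setTolerance(tol);
  solver.setMaxIterations(maxit);
  solver.compute(Ac);
  if (solver.info() != Eigen::Success) stop("ILUT preconditioner failed");
  NumericMatrix out(n, b.ncol());
  double worst = 0.0;
  for (int k = 0; k < b.ncol(); ++k) {
    Eigen::Map<const Eigen::VectorXd> bk(&b(0, k), n);
    Eigen::VectorXd xk = solver.solve(bk);
    double bn = bk.cwiseAbs().maxCoeff();
    Eigen::VectorXd r = bk - Ac * xk;
    double rel = (bn > 0) ? r.cwiseAbs().maxCoeff() / bn : 0.0;
    if (rel > worst) worst = rel;
    std::copy(xk.data(), xk.data() + n, &out(0, k));
  }
  out.attr("rel_resid") = worst;
  out.attr("iterations") = (int)solver.iterations();
  return out;
#else
  stop("compiled without Eigen support");
#endif
}

#ifdef HAVE_EIGEN
#include <unsupported/Eigen/IterativeSolvers>
#endif

// ILUT-preconditioned restarted GMRES.
// [[Rcpp::export]]
NumericMatrix wss_gmres_ilut(int n, IntegerVector p, IntegerVector i,
                             NumericVector x, NumericMatrix b,
                             double droptol = 1e-4, int fillfactor = 30,
                             double tol = 1e-12, int maxit = 1000,
                             int restart = 100) {
#ifdef HAVE_EIGEN
  Eigen::Map<const Eigen::SparseMatrix<double> > A(n, n, x.size(), p.begin(),
                                                   i.begin(), x.begin());
  Eigen::SparseMatrix<double> Ac(A);
  Eigen::GMRES<Eigen::SparseMatrix<double>, Eigen::IncompleteLUT<double> > solver;
  solver.preconditioner().setDroptol(droptol);
  solver.preconditioner().setFillfactor(fillfactor);
  solver.setTolerance(tol);
  solver.setMaxIterations(maxit);
  solver.set_restart(restart);
  solver.compute(Ac);
  if (solver.info() != Eigen::Success) stop("ILUT preconditioner failed");
  NumericMatrix out(n, b.ncol());
  double worst = 0.0;
  int iters = 0;
  for (int k = 0; k < b.ncol(); ++k) {
    Eigen::Map<const Eigen::VectorXd> bk(&b(0, k), n);
    Eigen::VectorXd xk = solver.solve(bk);
    iters = (int)solver.iterations();
    double bn = bk.cwiseAbs().maxCoeff();
    Eigen::VectorXd r = bk - Ac * xk;
    double rel = (bn > 0) ? r.cwiseAbs().maxCoeff() / bn : 0.0;
    if (rel > worst) worst = rel;
    std::copy(xk.data(), xk.data() + n, &out(0, k));
  }
  out.attr("rel_resid") = worst;
  out.attr("iterations") = iters;
  return out;
#else
  stop("compiled without Eigen support");
#endif
}
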