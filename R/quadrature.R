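# Quadrature rules on the unit interval, reference triangle and reference
# tetrahedron.  Weights sum to the reference-element measure (1, 1/2, 1/6), so
# that sum(w * f(points)) approximates the reference integral and mapping to a
# physical affine cell only needs |det J|.

#' Quadrature rule on a reference simplex or the unit interval
#'
#' Returns nodes and weights integrating polynomials up to the requested
#' degree exactly.  Degrees 1 and 2 use classical symmetric rules; higher
#' degrees use the Grundmann-Moller construction (which may carry negative
#' weights but is exact by design).
#'
#' @param dim 1 (interval), 2 (triangle) or 3 (tetrahedron).
#' @param degree polynomial degree to be integrated exactly.
#' @return list with `points` (n x dim matrix of reference coordinates) and
#'   `weights` (length-n vector summing to the reference measure).
#' @export
simplex_quadrature <- function(dim, degree) {
  stopifnot(dim %in% 1:3, degree >= 0)
  if (dim == 1L) return(gauss_legendre_01(ceiling((degree + 1) / 2)))
  if (degree <= 1) {
    centroid <- matrix(rep(1 / (dim + 1), dim), nrow = 1)
    return(list(points = centroid, weights = 1 / factorial(dim)))
  }
  if (degree == 2 && dim == 2) {
    # midpoint-of-edge rule, degree 2
    pts <- matrix(c(0.5, 0.0,
                    0.5, 0.5,
                    0.0, 0.5), ncol = 2, byrow = TRUE)
    return(list(points = pts, weights = rep(1 / 6, 3)))
  }
  if (degree == 2 && dim == 3) {
    a <- (5 + 3 * sqrt(5)) / 20
    b <- (5 - sqrt(5)) / 20
    pts <- rbind(c(a, b, b), c(b, a, b), c(b, b, a), c(b, b, b))
    return(list(points = pts, weights = rep(1 / 24, 4)))
  }
  s <- ceiling((degree - 1) / 2)
  grundmann_moller(dim, s)
}

# Gauss-Legendre on [0,1]
gauss_legendre_01 <- function(n) {
  n <- max(1L, as.integer(n))
  if (n > 8L) n <- 8L
  # nodes/weights on [-1,1]
  gl <- switch(n,
    list(x = 0, w = 2),
    list(x = c(-1, 1) / sqrt(3), w = c(1, 1)),
    list(x = c(-sqrt(3 / 5), 0, sqrt(3 / 5)), w = c(5, 8, 5) / 9),
    {
      a <- sqrt(3 / 7 - 2 / 7 * sqrt(6 / 5)); b <- sqrt(3 / 7 + 2 / 7 * sqrt(6 / 5))
      wa <- (18 + sqrt(30)) / 36; wb <- (18 - sqrt(30)) / 36
      list(x = c(-b, -a, a, b), w = c(wb, wa, wa, wb))
    },
    {
      a <- 1 / 3 * sqrt(5 - 2 * sqrt(10 / 7)); b <- 1 / 3 * sqrt(5 + 2 * sqrt(10 / 7))
      wa <- (322 + 13 * sqrt(70)) / 900; wb <- (322 - 13 * sqrt(70)) / 900
      list(x = c(-b, -a, 0, a, b), w = c(wb, wa, 128 / 225, wa, wb))
    },
    legendre_rule_numeric(6),
    legendre_rule_numeric(7),
    legendre_rule_numeric(8)
  )
  list(points = matrix((gl$x + 1) / 2, ncol = 1), weights = gl$w / 2)
}

# Golub-Welsch via the symmetric tridiagonal Jacobi matrix.
legendre_rule_numeric <- function(n) {
  k <- seq_len(n - 1)
  beta <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- beta
  J[cbind(k + 1, k)] <- beta
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = 2 * e$vectors[1, ]^2)
}

# Grundmann-Moller rule of index s on the n-simplex; exact to degree 2s+1.
grundmann_moller <- function(n, s) {
  d <- 2L * s + 1L
  pts <- NULL
  wts <- NULL
  vol <- 1 / factorial(n)
  for (i in 0:s) {
    coef <- (-1)^i * 2^(-2 * s) * (d + n - 2 * i)^d /
      (factorial(i) * factorial(d + n - i))
    comps <- compositions_of(s - i, n + 1L)
    p <- (2 * comps + 1) / (d + n - 2 * i)   # barycentric
    pts <- rbind(pts, p[, -1L, drop = FALSE])
    wts <- c(wts, rep(coef, nrow(p)))
  }
  # GM weights as published integrate with the simplex volume factored out of
  # the weight normalization below.
  wts <- wts * factorial(n) * vol
  # normalize so weights sum to the reference measure (exact for constants)
  wts <- wts / sum(wts) * vol
  list(points = pts, weights = wts)
}

# all length-k nonnegative integer vectors summing to m, as rows
compositions_of <- function(m, k) {
  if (k == 1L) return(matrix(m, ncol = 1))
  out <- NULL
  for (j in 0:m) {
    rest <- compositions_of(m - j, k - 1L)
    out <- rbind(out, cbind(j, rest, deparse.level = 0))
  }
  out
}
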