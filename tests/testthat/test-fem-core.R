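# Quadrature and reference-element internals (all authored here, so they get
# their own exactness checks).

test_that("simplex quadrature integrates monomials to closed form", {
  # triangle: int x^a y^b = a! b! / (a+b+2)!
  q <- simplex_quadrature(2, 8)
  for (a in 0:4) for (b in 0:4) {
    if (a + b > 8) next
    expect_equal(sum(q$weights * q$points[, 1]^a * q$points[, 2]^b),
                 factorial(a) * factorial(b) / factorial(a + b + 2),
                 tolerance = 1e-13)
  }
  # tetrahedron: int x^a y^b z^c = a! b! c! / (a+b+c+3)!
  q3 <- simplex_quadrature(3, 5)
  for (a in 0:3) for (b in 0:2) for (cc in 0:2) {
    if (a + b + cc > 5) next
    expect_equal(sum(q3$weights * q3$points[, 1]^a * q3$points[, 2]^b *
                       q3$points[, 3]^cc),
                 factorial(a) * factorial(b) * factorial(cc) /
                   factorial(a + b + cc + 3),
                 tolerance = 1e-14)
  }
  # interval Gauss rules
  q1 <- simplex_quadrature(1, 9)
  for (a in 0:9) {
    expect_equal(sum(q1$weights * q1$points[, 1]^a), 1 / (a + 1),
                 tolerance = 1e-14)
  }
})

test_that("reference bases form a partition of unity with consistent gradients", {
  for (d in 2:3) for (deg in 1:2) {
    pts <- simplex_quadrature(d, 3)$points
    rb <- wssbench:::ref_basis(d, deg, pts)
    expect_equal(colSums(rb$val), rep(1, nrow(pts)), tolerance = 1e-13)
    gsum <- apply(rb$grad, c(2, 3), sum)
    expect_lt(max(abs(gsum)), 1e-12)
    # nodal interpolation property: basis i equals 1 at node i, 0 elsewhere
    nodes <- wssbench:::ref_nodes(d, deg)
    vals <- wssbench:::ref_basis(d, deg, nodes)$val
    expect_equal(unname(vals), diag(nrow(nodes)), tolerance = 1e-13)
    # finite-difference check of the stored gradients
    eps <- 1e-6
    for (b in seq_len(d)) {
      pp <- pts; pp[, b] <- pp[, b] + eps
      pm <- pts; pm[, b] <- pm[, b] - eps
      fd <- (wssbench:::ref_basis(d, deg, pp)$val -
               wssbench:::ref_basis(d, deg, pm)$val) / (2 * eps)
      expect_equal(fd, rb$grad[, b, ], tolerance = 1e-8)
    }
  }
})

test_that("circumdiameters match closed forms on canonical cells", {
  # unit right triangle: hypotenuse is the circumdiameter
  m <- one_triangle_mesh()
  expect_equal(m$cell_h, sqrt(2), tolerance = 1e-14)
  # regular tetrahedron with edge a: diameter = a * sqrt(3/2)
  a <- 2
  verts <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) *
    (a / (2 * sqrt(2)))
  mt <- tagged_mesh(verts, rbind(1:4), region_names = c("1" = "boundary"),
                    facet_tagger = function(cen, nrm) rep(1L, nrow(cen)))
  expect_equal(mt$cell_h, a * sqrt(3 / 2), tolerance = 1e-12)
})
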