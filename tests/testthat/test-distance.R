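test_that("axis and boundary projectors decompose the identity", {
  for (b in 1:6) {
    pr <- s6_projectors(b)
    expect_equal(pr$axis + pr$perp, diag(6), ignore_attr = TRUE)
    expect_equal(pr$axis %*% pr$axis, pr$axis)
    expect_equal(pr$perp %*% pr$perp, pr$perp)
    expect_identical(pr$axis, t(pr$axis))
    expect_identical(pr$perp, t(pr$perp))
  }
})

test_that("make_vcp implements transform-projection-minus-perp and is equivariant", {
  withr::with_seed(61, {
    p <- -runif(6, 0.5, 5)
    for (b in 1:6) {
      pr <- s6_projectors(b)
      e <- sellingr:::edge_transform(b, 1)
      expected <- as.numeric(e$matrix %*% (pr$perp %*% p) - pr$axis %*% p)
      expect_equal(make_vcp(p, b), expected, tolerance = 1e-13)
      # on the boundary the VCP is the plain edge transform of the point
      pb <- p; pb[b] <- 0
      expect_equal(make_vcp(pb, b), as.numeric(e$matrix %*% pb), tolerance = 1e-14)
    }
    # the full candidate set commutes with reflections: candidates(R p) = R candidates(p)
    r17 <- s6_reflections()[[17]]$matrix
    cand_p <- sellingr:::vcp_candidates(p)
    cand_rp <- sellingr:::vcp_candidates(as.numeric(r17 %*% p))
    key <- function(m) sort(apply(round(m, 9), 2, paste, collapse = ","))
    expect_identical(key(cand_rp), key(r17 %*% cand_p))
  })
})

test_that("a VCP route can undercut the direct route for near-boundary points", {
  # two points close to the s1 = 0 boundary on opposite sides of a transform
  p <- c(-0.05, -3, -4, -5, -6, -7)
  vcp <- make_vcp(p, 1)
  q <- vcp; q[1] <- -0.05  # reduced point near the VCP
  expect_true(is_reduced(q))
  direct <- min(colSums((matrix(sellingr:::refl_stack() %*% p, 6) - q)^2))
  expect_lt(dist_vcp1(p, q)$distance, sqrt(direct))
})

test_that("dist_vcp1 vanishes on a lattice's own orbit and matches the worked example", {
  p <- ORTHO_S6
  expect_identical(dist_vcp1(p, p)$distance, 0)
  for (op in s6_reflections()) {
    expect_identical(dist_vcp1(p, apply_sym(op, p))$distance, 0)
  }
  q <- cell_to_s6(c(10, 12, 20.1, 90, 90, 90))
  expect_equal(dist_vcp1(p, q)$distance, 20.1^2 - 400, tolerance = 1e-12)
  expect_error(dist_vcp1(RHOMB60_S6, p), "selling_reduce")
})

test_that("interior pairs reduce to the plain reflection minimum", {
  withr::with_seed(71, {
    for (rep in 1:200) {
      p <- -runif(6, 5, 15)    # all components at least 5 from every boundary
      q <- p + runif(6, -0.4, 0.4)
      expect_true(is_reduced(q))
      oracle <- sqrt(min(colSums((matrix(sellingr:::refl_stack() %*% q, 6) - p)^2)))
      expect_equal(dist_vcp1(p, q)$distance, oracle, tolerance = 1e-12)
      expect_equal(dist_vcp2(p, q)$distance, oracle, tolerance = 1e-12)
    }
  })
})

test_that("two-boundary distances never exceed one-boundary distances", {
  withr::with_seed(83, {
    pts <- sellingr:::random_reduced_s6(400)
    for (i in 1:200) {
      d <- sellingr:::d12_pair(pts[[2 * i - 1]], pts[[2 * i]])
      expect_lte(d[2], d[1] * (1 + 1e-12))
    }
  })
  expect_identical(dist_vcp2(ORTHO_S6, ORTHO_S6)$distance, 0)
})

test_that("one-boundary distances match a numerical geodesic oracle at a boundary", {
  # p sits at height h below boundary b; q is the reduced image of the point
  # at height h straight above it. The one-boundary geodesic length is found
  # independently by minimizing |p - m| + |M_b m - q| over crossing points m
  # in the boundary plane (the transform is an isometry only on that plane,
  # where it acts as a permutation); closed form for this construction: 3h.
  withr::with_seed(97, {
    for (rep in 1:10) {
      w <- -runif(6, 3, 9)
      b <- sample.int(6, 1)
      w[b] <- 0
      h <- runif(1, 0.05, 0.3)
      p <- w; p[b] <- -h
      z <- w; z[b] <- h
      q <- reduce_s6(z)
      mmat <- sellingr:::edge_transform(b, 1)$matrix
      leglen <- function(m5) {
        m <- numeric(6); m[-b] <- m5
        sqrt(sum((p - m)^2)) + sqrt(sum((as.numeric(mmat %*% m) - q)^2))
      }
      opt <- optim(w[-b], leglen, method = "BFGS", control = list(maxit = 500))
      d1 <- dist_vcp1(p, q)$distance
      expect_equal(d1, opt$value, tolerance = 1e-5)
      expect_equal(d1, 3 * h, tolerance = 1e-9)
    }
  })
})

test_that("mirror distances are sandwiched between VCP and plain reflection distances", {
  expect_identical(dist_mirror(ORTHO_S6, ORTHO_S6)$distance, 0)
  withr::with_seed(98, {
    pts <- sellingr:::random_reduced_s6(60)
    for (i in 1:30) {
      p <- pts[[2 * i - 1]]; q <- pts[[2 * i]]
      dm <- dist_mirror(p, q)$distance
      d1 <- dist_vcp1(p, q)$distance
      de <- dist_euclidean(p, q)$distance
      expect_lte(d1, dm + 1e-9 * max(1, d1))
      expect_lte(dm, de + 1e-12)
      # symmetry of the mirror strategy
      expect_equal(dm, dist_mirror(q, p)$distance, tolerance = 1e-12)
    }
  })
  # interior pairs: no boundary path helps, every strategy agrees
  p0 <- c(-8, -9, -10, -11, -12, -13)
  q0 <- p0 + c(0.1, -0.2, 0.15, 0.05, -0.1, 0.2)
  expect_equal(dist_mirror(p0, q0)$distance, dist_euclidean(p0, q0)$distance,
               tolerance = 1e-12)
  expect_equal(dist_mirror(p0, q0)$distance, dist_vcp1(p0, q0)$distance,
               tolerance = 1e-12)
})

test_that("cs6dist is symmetric, reduction-invariant and bounded by the canonical Euclidean distance", {
  expect_equal(cs6dist(c(10, 12, 20, 90, 90, 90), c(10, 12, 20.1, 90, 90, 90))$distance,
               4.01, tolerance = 1e-12)
  withr::with_seed(13, {
    for (rep in 1:25) {
      base <- reduce_s6(cell_to_s6(sellingr:::random_cell_matrix(1)[1, ]))
      # deliberately unreduced presentation of the same lattice
      s <- unreduce_random(base, k = 3)
      expect_equal(cs6dist(s, base, input = "s6")$distance, 0,
                   tolerance = 1e-7 * sqrt(sum(base^2)))
      other <- reduce_s6(cell_to_s6(sellingr:::random_cell_matrix(1)[1, ]))
      d_pq <- cs6dist(base, other, input = "s6")$distance
      d_qp <- cs6dist(other, base, input = "s6")$distance
      expect_identical(d_pq, d_qp)
      cb <- canon(base); co <- canon(other)
      expect_lte(d_pq, sqrt(sum((cb - co)^2)) + 1e-12)
      # reflection applied to one argument changes nothing
      refl <- s6_reflections()[[sample.int(24, 1)]]
      expect_equal(cs6dist(apply_sym(refl, base), other, input = "s6")$distance,
                   d_pq, tolerance = 1e-12)
    }
  })
})

test_that("cs6dist tells cells and S6 vectors apart and supports normalization", {
  # a valid cell parameter set is taken as a cell, not as scalars
  d <- cs6dist(c(10, 12, 20, 90, 90, 90), c(10, 12, 20, 90, 90, 90))
  expect_identical(d$distance, 0)
  s <- cell_to_s6(ORTHO_CELL)
  expect_identical(cs6dist(s, ORTHO_CELL)$distance, 0) # mixed input forms
  dn <- cs6dist(c(10, 12, 20, 90, 90, 90), c(10, 12, 20.1, 90, 90, 90), normalize = TRUE)
  expect_equal(dn$distance, 4.01 / (sqrt(sum(s^2)) + sqrt(sum(cell_to_s6(c(10, 12, 20.1, 90, 90, 90))^2))),
               tolerance = 1e-12)
})

test_that("distance_matrix is symmetric with a zero diagonal and matches cs6dist", {
  cells <- generate_cells(5, seed = 19)
  d <- distance_matrix(cells)
  m <- as.matrix(d)
  expect_identical(diag(m), setNames(rep(0, 5), cells$label))
  expect_identical(m, t(m))
  expect_true(all(m >= 0))
  expect_equal(m[2, 4], cs6dist(cells[2, ], cells[4, ])$distance, tolerance = 1e-12)
  m2 <- as.matrix(distance_matrix(cells, strategy = "euclidean"))
  expect_true(all(m2 + 1e-12 >= m))
})
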