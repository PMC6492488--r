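# Minimal distances between Selling-reduced lattices.
#
# The fundamental region (all scalars <= 0) carries the Euclidean metric, but
# a shortest path between two lattices may leave it through a sign boundary,
# where the gluing map is a non-diagonal isometry. Two constructions recover
# minimal one-boundary paths: virtual Cartesian points (apply the boundary's
# signed-permutation operator, then measure Euclidean distance in the
# fundamental unit) and tunneled mirrored boundaries (touch the boundary at a
# classical mirror point, tunnel at no cost to its transformed image).

#' Axis and boundary projectors of S6
#'
#' For each sign boundary `s_b = 0`: the rank-one projector onto the `s_b`
#' axis and the rank-five projector onto the boundary polytope. The two sum
#' to the identity; both are idempotent and symmetric (the S6 axes are
#' orthogonal).
#'
#' @param boundary Boundary index 1..6.
#' @return A list with 6x6 matrices `axis` and `perp`.
#' @examples
#' pr <- s6_projectors(2)
#' pr$axis + pr$perp # identity
#' @export
s6_projectors <- function(boundary) {
  if (!boundary %in% 1:6) abort("boundary must be 1..6")
  ax <- matrix(0, 6, 6)
  ax[boundary, boundary] <- 1
  list(axis = ax, perp = diag(6) - ax)
}

#' Virtual Cartesian point of a reduced vector
#'
#' Applies the edge transform of the chosen boundary to the projection of `p`
#' onto that boundary and subtracts the axis component: the resulting point
#' (generally outside the reduced orthant) is at the same distance from the
#' boundary as `p`, and Euclidean distances from reduced points to it measure
#' path lengths that cross the boundary once. Equivalently, the VCP is the
#' boundary's orthogonal signed-permutation operator applied to `p`; for `p`
#' on the boundary it coincides with the plain edge transform of `p`.
#'
#' @param p A Selling-reduced S6 vector.
#' @param boundary Boundary index 1..6.
#' @param variant Edge-transform variant (1 or 2); the variant-2 VCP is a
#'   reflection of the variant-1 VCP, so distance searches that already apply
#'   the 24 reflections need only variant 1.
#' @return An S6 vector.
#' @examples
#' make_vcp(c(0, -1, -1, -2, -2, -2), boundary = 1)
#' @export
make_vcp <- function(p, boundary, variant = 1) {
  as.numeric(edge_transform(boundary, variant)$vcp_matrix %*% as_s6(p))
}

# 6 x 168 candidate matrix for one point: all 24 reflections of the point and
# of its six variant-1 VCPs; columns ordered reflection-fastest, base point
# (original, then boundaries 1..6) slowest
vcp_candidates <- function(p) {
  p <- as_s6(p)
  x7 <- cbind(p, vapply(1:6, function(b) {
    as.numeric(edge_transform(b, 1)$vcp_matrix %*% p)
  }, numeric(6)))
  a <- refl_stack() %*% x7        # 144 x 7, blocks of 6 rows per reflection
  dim(a) <- c(6, 168)
  a
}

# 6 x 7 matrix: the point and its six VCPs
vcp7 <- function(p) {
  cbind(p, vapply(1:6, function(b) {
    as.numeric(edge_transform(b, 1)$vcp_matrix %*% p)
  }, numeric(6)))
}

check_reduced_input <- function(s, tol, who) {
  if (!is_reduced(s, tol)) {
    abort(paste0(who, ": input is not Selling reduced; apply selling_reduce first"))
  }
}

# one-boundary and two-boundary distances for one ordered pair, in one pass:
# returns c(d1, d2) where d1 uses q only and d2 uses q and its six VCPs.
# squared distances are taken on explicit differences (not the expanded
# ||x||^2 + ||y||^2 - 2 x.y form, which cancels catastrophically when the
# points are near-coincident relative to their norm)
d12_one_sided <- function(cp, q) {
  yq <- vcp7(q)
  mins <- vapply(1:7, function(j) min(colSums((cp - yq[, j])^2)), numeric(1))
  c(sqrt(max(mins[1], 0)), sqrt(max(min(mins), 0)))
}

# symmetric d1/d2 evaluated over both argument orders
d12_pair <- function(p, q) {
  a <- d12_one_sided(vcp_candidates(p), q)
  b <- d12_one_sided(vcp_candidates(q), p)
  pmin(a, b)
}

dist_result <- function(distance, strategy, witness = NULL) {
  structure(list(distance = distance, strategy = strategy, witness = witness),
            class = "s6_distance")
}

#' @export
print.s6_distance <- function(x, ...) {
  cat("<s6_distance> ", format(x$distance), " A^2  (", x$strategy, ")\n", sep = "")
  if (!is.null(x$witness)) {
    w <- x$witness
    cat("  witness: ", w$description, "\n", sep = "")
  }
  invisible(x)
}

witness_from_index <- function(k, side) {
  j <- (k - 1) %/% 24 + 1   # 1 = the point itself, 2..7 = boundary j - 1
  r <- (k - 1) %% 24 + 1
  list(side = side,
       boundary = if (j == 1) NA_integer_ else j - 1L,
       reflection = r,
       description = sprintf(
         "%s candidate: %s, reflection %d",
         side, if (j == 1) "point itself" else paste0("VCP of boundary s", j - 1), r))
}

#' Lattice distances between two Selling-reduced S6 vectors
#'
#' All four strategies return the minimum Euclidean length over a family of
#' candidate paths and are symmetric in their arguments, zero for two
#' presentations of the same lattice, and invariant under any of the 24
#' reflections applied to either input:
#'
#' * `dist_euclidean()` — baseline: the minimum over the 24 reflections of one
#'   point of the plain Euclidean distance.
#' * `dist_vcp1()` — one-boundary virtual Cartesian points: minimum distance
#'   from one point to the 168 candidates (24 reflections of the other point
#'   and of its six VCPs), evaluated in both argument orders.
#' * `dist_vcp2()` — two-boundary solutions: minimum over all pairs drawn
#'   from the 168-candidate set of one point and the 7-point set (point plus
#'   six VCPs) of the other; never exceeds `dist_vcp1()`.
#' * `dist_mirror()` — tunneled mirrored boundaries: for each boundary and
#'   reflection, a path touching the boundary at the classical mirror point
#'   (heights divided proportionally) and continuing from the mirror point's
#'   zero-cost transformed image, minimized over reflections of that image;
#'   the direct reflection distance is always among the candidates.
#'
#' Inputs must already be Selling reduced (see [selling_reduce()]); an
#' unreduced input is an error. The returned value is a valid minimum over a
#' restricted path family: the triangle inequality is not guaranteed.
#'
#' @param p,q Selling-reduced numeric S6 vectors.
#' @param tol Reduction-check tolerance (see [is_reduced()]).
#' @return An object of class `s6_distance` with fields `distance` (Angstrom
#'   squared), `strategy`, `witness`.
#' @examples
#' p <- cell_to_s6(c(10, 12, 20, 90, 90, 90))
#' q <- cell_to_s6(c(10, 12, 20.1, 90, 90, 90))
#' dist_vcp1(p, q)$distance # 4.01
#' @export
dist_vcp1 <- function(p, q, tol = NULL) {
  p <- as_s6(p); q <- as_s6(q)
  check_reduced_input(p, tol, "dist_vcp1")
  check_reduced_input(q, tol, "dist_vcp1")
  cp <- vcp_candidates(p)
  da2 <- colSums((cp - q)^2)
  cq <- vcp_candidates(q)
  db2 <- colSums((cq - p)^2)
  if (min(da2) <= min(db2)) {
    k <- which.min(da2)
    dist_result(sqrt(max(min(da2), 0)), "vcp1", witness_from_index(k, "first"))
  } else {
    k <- which.min(db2)
    dist_result(sqrt(max(min(db2), 0)), "vcp1", witness_from_index(k, "second"))
  }
}

#' @rdname dist_vcp1
#' @export
dist_vcp2 <- function(p, q, tol = NULL) {
  p <- as_s6(p); q <- as_s6(q)
  check_reduced_input(p, tol, "dist_vcp2")
  check_reduced_input(q, tol, "dist_vcp2")
  best <- Inf; wit <- NULL
  for (ord in 1:2) {
    x <- if (ord == 1) p else q
    y <- if (ord == 1) q else p
    cx <- vcp_candidates(x)
    yy <- vcp7(y)
    d2 <- vapply(1:7, function(j) colSums((cx - yy[, j])^2), numeric(ncol(cx)))
    k <- arrayInd(which.min(d2), dim(d2))
    if (min(d2) < best) {
      best <- min(d2)
      wit <- list(first = witness_from_index(k[1], if (ord == 1) "first" else "second"),
                  second_boundary = if (k[2] == 1) NA_integer_ else k[2] - 1L,
                  description = sprintf("two-boundary pair: candidate %d vs %s",
                                        k[1],
                                        if (k[2] == 1) "point itself"
                                        else paste0("VCP of boundary s", k[2] - 1)))
    }
  }
  dist_result(sqrt(max(best, 0)), "vcp2", wit)
}

#' @rdname dist_vcp1
#' @export
dist_euclidean <- function(p, q, tol = NULL) {
  p <- as_s6(p); q <- as_s6(q)
  check_reduced_input(p, tol, "dist_euclidean")
  check_reduced_input(q, tol, "dist_euclidean")
  a <- refl_stack() %*% q
  dim(a) <- c(6, 24)
  d2 <- colSums((a - p)^2)
  k <- which.min(d2)
  dist_result(sqrt(max(min(d2), 0)), "euclidean",
              list(reflection = k, description = paste0("reflection ", k, " of second point")))
}

#' @rdname dist_vcp1
#' @export
dist_mirror <- function(p, q, tol = NULL) {
  p <- as_s6(p); q <- as_s6(q)
  check_reduced_input(p, tol, "dist_mirror")
  check_reduced_input(q, tol, "dist_mirror")
  a <- mirror_one_sided(p, q)
  b <- mirror_one_sided(q, p)
  if (a$distance <= b$distance) a else b
}

# tunneled mirror search from p's side against all reflections of q
mirror_one_sided <- function(p, q) {
  rs <- refl_stack()
  qr_all <- rs %*% q; dim(qr_all) <- c(6, 24)
  # direct reflection distances are always candidates
  best <- min(colSums((qr_all - p)^2))
  best <- sqrt(max(best, 0))
  wit <- list(description = "direct reflection path")
  for (r in 1:24) {
    qq <- qr_all[, r]
    for (b in 1:6) {
      hp <- max(-p[b], 0)
      hq <- max(-qq[b], 0)
      pp <- p; pp[b] <- 0
      qp <- qq; qp[b] <- 0
      frac <- if (hp + hq > 0) hp / (hp + hq) else 0.5
      mp <- pp + frac * (qp - pp)
      len1 <- sqrt(sum((p - mp)^2))
      if (len1 >= best) next
      mpx <- as.numeric(edge_transform(b, 1)$matrix %*% mp)  # on-boundary: isometric image
      mimg <- rs %*% mpx; dim(mimg) <- c(6, 24)
      len2 <- sqrt(max(min(colSums((mimg - qq)^2)), 0))
      if (len1 + len2 < best) {
        best <- len1 + len2
        wit <- list(boundary = b, reflection = r,
                    description = sprintf("tunnel through boundary s%d (reflection %d)", b, r))
      }
    }
  }
  dist_result(best, "mirror", wit)
}

#' Distance between two lattices given as cells or S6 vectors
#'
#' The user-facing entry point: accepts unit cells (six parameters or one-row
#' data frames) or raw S6 vectors in any presentation, Selling-reduces both
#' internally, and dispatches to the chosen strategy. The result is symmetric
#' and non-negative, and is zero (within tolerance) iff the inputs describe
#' the same lattice.
#'
#' @param p,q Unit cells (`c(a, b, c, alpha, beta, gamma)`, degrees) or S6
#'   vectors (Angstrom squared). A six-number input is interpreted as a cell
#'   when it satisfies the cell invariants (positive lengths, angles in
#'   (0, 180) admitting a positive-definite metric), otherwise as an S6
#'   vector; override with `input`.
#' @param strategy One of `"vcp1"` (default), `"vcp2"`, `"euclidean"`,
#'   `"mirror"`.
#' @param input `"auto"`, `"s6"` or `"cell"`.
#' @param normalize Divide the distance by (|p| + |q|) of the reduced vectors
#'   for a scale-free value? Off by default.
#' @return An `s6_distance` object.
#' @examples
#' cs6dist(c(10, 12, 20, 90, 90, 90), c(10, 12, 20.1, 90, 90, 90))$distance
#' @export
cs6dist <- function(p, q, strategy = c("vcp1", "vcp2", "euclidean", "mirror"),
                    input = c("auto", "s6", "cell"), normalize = FALSE) {
  strategy <- match.arg(strategy)
  input <- match.arg(input)
  ps <- reduce_s6(coerce_to_s6(p, input))
  qs <- reduce_s6(coerce_to_s6(q, input))
  res <- switch(strategy,
    vcp1 = dist_vcp1(ps, qs),
    vcp2 = dist_vcp2(ps, qs),
    euclidean = dist_euclidean(ps, qs),
    mirror = dist_mirror(ps, qs))
  if (normalize) {
    denom <- sqrt(sum(ps^2)) + sqrt(sum(qs^2))
    if (denom > 0) res$distance <- res$distance / denom
  }
  res
}

coerce_to_s6 <- function(x, input = "auto") {
  if (is.data.frame(x)) {
    if (all(c("s1", "s6") %in% names(x))) return(as_s6(as.numeric(x[1, paste0("s", 1:6)])))
    return(cell_to_s6(x))
  }
  v <- as.numeric(x)
  if (length(v) != 6) abort("input must have six components (cell parameters or S6 scalars)")
  treat_as_cell <- switch(input,
    cell = TRUE,
    s6 = FALSE,
    auto = is.null(cell_check(v)))
  if (treat_as_cell) cell_to_s6(v) else v
}

#' Pairwise distance matrix for a set of cells
#'
#' Reduces every cell once, then computes all pairwise lattice distances with
#' the chosen strategy. The result is symmetric with a zero diagonal.
#'
#' @param cells A data frame of cells (columns `a..gamma`) or of S6 vectors
#'   (columns `s1..s6`); labels are used as dimnames.
#' @param strategy Distance strategy (see [cs6dist()]).
#' @return A [stats::dist] object (use `as.matrix()` for the square form).
#' @examples
#' d <- distance_matrix(generate_cells(4, seed = 1))
#' as.matrix(d)
#' @export
distance_matrix <- function(cells, strategy = c("vcp1", "vcp2", "euclidean", "mirror")) {
  strategy <- match.arg(strategy)
  m <- if (is.data.frame(cells) && all(c("a", "alpha") %in% names(cells))) {
    as_s6_matrix(cells_to_s6(cells))
  } else {
    as_s6_matrix(cells)
  }
  labs <- if (is.data.frame(cells) && "label" %in% names(cells)) as.character(cells$label)
          else paste0("cell_", seq_len(nrow(m)))
  n <- nrow(m)
  red <- lapply(seq_len(n), function(i) reduce_s6(m[i, ]))
  cands <- if (strategy %in% c("vcp1", "vcp2")) lapply(red, vcp_candidates) else NULL
  dm <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      dm[i, j] <- dm[j, i] <- switch(strategy,
        vcp1 = min(sqrt(max(min(colSums((cands[[i]] - red[[j]])^2)), 0)),
                   sqrt(max(min(colSums((cands[[j]] - red[[i]])^2)), 0))),
        vcp2 = min(d12_one_sided(cands[[i]], red[[j]])[2],
                   d12_one_sided(cands[[j]], red[[i]])[2]),
        euclidean = dist_euclidean(red[[i]], red[[j]])$distance,
        mirror = dist_mirror(red[[i]], red[[j]])$distance)
    }
  }
  dimnames(dm) <- list(labs, labs)
  as.dist(dm)
}

#' Monte-Carlo comparison of one- and two-boundary distances
#'
#' Samples pairs of independent random Selling-reduced S6 vectors and
#' computes the one-boundary and two-boundary VCP distances for every pair.
#' The default sampler draws each component uniformly in the reduced
#' (all-negative) orthant, which spans near-boundary (some component close to
#' zero) and interior regimes; `sampler = "cells"` instead reduces random
#' cells from [generate_cells()]'s basis sampler, a distribution whose points
#' hug the boundaries much more tightly (generic reduced lattices have a
#' near-zero scalar) and therefore shows far more frequent, far smaller
#' two-boundary improvements — see the methods vignette. Use
#' [two_boundary_summary()] to extract the fraction of improved pairs and the
#' size of the improvements. Set the RNG seed beforehand for reproducibility.
#'
#' @param n_pairs Number of point pairs.
#' @param sampler `"uniform"` (components uniform in `[-scale, 0]`) or
#'   `"cells"` (reduced random cells).
#' @param scale Magnitude of the uniform draw in Angstrom squared (the
#'   improvement statistics are scale-free).
#' @param length_range Cell-edge range (Angstrom) for `sampler = "cells"`.
#' @return A tibble with columns `d1`, `d2` (Angstrom squared).
#' @examples
#' set.seed(7)
#' mc <- mc_two_boundary_experiment(200)
#' two_boundary_summary(mc)
#' @export
mc_two_boundary_experiment <- function(n_pairs = 10000,
                                       sampler = c("uniform", "cells"),
                                       scale = 100, length_range = c(10, 100)) {
  sampler <- match.arg(sampler)
  pts <- random_reduced_s6(2L * n_pairs, method = sampler, scale = scale,
                           length_range = length_range)
  d <- matrix(0, n_pairs, 2)
  for (i in seq_len(n_pairs)) {
    d[i, ] <- d12_pair(pts[[2 * i - 1]], pts[[2 * i]])
  }
  tibble::tibble(d1 = d[, 1], d2 = d[, 2])
}

#' @param mc A tibble from [mc_two_boundary_experiment()].
#' @param rel_tol Relative tolerance beyond which an improvement counts as
#'   strict.
#' @rdname mc_two_boundary_experiment
#' @export
two_boundary_summary <- function(mc, rel_tol = 1e-9) {
  improved <- mc$d2 < mc$d1 * (1 - rel_tol)
  rel <- (mc$d1[improved] - mc$d2[improved]) / mc$d1[improved]
  list(
    n_pairs = nrow(mc),
    n_improved = sum(improved),
    improved_fraction_pct = 100 * mean(improved),
    median_improvement_pct = if (any(improved)) 100 * stats::median(rel) else 0,
    max_improvement_pct = if (any(improved)) 100 * max(rel) else 0
  )
}

# random Selling-reduced S6 vectors in a random presentation, as a list
random_reduced_s6 <- function(n, method = c("uniform", "cells"), scale = 100,
                              length_range = c(10, 100)) {
  method <- match.arg(method)
  if (method == "uniform") {
    return(lapply(seq_len(n), function(i) -scale * runif(6)))
  }
  cells <- random_cell_matrix(n, length_range)
  lapply(seq_len(n), function(i) {
    s <- reduce_s6(cell_to_s6(cells[i, ]))
    apply_sym(s6_reflections()[[sample.int(24, 1)]], s)
  })
}
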