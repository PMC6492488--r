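# Selling reduction.
#
# A presentation is Selling reduced when all six scalars are <= 0. Crossing
# the sign boundary of scalar s_b is effected by a Delone basis step: negate
# one vector of the pair whose dot product is s_b, keep its partner, and add
# the negated vector to the two remaining tetrahedron vectors. Each boundary
# has two such steps (one per pair member), giving 12 edge transforms; the two
# variants of a boundary are related by one of the 24 reflections, and every
# transform is its own inverse (unreduction = reduction).

# scalar index of the unordered tetrahedron-vector pair {i, j}
pair_slot <- function(i, j) {
  ij <- sort(c(i, j))
  for (k in 1:6) if (all(PAIR_IDX[[k]] == ij)) return(k)
  abort("no scalar for this vector pair")
}

make_edge_transform <- function(boundary, variant) {
  pair <- PAIR_IDX[[boundary]]
  neg <- pair[variant]
  others <- setdiff(1:4, pair)
  tmat <- diag(4)
  tmat[neg, neg] <- -1
  tmat[others, neg] <- 1
  m <- s6_map_from_vector_transform(tmat)
  # on the boundary s_b = 0 the transform is a permutation; combined with the
  # negated axis component it is a signed permutation (orthogonal): the
  # operator that builds virtual Cartesian points
  p_axis <- matrix(0, 6, 6); p_axis[boundary, boundary] <- 1
  vcp <- m %*% (diag(6) - p_axis) - p_axis
  structure(list(
    boundary = boundary,
    variant = variant,
    negated_vector = c("a", "b", "c", "d")[neg],
    swap_slots = sort(c(pair_slot(neg, others[1]), pair_slot(neg, others[2]))),
    matrix = m,
    vcp_matrix = round(vcp)
  ), class = "s6_edge_transform")
}

#' The twelve edge transforms of S6
#'
#' Returns the boundary (edge) transforms of the Selling-reduced region: two
#' per scalar sign boundary, ordered by boundary then variant. Each transform
#' object carries two matrix forms:
#'
#' * `matrix` — the lattice-preserving reduction step (an involution). Applied
#'   to a vector with positive scalar `s_b` it negates that scalar and updates
#'   the coupled scalars, representing the same lattice in a new basis. It is
#'   not orthogonal off the boundary.
#' * `vcp_matrix` — the orthogonal signed permutation obtained by applying the
#'   step to the projection onto the boundary `s_b = 0` and negating the axis
#'   component. On the boundary the two forms coincide; off the boundary the
#'   signed permutation is the isometric gluing map used by the distance
#'   algorithms (it builds the virtual Cartesian points).
#'
#' The two variants of one boundary are related by a reflection from
#' [s6_reflections()].
#'
#' @return A list of 12 objects of class `s6_edge_transform` with fields
#'   `boundary` (1..6), `variant` (1 or 2), `negated_vector`, `swap_slots`,
#'   `matrix`, `vcp_matrix`.
#' @examples
#' length(s6_edge_transforms())
#' s6_edge_transforms()[[5]]$matrix # boundary 3, variant 1
#' @export
s6_edge_transforms <- function() {
  cached <- .selling_cache$edge_transforms
  if (!is.null(cached)) return(cached)
  ets <- list()
  for (b in 1:6) for (v in 1:2) ets[[length(ets) + 1]] <- make_edge_transform(b, v)
  .selling_cache$edge_transforms <- ets
  ets
}

# transform for one boundary/variant
edge_transform <- function(boundary, variant = 1) {
  s6_edge_transforms()[[2 * (boundary - 1) + variant]]
}

#' @export
print.s6_edge_transform <- function(x, ...) {
  cat("<s6_edge_transform> boundary s", x$boundary, ", variant ", x$variant,
      " (negates ", x$negated_vector, ", exchanges s", x$swap_slots[1],
      " and s", x$swap_slots[2], ")\n", sep = "")
  print(x$matrix)
  invisible(x)
}

#' Is an S6 vector Selling reduced?
#'
#' TRUE iff every component is at or below `tol` (default: 1e-10 times the
#' vector norm, so that roundoff-positive components still count as reduced).
#'
#' @param s A numeric S6 vector.
#' @param tol Absolute tolerance in Angstrom squared.
#' @examples
#' is_reduced(c(0, 0, 0, -100, -144, -400)) # TRUE
#' is_reduced(c(0.5, 0.5, 0.5, -2, -2, -2)) # FALSE
#' @export
is_reduced <- function(s, tol = NULL) {
  s <- as_s6(s)
  if (is.null(tol)) tol <- 1e-10 * sqrt(sum(s^2))
  max(s) <= tol
}

#' Selling reduction of an S6 vector
#'
#' Repeatedly applies the edge transform of the largest positive scalar until
#' all six scalars are non-positive (within `tol`). Each step strictly
#' decreases -(s1 + ... + s6) = (|a|^2 + |b|^2 + |c|^2 + |d|^2) / 2 by the
#' eliminated positive scalar, which guarantees termination for any vector
#' arising from a non-degenerate lattice. The reduced vector represents the
#' same lattice as the input (the unit-cell volume is unchanged).
#'
#' @param s A numeric S6 vector with negative component sum.
#' @param tol Absolute reduction tolerance in Angstrom squared; default
#'   1e-10 times the input norm.
#' @param max_iter Iteration cap; exceeding it signals an error naming the
#'   last state (a symptom of degenerate input).
#' @param variant Which member of each boundary pair to use (1 or 2); the
#'   results for the two variants are reflections of one another.
#' @return An object of class `selling_reduction`: list with `reduced` (the
#'   reduced S6 vector), `ops_applied` (tibble of `boundary`, `variant`,
#'   `eliminated` scalar values), `iterations`, and `input`.
#' @examples
#' selling_reduce(cell_to_s6(c(1, 1, 1, 60, 60, 60)))$reduced
#' @export
selling_reduce <- function(s, tol = NULL, max_iter = 1000, variant = 1) {
  s <- as_s6(s)
  input <- s
  if (is.null(tol)) tol <- 1e-10 * sqrt(sum(s^2))
  if (!variant %in% c(1, 2)) abort("variant must be 1 or 2")
  ops_b <- integer(0); ops_v <- integer(0); elim <- numeric(0)
  it <- 0L
  while (max(s) > tol) {
    if (it >= max_iter) {
      abort(sprintf(
        "selling_reduce: iteration cap %d exceeded (degenerate or invalid input?); last state: %s",
        max_iter, paste(signif(s, 6), collapse = ", ")))
    }
    b <- which.max(s)
    elim <- c(elim, s[b])
    s <- as.numeric(edge_transform(b, variant)$matrix %*% s)
    ops_b <- c(ops_b, b); ops_v <- c(ops_v, variant)
    it <- it + 1L
  }
  structure(list(
    reduced = s,
    ops_applied = tibble::tibble(boundary = ops_b, variant = ops_v, eliminated = elim),
    iterations = it,
    input = input
  ), class = "selling_reduction")
}

#' @export
print.selling_reduction <- function(x, ...) {
  cat("<selling_reduction> ", x$iterations, " step(s)\n", sep = "")
  cat("reduced:", paste(signif(x$reduced, 6), collapse = "  "), "\n")
  invisible(x)
}

# convenience: reduced vector only
reduce_s6 <- function(s, ...) selling_reduce(s, ...)$reduced

#' One Selling reduction step in the complex form
#'
#' Applies a single reduction step to a C3 vector, eliminating the named part
#' (real or imaginary) of the named component, using complex arithmetic
#' throughout (independent of the S6 matrices, against which it is
#' cross-checked by the test suite). The step is:
#'
#' 1. subtract the eliminated part from its partner part within the same
#'    component and negate the eliminated part;
#' 2. add the original value of the eliminated part to the real and imaginary
#'    parts of the other two components;
#' 3. exchange one scalar pair between the other two components: the two
#'    scalars that couple the negated tetrahedron vector to the two non-pair
#'    vectors (a cross real/imaginary exchange for a real-part step, a
#'    same-part exchange for an imaginary-part step; `variant` selects which
#'    of the two valid choices, which are reflections of one another).
#'
#' @param w A complex C3 vector.
#' @param component Which complex component (1..3).
#' @param part `"real"` or `"imaginary"`.
#' @param variant 1 or 2.
#' @return The transformed C3 vector.
#' @examples
#' w <- s6_to_c3(c(0.5, 0.5, 0.5, -2, -2, -2))
#' c3_reduce_step(w, 3, "real")
#' @export
c3_reduce_step <- function(w, component, part = c("real", "imaginary"), variant = 1) {
  part <- match.arg(part)
  w <- as.complex(w)
  if (!component %in% 1:3) abort("component must be 1, 2 or 3")
  boundary <- if (part == "real") component else component + 3L
  others <- setdiff(1:3, component)
  t0 <- if (part == "real") Re(w[component]) else Im(w[component])
  # step 1: negate the eliminated part, subtract it from its partner part
  if (part == "real") {
    w[component] <- complex(real = -t0, imaginary = Im(w[component]) - t0)
  } else {
    w[component] <- complex(real = Re(w[component]) - t0, imaginary = -t0)
  }
  # step 2: spread the eliminated value into both parts of the other two
  w[others] <- w[others] + t0 * (1 + 1i)
  # step 3: exchange the scalar pair tied to the negated vector
  slots <- edge_transform(boundary, variant)$swap_slots
  s <- c3_to_s6(w)
  s[slots] <- s[rev(slots)]
  s6_to_c3(s)
}

#' Canonical presentation in the C3 asymmetric unit
#'
#' Collapses the 24-fold orbit of a Selling-reduced vector to a single
#' representative: the three complex components sorted by non-decreasing
#' magnitude, with the real part not exceeding the imaginary part on the
#' first and second components (real/imaginary exchanges are applied in the
#' pairs required to stay inside the group; the part order of the third
#' component is then determined up to residual ties, which are broken by
#' lexicographic comparison of real then imaginary parts). All 24 reflections
#' of one presentation yield the identical canonical output, and the map is
#' idempotent. Note the collapse covers the 24-fold reflection ambiguity
#' only: a lattice sitting exactly on a sign boundary has additional reduced
#' presentations (new bases produced by the boundary's edge transform) that
#' form their own 24-orbits; comparing lattices across that degeneracy is the
#' job of the distance functions, not of the canonical form.
#'
#' @param w A Selling-reduced C3 vector (see [s6_to_c3()]).
#' @param tol Reduction tolerance passed to [is_reduced()].
#' @return The canonical C3 vector.
#' @examples
#' w <- s6_to_c3(c(0, -1, -3, -2, -5, -4))
#' canonical_presentation(w)
#' @export
canonical_presentation <- function(w, tol = NULL) {
  w <- as.complex(w)
  s <- c3_to_s6(w)
  if (!is_reduced(s, tol)) abort("canonical_presentation needs a Selling-reduced input; run selling_reduce first")
  canonical_search(s)
}

# orbit search shared by the C3 and S6 entry points: enumerate the 24 images,
# keep those satisfying the asymmetric-unit constraints, break residual ties
# lexicographically; reflections permute components exactly, so the candidate
# set (hence the winner) is identical for every start presentation
canonical_search <- function(s) {
  scale <- max(sqrt(sum(s^2)), .Machine$double.xmin)
  eps <- 1e-9 * scale
  cand <- lapply(s6_reflections(), function(op) apply_sym(op, s))
  keep <- vapply(cand, function(x) {
    m <- Mod(complex(real = x[1:3], imaginary = x[4:6]))
    all(diff(m) >= -eps) && x[1] <= x[4] + eps && x[2] <= x[5] + eps
  }, logical(1))
  if (!any(keep)) keep <- rep(TRUE, length(cand))  # unreachable safety net
  cand <- cand[keep]
  best <- cand[[1]]
  for (x in cand[-1]) {
    cmp <- x - best
    nz <- which(cmp != 0)
    if (length(nz) && cmp[nz[1]] < 0) best <- x
  }
  s6_to_c3(best)
}

# canonical S6 form: reduce if needed, then collapse the orbit; the workhorse
# equality test for "represents the same lattice"
canonical_s6 <- function(s, tol = NULL) {
  s <- as_s6(s)
  if (!is_reduced(s, tol)) s <- reduce_s6(s)
  c3_to_s6(canonical_search(s))
}

#' Random alternative presentations of a lattice
#'
#' Walks a reduced S6 vector out of the fundamental region by applying `k`
#' randomly chosen edge transforms (each its own inverse, so this is the
#' unreduction direction) followed by an optional random reflection. The
#' output represents the same lattice as the input; reducing it recovers a
#' vector in the same 24-fold orbit.
#'
#' @param s A numeric S6 vector (reduced or not; used as-is).
#' @param k Number of unreduction steps.
#' @param reflect Also apply a random reflection at the end?
#' @return An S6 vector.
#' @examples
#' set.seed(1)
#' unreduce_random(c(0, 0, 0, -100, -144, -400), k = 2)
#' @export
unreduce_random <- function(s, k = 1, reflect = TRUE) {
  s <- as_s6(s)
  for (i in seq_len(k)) {
    b <- sample.int(6, 1)
    v <- sample.int(2, 1)
    s <- as.numeric(edge_transform(b, v)$matrix %*% s)
  }
  if (reflect) s <- apply_sym(s6_reflections()[[sample.int(24, 1)]], s)
  s
}

#' Reduce a table of cells or S6 vectors
#'
#' Pipeline version of [selling_reduce()]: takes a cell table (columns
#' `a..gamma`) or an S6 table (columns `s1..s6`), reduces every row, and
#' returns a tibble of reduced Selling scalars with the iteration count per
#' row (and, for cell input, the reduced scalars' back-converted cell when
#' `as_cells = TRUE`).
#'
#' @param x A data frame of cells or of S6 vectors.
#' @param as_cells Return back-converted cell parameters instead of scalars?
#' @param ... Passed to [selling_reduce()].
#' @return A tibble with columns `s1..s6` (or `a..gamma`), `iterations`,
#'   `label`.
#' @examples
#' cell_tbl(1, 1, 1, 60, 60, 60) |> reduce_cells()
#' @export
reduce_cells <- function(x, as_cells = FALSE, ...) {
  m <- if (is.data.frame(x) && all(c("a", "alpha") %in% names(x))) {
    as_s6_matrix(cells_to_s6(x))
  } else {
    as_s6_matrix(x)
  }
  labs <- if (is.data.frame(x) && "label" %in% names(x)) as.character(x$label)
          else paste0("cell_", seq_len(nrow(m)))
  res <- lapply(seq_len(nrow(m)), function(i) selling_reduce(m[i, ], ...))
  red <- t(vapply(res, `[[`, numeric(6), "reduced"))
  out <- tibble::as_tibble(as.data.frame(red))
  names(out) <- paste0("s", 1:6)
  out$iterations <- vapply(res, `[[`, integer(1), "iterations")
  out$label <- labs
  if (as_cells) {
    cells <- s6_to_cells(out)
    cells$iterations <- out$iterations
    return(cells)
  }
  out
}
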