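# The 24 equivalent presentations of a Selling-reduced lattice.
#
# Because no ordering of the tetrahedron vectors (a, b, c, d) is preferred,
# each of the 4! = 24 permutations of the vectors permutes the six Selling
# scalars, giving 24 equivalent S6 presentations of the same lattice. The
# matrices are kept in the published table order (identity first) and are
# regenerated programmatically from the vector permutations; the test suite
# asserts the two sources agree.

# row notation: each row of the 6x6 matrix written as a 6-character 0/1 string
REFLECTION_ROWS <- c(
  "100000/010000/001000/000100/000010/000001",
  "100000/001000/010000/000100/000001/000010",
  "100000/000010/000001/000100/010000/001000",
  "100000/000001/000010/000100/001000/010000",
  "010000/100000/001000/000010/000100/000001",
  "010000/001000/100000/000010/000001/000100",
  "010000/000100/000001/000010/100000/001000",
  "010000/000001/000100/000010/001000/100000",
  "001000/100000/010000/000001/000100/000010",
  "001000/010000/100000/000001/000010/000100",
  "001000/000100/000010/000001/100000/010000",
  "001000/000010/000100/000001/010000/100000",
  "000100/010000/000001/100000/000010/001000",
  "000100/001000/000010/100000/000001/010000",
  "000100/000010/001000/100000/010000/000001",
  "000100/000001/010000/100000/001000/000010",
  "000010/100000/000001/010000/000100/001000",
  "000010/001000/000100/010000/000001/100000",
  "000010/000100/001000/010000/100000/000001",
  "000010/000001/100000/010000/001000/000100",
  "000001/100000/000010/001000/000100/010000",
  "000001/010000/000100/001000/000010/100000",
  "000001/000100/010000/001000/100000/000010",
  "000001/000010/100000/001000/010000/000100")

parse_row_notation <- function(rows) {
  m <- do.call(rbind, lapply(strsplit(rows, "/")[[1]], function(r) {
    as.integer(strsplit(r, "")[[1]])
  }))
  stopifnot(nrow(m) == 6, ncol(m) == 6)
  m
}

format_row_notation <- function(m) {
  paste(apply(round(m), 1, paste, collapse = ""), collapse = "/")
}

# the linear map on S6 induced by a transformation T of the four tetrahedron
# vectors (new_i = sum_j T[i, j] old_j): conjugate the Gram matrix and read
# off where each scalar lands; exact for integer T
s6_map_from_vector_transform <- function(tmat) {
  cols <- vapply(1:6, function(k) {
    e <- numeric(6); e[k] <- 1
    s6_from_gram(tmat %*% gram_from_s6(e) %*% t(tmat))
  }, numeric(6))
  round(cols)
}

perms4 <- function() {
  out <- list()
  for (i in 1:4) for (j in setdiff(1:4, i)) for (k in setdiff(1:4, c(i, j))) {
    out[[length(out) + 1]] <- c(i, j, k, setdiff(1:4, c(i, j, k)))
  }
  out
}

# the 24 reflection matrices regenerated from vector permutations, as a named
# list keyed by row notation (used by tests as the independent source)
generate_reflections_from_perms <- function() {
  res <- list()
  for (p in perms4()) {
    tmat <- matrix(0, 4, 4)
    tmat[cbind(1:4, p)] <- 1
    m <- s6_map_from_vector_transform(tmat)
    res[[format_row_notation(m)]] <- list(perm4 = p, matrix = m)
  }
  res
}

# C3 description of a reflection: where each complex component comes from and
# whether its real/imaginary parts are exchanged (the X operation)
c3_form_of <- function(m) {
  src <- apply(m, 1, function(r) which(r == 1))  # out_i = s[src[i]]
  from <- integer(3); x <- logical(3)
  for (j in 1:3) {
    pair <- c(src[j], src[j + 3])
    if (pair[1] <= 3 && pair[2] == pair[1] + 3) {
      from[j] <- pair[1]; x[j] <- FALSE
    } else if (pair[1] >= 4 && pair[2] == pair[1] - 3) {
      from[j] <- pair[2]; x[j] <- TRUE
    } else {
      abort("matrix does not map opposite scalar pairs to pairs")
    }
  }
  list(from = from, x = x,
       label = paste(vapply(1:3, function(j) {
         s <- paste0("c", from[j]); if (x[j]) s <- paste0("X(", s, ")")
         paste0("c", j, "<-", s)
       }, character(1)), collapse = ", "))
}

#' The 24 reflections of S6
#'
#' Returns the reflection group relating the equivalent presentations of a
#' Selling-reduced lattice: one 6x6 permutation matrix per permutation of the
#' Bravais-tetrahedron vectors (a, b, c, d), in the published table order with
#' the identity first. Each element records the matrix, the generating
#' 4-vector permutation, and its C3 form (a permutation of the three complex
#' components with real/imaginary exchange, the X operation, applied to an
#' even number of them).
#'
#' @return A list of 24 objects of class `s6_symop` with fields `index`,
#'   `name`, `matrix`, `perm4`, `c3` (list `from`, `x`, `label`).
#' @examples
#' length(s6_reflections())
#' s6_reflections()[[5]]$name # exchanges a and b
#' @export
s6_reflections <- function() {
  cached <- .selling_cache$reflections
  if (!is.null(cached)) return(cached)
  gen <- generate_reflections_from_perms()
  ops <- lapply(seq_along(REFLECTION_ROWS), function(i) {
    m <- parse_row_notation(REFLECTION_ROWS[i])
    key <- format_row_notation(m)
    g <- gen[[key]]
    if (is.null(g)) abort("internal: a transcribed reflection is not generated by any vector permutation")
    structure(list(
      index = i,
      name = paste(c("a", "b", "c", "d")[g$perm4], collapse = ""),
      matrix = m,
      perm4 = g$perm4,
      c3 = c3_form_of(m)
    ), class = "s6_symop")
  })
  .selling_cache$reflections <- ops
  ops
}

#' @export
print.s6_symop <- function(x, ...) {
  cat("<s6_symop ", x$index, "> vectors: ", x$name,
      "   C3: ", x$c3$label, "\n", sep = "")
  cat(format_row_notation(x$matrix), "\n")
  invisible(x)
}

#' Apply a reflection to an S6 or C3 vector
#'
#' `apply_sym()` applies one of the 24 reflections to an S6 vector (a
#' component permutation; the Euclidean norm is preserved exactly).
#' `apply_sym_c3()` applies the same operation in the complex form, using its
#' description as a permutation of (c1, c2, c3) with real/imaginary exchange
#' X(c) = i * Conj(c) where required; the two routes agree exactly.
#'
#' @param op An `s6_symop` (see [s6_reflections()]), or a 6x6 matrix.
#' @param s A numeric S6 vector.
#' @param w A complex C3 vector.
#' @return The transformed vector.
#' @examples
#' op <- s6_reflections()[[5]]
#' apply_sym(op, c(1, 2, 3, 4, 5, 6))
#' @export
apply_sym <- function(op, s) {
  m <- if (inherits(op, "s6_symop")) op$matrix else op
  as.numeric(m %*% as_s6(s))
}

#' @rdname apply_sym
#' @export
apply_sym_c3 <- function(op, w) {
  if (!inherits(op, "s6_symop")) abort("apply_sym_c3 needs an s6_symop (for its C3 form)")
  w <- as.complex(w)
  out <- w[op$c3$from]
  flip <- op$c3$x
  out[flip] <- 1i * Conj(out[flip])
  out
}

# all 24 reflection matrices stacked vertically (144 x 6); multiplying a 6 x m
# matrix of points gives all reflected images in one product -- the hot path
# of the distance algorithms
refl_stack <- function() {
  cached <- .selling_cache$refl_stack
  if (!is.null(cached)) return(cached)
  st <- do.call(rbind, lapply(s6_reflections(), `[[`, "matrix"))
  storage.mode(st) <- "double"
  .selling_cache$refl_stack <- st
  st
}
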