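#' Unit-cell parameter tables
#'
#' A unit cell is described by the edge lengths `a`, `b`, `c` (in Angstrom)
#' and the inter-axial angles `alpha`, `beta`, `gamma` (in degrees).
#' `cell_tbl()` builds a validated tibble of cells; `validate_cells()` checks
#' an existing data frame and returns it as a tibble (or fails with a message
#' naming the offending row and condition).
#'
#' A parameter set describes a genuine (non-degenerate) parallelepiped iff all
#' lengths are positive, every angle lies strictly between 0 and 180 degrees,
#' the three angles sum to less than 360 degrees, and each angle is smaller
#' than the sum of the other two (equivalently the metric tensor is positive
#' definite).
#'
#' @param a,b,c Cell edge lengths in Angstrom.
#' @param alpha,beta,gamma Inter-axial angles in degrees (`alpha` between b
#'   and c, `beta` between a and c, `gamma` between a and b).
#' @param label Optional identifier; defaults to `cell_1`, `cell_2`, ...
#' @return A tibble with columns `a, b, c, alpha, beta, gamma, label`.
#' @examples
#' cell_tbl(10, 12, 20, 90, 90, 90)
#' @export
cell_tbl <- function(a, b, c, alpha = 90, beta = 90, gamma = 90, label = NULL) {
  n <- max(length(a), length(b), length(c),
           length(alpha), length(beta), length(gamma))
  out <- tibble::tibble(
    a = rep_len(as.numeric(a), n),
    b = rep_len(as.numeric(b), n),
    c = rep_len(as.numeric(c), n),
    alpha = rep_len(as.numeric(alpha), n),
    beta  = rep_len(as.numeric(beta), n),
    gamma = rep_len(as.numeric(gamma), n),
    label = if (is.null(label)) paste0("cell_", seq_len(n)) else rep_len(as.character(label), n)
  )
  validate_cells(out)
}

#' @param cells A data frame with columns `a, b, c, alpha, beta, gamma` and
#'   optionally `label`.
#' @rdname cell_tbl
#' @export
validate_cells <- function(cells) {
  need <- c("a", "b", "c", "alpha", "beta", "gamma")
  missing_cols <- setdiff(need, names(cells))
  if (length(missing_cols)) {
    abort(paste0("cell table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  cells <- tibble::as_tibble(cells)
  if (!"label" %in% names(cells)) cells$label <- paste0("cell_", seq_len(nrow(cells)))
  for (i in seq_len(nrow(cells))) {
    chk <- cell_check(as.numeric(cells[i, need]))
    if (!is.null(chk)) abort(paste0("invalid cell in row ", i, " (", cells$label[i], "): ", chk))
  }
  cells
}

# returns NULL if valid, otherwise a message naming the violated condition
cell_check <- function(p) {
  if (any(!is.finite(p))) return("non-finite parameter")
  if (any(p[1:3] <= 0)) return("edge lengths must be positive")
  ang <- p[4:6]
  if (any(ang <= 0) || any(ang >= 180)) return("angles must lie strictly between 0 and 180 degrees")
  if (sum(ang) >= 360) return("angle sum must be below 360 degrees")
  if (ang[1] + ang[2] - ang[3] <= 0) return("alpha + beta - gamma must be positive")
  if (ang[1] - ang[2] + ang[3] <= 0) return("alpha - beta + gamma must be positive")
  if (-ang[1] + ang[2] + ang[3] <= 0) return("-alpha + beta + gamma must be positive")
  NULL
}

#' Basis vectors of a unit cell
#'
#' Builds a right-handed Cartesian basis for one unit cell using the standard
#' crystallographic frame (a along x, b in the xy plane), and appends the
#' Bravais-tetrahedron body diagonal d = -(a + b + c), so that the four
#' returned vectors sum to zero exactly.
#'
#' @param cell A numeric vector `c(a, b, c, alpha, beta, gamma)` (degrees) or
#'   a one-row data frame with those columns.
#' @return A 3 x 4 numeric matrix with columns `a`, `b`, `c`, `d`.
#' @examples
#' cell_to_basis(c(10, 12, 20, 90, 90, 90))
#' @export
cell_to_basis <- function(cell) {
  p <- as_cell_params(cell)
  chk <- cell_check(p)
  if (!is.null(chk)) abort(paste0("invalid cell: ", chk))
  # cospi/sinpi keep right angles exact (cospi(1/2) == 0)
  ca <- cospi(p[4] / 180); cb <- cospi(p[5] / 180)
  cg <- cospi(p[6] / 180); sg <- sinpi(p[6] / 180)
  av <- c(p[1], 0, 0)
  bv <- c(p[2] * cg, p[2] * sg, 0)
  cy <- (ca - cb * cg) / sg
  cz2 <- 1 - cb^2 - cy^2
  if (cz2 <= 0) {
    abort("invalid cell: angle combination gives a non-positive-definite metric tensor")
  }
  cv <- p[3] * c(cb, cy, sqrt(cz2))
  m <- cbind(a = av, b = bv, c = cv)
  cbind(m, d = -rowSums(m))
}

as_cell_params <- function(cell) {
  if (is.data.frame(cell)) {
    stopifnot(nrow(cell) == 1)
    cell <- as.numeric(cell[1, c("a", "b", "c", "alpha", "beta", "gamma")])
  }
  p <- as.numeric(cell)
  if (length(p) != 6) abort("a cell needs six parameters: a, b, c, alpha, beta, gamma")
  p
}

#' Selling scalars of a unit cell
#'
#' Maps a unit cell to its S6 vector: the six pairwise dot products among the
#' Bravais-tetrahedron vectors a, b, c and d = -(a + b + c), in the order
#' (b.c, a.c, a.b, a.d, b.d, c.d), all in Angstrom squared. A cell is Selling
#' reduced iff all six scalars are non-positive; orthorhombic cells give
#' exactly three zeros (the first three components).
#'
#' @inheritParams cell_to_basis
#' @return A numeric vector of length 6 (components `s1..s6`).
#' @examples
#' cell_to_s6(c(10, 12, 20, 90, 90, 90)) # 0 0 0 -100 -144 -400
#' @export
cell_to_s6 <- function(cell) {
  m <- cell_to_basis(cell)
  s6_from_gram(crossprod(m))
}

# S6 component k is the dot product of tetrahedron vectors PAIR_IDX[[k]],
# with (a, b, c, d) = (1, 2, 3, 4); this ordering constant pins the
# convention used everywhere in the package.
PAIR_IDX <- list(c(2L, 3L), c(1L, 3L), c(1L, 2L), c(1L, 4L), c(2L, 4L), c(3L, 4L))

# 4x4 Gram matrix of (a, b, c, d) from the six Selling scalars; the diagonal
# follows from a + b + c + d = 0
gram_from_s6 <- function(s) {
  g <- matrix(0, 4, 4)
  for (k in 1:6) {
    ij <- PAIR_IDX[[k]]
    g[ij[1], ij[2]] <- g[ij[2], ij[1]] <- s[k]
  }
  diag(g) <- c(-(s[2] + s[3] + s[4]),
               -(s[1] + s[3] + s[5]),
               -(s[1] + s[2] + s[6]),
               -(s[4] + s[5] + s[6]))
  g
}

s6_from_gram <- function(g) {
  vapply(PAIR_IDX, function(ij) g[ij[1], ij[2]], numeric(1))
}

#' Unit cell from Selling scalars
#'
#' Inverts [cell_to_s6()]: recovers cell lengths from the squared lengths
#' |a|^2 = -(s2+s3+s4), |b|^2 = -(s1+s3+s5), |c|^2 = -(s1+s2+s6) (which follow
#' from a+b+c+d = 0) and angles from the dot products. Fails with an explicit
#' error when the vector is not realizable as a lattice (non-positive implied
#' squared length, cosine outside (-1, 1), or metric tensor not positive
#' definite); it never returns NaN. No sorting is applied: the cell comes
#' back in the presentation encoded by the scalars.
#'
#' @param s A numeric S6 vector (length 6, Angstrom squared).
#' @return A numeric vector `c(a, b, c, alpha, beta, gamma)` (degrees).
#' @examples
#' s6_to_cell(c(0, 0, 0, -100, -144, -400)) # 10 12 20 90 90 90
#' @export
s6_to_cell <- function(s) {
  s <- as_s6(s)
  aa <- -(s[2] + s[3] + s[4])
  bb <- -(s[1] + s[3] + s[5])
  cc <- -(s[1] + s[2] + s[6])
  if (aa <= 0 || bb <= 0 || cc <= 0) {
    abort(sprintf(
      "S6 vector is not realizable: implied squared lengths (%.4g, %.4g, %.4g) must all be positive",
      aa, bb, cc))
  }
  al <- sqrt(aa); bl <- sqrt(bb); cl <- sqrt(cc)
  cosang <- c(s[1] / (bl * cl), s[2] / (al * cl), s[3] / (al * bl))
  if (any(abs(cosang) >= 1)) {
    abort("S6 vector is not realizable: an implied angle cosine lies outside (-1, 1)")
  }
  g3 <- matrix(c(aa, s[3], s[2],
                 s[3], bb, s[1],
                 s[2], s[1], cc), 3, 3)
  ev <- eigen(g3, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10 * max(abs(ev))) {
    abort("S6 vector is not realizable: implied metric tensor is not positive definite")
  }
  c(al, bl, cl, acos(cosang) * 180 / pi)
}

as_s6 <- function(s) {
  s <- as.numeric(s)
  if (length(s) != 6 || any(!is.finite(s))) abort("an S6 vector must be 6 finite numbers")
  s
}

# squared cell volume from the 3x3 metric tensor; a lattice invariant used to
# verify that reduction preserves the lattice
s6_volume <- function(s) {
  g <- gram_from_s6(s)[1:3, 1:3]
  d <- det(g)
  if (d < 0) d <- 0
  sqrt(d)
}

#' Complex (C3) form of an S6 vector
#'
#' C3 pairs each Selling scalar with its "opposite" (the scalar of the
#' complementary vector pair of the tetrahedron): c1 = s1 + i s4,
#' c2 = s2 + i s5, c3 = s3 + i s6. The two forms carry identical data; the
#' complex form makes the reflection group and the reduction steps easier to
#' state. Round trips are bit-exact.
#'
#' @param s A numeric S6 vector.
#' @param w A complex vector of length 3.
#' @return `s6_to_c3()`: a complex vector of length 3; `c3_to_s6()`: a numeric
#'   vector of length 6.
#' @examples
#' s6_to_c3(c(1, 2, 3, 4, 5, 6)) # 1+4i 2+5i 3+6i
#' @export
s6_to_c3 <- function(s) {
  s <- as.numeric(s)
  if (length(s) != 6) abort("an S6 vector must have 6 components")
  complex(real = s[1:3], imaginary = s[4:6])
}

#' @rdname s6_to_c3
#' @export
c3_to_s6 <- function(w) {
  w <- as.complex(w)
  if (length(w) != 3) abort("a C3 vector must have 3 complex components")
  c(Re(w), Im(w))
}

#' Convert between cell tables and S6 tables
#'
#' Data-frame versions of [cell_to_s6()] and [s6_to_cell()] for pipelines:
#' `cells_to_s6()` maps a table of cells to a table of Selling scalars
#' (columns `s1..s6`, one row per cell, labels preserved), and `s6_to_cells()`
#' maps back.
#'
#' @param cells A data frame of cells (see [cell_tbl()]).
#' @param s6 A data frame with columns `s1..s6` and optionally `label`.
#' @return A tibble.
#' @examples
#' cell_tbl(10, 12, 20, 90, 90, 90) |> cells_to_s6()
#' @export
cells_to_s6 <- function(cells) {
  cells <- validate_cells(cells)
  m <- t(vapply(seq_len(nrow(cells)), function(i) {
    cell_to_s6(as.numeric(cells[i, c("a", "b", "c", "alpha", "beta", "gamma")]))
  }, numeric(6)))
  out <- tibble::as_tibble(as.data.frame(m, col.names = paste0("s", 1:6)))
  names(out) <- paste0("s", 1:6)
  out$label <- cells$label
  out
}

#' @rdname cells_to_s6
#' @export
s6_to_cells <- function(s6) {
  m <- as_s6_matrix(s6)
  cells <- t(apply(m, 1, s6_to_cell))
  out <- tibble::as_tibble(as.data.frame(cells))
  names(out) <- c("a", "b", "c", "alpha", "beta", "gamma")
  out$label <- s6_labels(s6)
  validate_cells(out)
}

# accepts a data frame with s1..s6 columns or a plain numeric matrix
as_s6_matrix <- function(s6) {
  if (is.data.frame(s6)) {
    need <- paste0("s", 1:6)
    if (!all(need %in% names(s6))) abort("S6 table needs columns s1..s6")
    m <- as.matrix(s6[, need])
  } else {
    m <- as.matrix(s6)
    if (ncol(m) == 1 && nrow(m) == 6) m <- t(m)
  }
  if (ncol(m) != 6) abort("S6 data must have 6 columns")
  storage.mode(m) <- "double"
  m
}

s6_labels <- function(s6) {
  if (is.data.frame(s6) && "label" %in% names(s6)) as.character(s6$label)
  else paste0("cell_", seq_len(nrow(as_s6_matrix(s6))))
}

#' Read and write cell or S6 tables
#'
#' `read_cells()` reads a plain-text table, one cell per line, columns
#' `a b c alpha beta gamma [label]` (whitespace- or comma-delimited; `#`
#' starts a comment). `read_s6()` reads six numeric columns `s1..s6 [label]`
#' the same way. `write_cells()`/`write_s6()` write CSV.
#'
#' @param path File path.
#' @param x Table to write.
#' @return A validated tibble.
#' @export
read_cells <- function(path) {
  df <- read_delim_guess(path, 6)
  names(df)[1:6] <- c("a", "b", "c", "alpha", "beta", "gamma")
  if (ncol(df) >= 7) names(df)[7] <- "label"
  validate_cells(df[, seq_len(min(ncol(df), 7))])
}

#' @rdname read_cells
#' @export
read_s6 <- function(path) {
  df <- read_delim_guess(path, 6)
  names(df)[1:6] <- paste0("s", 1:6)
  if (ncol(df) >= 7) names(df)[7] <- "label"
  tibble::as_tibble(df[, seq_len(min(ncol(df), 7))])
}

read_delim_guess <- function(path, min_cols) {
  first <- readLines(path, n = 50)
  first <- first[!grepl("^\\s*(#|$)", first)]
  sep <- if (length(first) && grepl(",", first[1])) "," else ""
  df <- read.table(path, header = FALSE, sep = sep, comment.char = "#",
                   stringsAsFactors = FALSE, strip.white = TRUE)
  # tolerate a header line of column names
  if (!is.numeric(df[[1]])) {
    df <- read.table(path, header = TRUE, sep = sep, comment.char = "#",
                     stringsAsFactors = FALSE, strip.white = TRUE)
  }
  if (ncol(df) < min_cols) abort(paste0(path, ": expected at least ", min_cols, " columns"))
  for (j in seq_len(min_cols)) df[[j]] <- as.double(df[[j]])
  df
}

#' @rdname read_cells
#' @export
write_cells <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_cells
#' @export
write_s6 <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
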