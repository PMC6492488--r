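# Synthetic unit cells.
#
# Random cells are built from an explicit basis -- three independent uniform
# unit directions scaled by uniform edge lengths -- so every draw is a valid
# (positive-definite) cell by construction; a determinant guard on the unit
# directions excludes near-degenerate bases. Perturbed and unreduced modes
# emulate, respectively, measurement scatter around a parent polymorph and
# alternative unreduced presentations of one lattice.

random_unit_dirs <- function(min_det = 0.2) {
  repeat {
    u <- matrix(rnorm(9), 3, 3)
    u <- sweep(u, 2, sqrt(colSums(u^2)), "/")
    if (abs(det(u)) >= min_det) return(u)
  }
}

basis_to_cell <- function(b3) {
  b3 <- unname(b3)
  len <- sqrt(colSums(b3^2))
  cosang <- c(sum(b3[, 2] * b3[, 3]) / (len[2] * len[3]),
              sum(b3[, 1] * b3[, 3]) / (len[1] * len[3]),
              sum(b3[, 1] * b3[, 2]) / (len[1] * len[2]))
  cosang <- pmin(pmax(cosang, -1), 1)
  c(len, acos(cosang) * 180 / pi)
}

# n x 6 matrix of random valid cell parameters
random_cell_matrix <- function(n, length_range = c(10, 100)) {
  t(vapply(seq_len(n), function(i) {
    u <- random_unit_dirs()
    len <- runif(3, length_range[1], length_range[2])
    basis_to_cell(sweep(u, 2, len, "*"))
  }, numeric(6)))
}

#' Generate synthetic unit cells
#'
#' Three modes:
#'
#' * `"random"` — independent valid cells: basis vectors with uniform random
#'   directions (determinant of the unit directions kept away from zero) and
#'   edge lengths uniform in `length_range`.
#' * `"perturbed"` — noisy replicates of `base`: each basis vector of the
#'   parent cell is displaced by an isotropic Gaussian of standard deviation
#'   `sigma` times its length (so `sigma` is a relative noise level affecting
#'   lengths and angles alike); `sigma = 0` returns exact copies.
#' * `"unreduced_presentations"` — alternative presentations of the one
#'   lattice described by `base`: 1..`k_max` random inverse edge transforms
#'   followed by a random reflection, back-converted to cell parameters. All
#'   outputs are the same lattice, so every pairwise [cs6dist()] is zero.
#'
#' With a fixed `seed` the output is bit-identical across runs (the caller's
#' RNG state is restored afterwards). Generator settings are recorded in the
#' `provenance` attribute.
#'
#' @param n Number of cells.
#' @param mode `"random"`, `"perturbed"` or `"unreduced_presentations"`.
#' @param base Parent cell (six numbers or one-row data frame) for the
#'   perturbed and unreduced modes.
#' @param sigma Relative Gaussian noise level for `"perturbed"` (must be
#'   >= 0).
#' @param k_max Maximum number of unreduction steps for
#'   `"unreduced_presentations"`.
#' @param seed Optional integer seed.
#' @param length_range Edge-length range in Angstrom for `"random"`.
#' @return A validated cell tibble with a `provenance` attribute.
#' @examples
#' generate_cells(3, seed = 1)
#' generate_cells(3, mode = "perturbed", base = c(10, 12, 20, 90, 90, 90),
#'                sigma = 0.002, seed = 1)
#' @export
generate_cells <- function(n, mode = c("random", "perturbed", "unreduced_presentations"),
                           base = NULL, sigma = 0.01, k_max = 3, seed = NULL,
                           length_range = c(10, 100)) {
  mode <- match.arg(mode)
  if (n < 1) abort("n must be at least 1")
  if (!is.finite(sigma) || sigma < 0) abort("sigma must be a non-negative number")
  if (!is.null(seed)) {
    if (!is.finite(seed)) abort("seed must be a finite integer")
    old <- globalenv()$.Random.seed
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  if (mode != "random" && is.null(base)) abort(paste0("mode '", mode, "' needs a base cell"))
  params <- switch(mode,
    random = random_cell_matrix(n, length_range),
    perturbed = {
      b0 <- cell_to_basis(base)[, 1:3]
      len0 <- sqrt(colSums(b0^2))
      t(vapply(seq_len(n), function(i) {
        noise <- matrix(rnorm(9), 3, 3) %*% diag(sigma * len0)
        basis_to_cell(b0 + noise)
      }, numeric(6)))
    },
    unreduced_presentations = {
      s0 <- cell_to_s6(base)
      t(vapply(seq_len(n), function(i) {
        s6_to_cell(unreduce_random(s0, k = sample.int(k_max, 1), reflect = TRUE))
      }, numeric(6)))
    })
  out <- tibble::as_tibble(as.data.frame(params))
  names(out) <- c("a", "b", "c", "alpha", "beta", "gamma")
  out$label <- sprintf("%s_%03d", sub("_presentations$", "", mode), seq_len(n))
  out <- validate_cells(out)
  attr(out, "provenance") <- list(mode = mode, n = n, seed = seed, sigma = sigma,
                                  k_max = k_max, length_range = length_range,
                                  base = if (is.null(base)) NULL else as_cell_params(base))
  out
}
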