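# shared fixtures and oracles, all built in code

ORTHO_CELL <- c(10, 12, 20, 90, 90, 90)
ORTHO_S6 <- c(0, 0, 0, -100, -144, -400)
RHOMB60_S6 <- c(0.5, 0.5, 0.5, -2, -2, -2)

canon <- function(s) sellingr:::canonical_s6(s)

# random valid cell parameter matrix (n x 6) under a local seed
rand_cell_mat <- function(n, seed) {
  withr::with_seed(seed, sellingr:::random_cell_matrix(n))
}

# independent oracle for the Selling scalars: metric-tensor construction
# G[i, j] = l_i l_j cos(angle_ij), extended by d = -(a + b + c), without
# touching cell_to_basis
s6_oracle_from_cell <- function(p) {
  l <- p[1:3]
  ca <- cos(p[4:6] * pi / 180) # alpha (b,c), beta (a,c), gamma (a,b)
  g <- matrix(0, 3, 3)
  diag(g) <- l^2
  g[2, 3] <- g[3, 2] <- l[2] * l[3] * ca[1]
  g[1, 3] <- g[3, 1] <- l[1] * l[3] * ca[2]
  g[1, 2] <- g[2, 1] <- l[1] * l[2] * ca[3]
  ad <- -sum(g[1, ]); bd <- -sum(g[2, ]); cd <- -sum(g[3, ])
  c(g[2, 3], g[1, 3], g[1, 2], ad, bd, cd)
}

# brute-force reduction oracle: explore every reduction path (any positive
# scalar, either variant) and collect the canonical forms of all terminal
# reduced states
brute_reduce_canonicals <- function(s, tol = 1e-10, max_depth = 12) {
  ets <- s6_edge_transforms()
  out <- new.env(parent = emptyenv())
  recurse <- function(v, depth) {
    if (max(v) <= tol * max(1, sqrt(sum(v^2)))) {
      key <- paste(signif(canon(v), 10), collapse = ",")
      assign(key, TRUE, envir = out)
      return(invisible())
    }
    if (depth >= max_depth) stop("oracle depth exceeded")
    for (b in which(v > tol * max(1, sqrt(sum(v^2))))) {
      for (variant in 1:2) {
        m <- ets[[2 * (b - 1) + variant]]$matrix
        recurse(as.numeric(m %*% v), depth + 1)
      }
    }
  }
  recurse(s, 0)
  ls(out)
}
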