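# Unit-cell clustering on the S6 metric.
#
# Serial-crystallography pipelines collect one (partial) cell per diffraction
# image and group images by lattice before merging; agglomerative clustering
# on a lattice-aware distance keeps polymorphs apart that plain cell-parameter
# distances can blur near 90 degrees.

#' Agglomerative clustering of unit cells
#'
#' Computes (or accepts) a pairwise lattice-distance matrix and runs standard
#' agglomerative clustering ([stats::hclust]); `hclust` merges the closest
#' pair at each step, with exactly tied merge heights resolved by the lowest
#' pair index, so results are deterministic. Cut the tree by cluster count
#' `k` or height `h` to obtain assignments.
#'
#' @param x A cell table (columns `a..gamma`), an S6 table (`s1..s6`), or a
#'   precomputed [stats::dist] object.
#' @param method Linkage: `"average"` (default), `"single"` or `"complete"`.
#' @param k Desired number of clusters (optional).
#' @param h Cut height in Angstrom squared (optional).
#' @param strategy Distance strategy when `x` is a table (see [cs6dist()]).
#' @return An object of class `cell_clustering`: list with `hclust`, `dist`,
#'   `method`, `strategy`, `assignments` (tibble `label`, `cluster`; NULL
#'   when neither `k` nor `h` is given).
#' @examples
#' set.seed(1)
#' cells <- generate_cells(6, mode = "perturbed",
#'                         base = c(10, 12, 20, 90, 90, 90), sigma = 0.002)
#' cl <- cluster_cells(cells, k = 1)
#' glance(cl)
#' @export
cluster_cells <- function(x, method = c("average", "single", "complete"),
                          k = NULL, h = NULL,
                          strategy = c("vcp1", "vcp2", "euclidean", "mirror")) {
  method <- match.arg(method)
  strategy <- match.arg(strategy)
  d <- if (inherits(x, "dist")) x else distance_matrix(x, strategy = strategy)
  n <- attr(d, "Size")
  if (is.null(n) || n < 1) abort("empty input: nothing to cluster")
  labs <- attr(d, "Labels") %||% paste0("cell_", seq_len(n))
  if (n == 1) {
    assignments <- tibble::tibble(label = labs, cluster = 1L)
    return(structure(list(hclust = NULL, dist = d, method = method,
                          strategy = strategy, assignments = assignments,
                          k = 1L, h = h), class = "cell_clustering"))
  }
  hc <- hclust(d, method = method)
  assignments <- NULL
  if (!is.null(k) || !is.null(h)) {
    cl <- if (!is.null(k)) cutree(hc, k = k) else cutree(hc, h = h)
    assignments <- tibble::tibble(label = labs, cluster = as.integer(cl))
  }
  structure(list(hclust = hc, dist = d, method = method, strategy = strategy,
                 assignments = assignments, k = k, h = h),
            class = "cell_clustering")
}

#' @export
print.cell_clustering <- function(x, ...) {
  n <- attr(x$dist, "Size")
  cat("<cell_clustering> ", n, " cells, ", x$method, " linkage on ",
      x$strategy, " distances\n", sep = "")
  if (!is.null(x$assignments)) {
    cat("clusters:", paste(table(x$assignments$cluster), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.cell_clustering <- function(x, ...) {
  if (is.null(x$hclust)) {
    return(tibble::tibble(step = integer(), left = integer(), right = integer(),
                          height = numeric()))
  }
  m <- x$hclust$merge
  tibble::tibble(step = seq_len(nrow(m)), left = m[, 1], right = m[, 2],
                 height = x$hclust$height)
}

#' @export
glance.cell_clustering <- function(x, ...) {
  tibble::tibble(
    n = attr(x$dist, "Size"),
    method = x$method,
    strategy = x$strategy,
    max_height = if (is.null(x$hclust)) 0 else max(x$hclust$height),
    n_clusters = if (is.null(x$assignments)) NA_integer_
                 else length(unique(x$assignments$cluster)))
}

#' Newick export of a cell dendrogram
#'
#' Converts the merge tree to a `phylo` object (via the ape package) and
#' returns, or writes, its Newick representation.
#'
#' @param x A `cell_clustering` (with at least two cells).
#' @param path Optional file path; when NULL the Newick string is returned.
#' @export
as_newick <- function(x, path = NULL) {
  if (is.null(x$hclust)) abort("need at least two cells for a dendrogram")
  phy <- ape::as.phylo(x$hclust)
  if (is.null(path)) ape::write.tree(phy) else {
    ape::write.tree(phy, file = path)
    invisible(path)
  }
}

# x/y segments of an hclust dendrogram, computed from the merge matrix
dendro_segments <- function(hc) {
  n <- length(hc$order)
  leaf_x <- numeric(n)
  leaf_x[hc$order] <- seq_len(n)
  node_x <- numeric(nrow(hc$merge))
  node_y <- hc$height
  segs <- list()
  xy <- function(id) {
    if (id < 0) c(leaf_x[-id], 0) else c(node_x[id], node_y[id])
  }
  for (i in seq_len(nrow(hc$merge))) {
    l <- xy(hc$merge[i, 1]); r <- xy(hc$merge[i, 2])
    node_x[i] <- (l[1] + r[1]) / 2
    segs[[length(segs) + 1]] <- data.frame(
      x = c(l[1], l[1], r[1]), xend = c(l[1], r[1], r[1]),
      y = c(l[2], node_y[i], node_y[i]), yend = c(node_y[i], node_y[i], r[2]))
  }
  do.call(rbind, segs)
}

#' @export
autoplot.cell_clustering <- function(object, ...) {
  if (is.null(object$hclust)) abort("nothing to plot for a single cell")
  hc <- object$hclust
  segs <- dendro_segments(hc)
  leaves <- data.frame(x = seq_along(hc$order), y = 0,
                       label = hc$labels[hc$order])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend),
                          linewidth = 0.3) +
    ggplot2::geom_text(data = leaves,
                       ggplot2::aes(x = .data$x, y = .data$y, label = .data$label),
                       angle = 90, hjust = 1.1, size = 2.5) +
    ggplot2::scale_y_continuous(expand = ggplot2::expansion(mult = c(0.25, 0.05))) +
    ggplot2::labs(x = NULL, y = expression("merge height (" * ring(A)^2 * ")"),
                  title = paste0("Cell dendrogram (", object$method, " linkage, ",
                                 object$strategy, ")")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid.major.x = ggplot2::element_blank())
}

#' @export
tidy.selling_reduction <- function(x, ...) x$ops_applied

#' @export
glance.selling_reduction <- function(x, ...) {
  tibble::tibble(iterations = x$iterations,
                 neg_sum_before = -sum(x$input),
                 neg_sum_after = -sum(x$reduced),
                 max_component = max(x$reduced))
}
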