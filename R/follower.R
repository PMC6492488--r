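# The Follower validation scan.
#
# A straight line is drawn in S6 from an (unreduced) start point to its
# Selling-reduced image, and the lattice distance from each sample on the
# line to the endpoint is recorded. Because start and endpoint describe the
# same lattice, a correct metric gives zero distance at both ends, and a
# continuous trace in between with slope breaks only at boundary crossings;
# deviations expose defects in a distance implementation.

#' Distance trace along the reduction segment
#'
#' Samples `n_samples` evenly spaced points on the straight S6 segment from
#' `start` to its reduced image, Selling-reduces each sample (so distances
#' are evaluated between valid fundamental-unit presentations; disable with
#' `reduce_samples = FALSE` to scan the raw segment), and records the
#' distance to the endpoint under the chosen strategy.
#'
#' @param start An S6 vector (typically unreduced; see [unreduce_random()])
#'   or a unit cell.
#' @param n_samples Number of samples including both ends (>= 2).
#' @param strategy Distance strategy (see [cs6dist()]).
#' @param reduce_samples Reduce each sample before measuring the distance?
#' @return An object of class `follower_trace`: list with `samples` (tibble
#'   `t`, `distance`), `start`, `endpoint`, `strategy`, `step_length`,
#'   `reduce_samples`.
#' @examples
#' set.seed(2)
#' s0 <- unreduce_random(cell_to_s6(c(10, 12, 20, 90, 90, 90)), k = 2)
#' tr <- follower_trace(s0, n_samples = 50)
#' follower_qc(tr)
#' @export
follower_trace <- function(start, n_samples = 200,
                           strategy = c("vcp1", "vcp2", "euclidean", "mirror"),
                           reduce_samples = TRUE) {
  strategy <- match.arg(strategy)
  if (n_samples < 2) abort("n_samples must be at least 2")
  s0 <- coerce_to_s6(start)
  s1 <- reduce_s6(s0)
  ts <- seq(0, 1, length.out = n_samples)
  cand_end <- vcp_candidates(s1)
  dist_to_end <- function(x) {
    switch(strategy,
      vcp1 = min(sqrt(max(min(colSums((cand_end - x)^2)), 0)),
                 sqrt(max(min(colSums((vcp_candidates(x) - s1)^2)), 0))),
      vcp2 = min(d12_one_sided(cand_end, x)[2],
                 d12_one_sided(vcp_candidates(x), s1)[2]),
      euclidean = dist_euclidean(x, s1)$distance,
      mirror = dist_mirror(x, s1)$distance)
  }
  pts <- matrix(0, n_samples, 6)
  d <- numeric(n_samples)
  degenerate <- identical(s0, s1)  # already reduced start: a zero-length segment
  for (i in seq_along(ts)) {
    x <- if (degenerate) s1 else (1 - ts[i]) * s0 + ts[i] * s1
    if (reduce_samples) x <- reduce_s6(x)
    pts[i, ] <- x
    d[i] <- dist_to_end(x)
  }
  structure(list(
    samples = tibble::tibble(t = ts, distance = d),
    points = pts,
    start = s0, endpoint = s1, strategy = strategy,
    step_length = sqrt(sum((s0 - s1)^2)) / (n_samples - 1),
    reduce_samples = reduce_samples
  ), class = "follower_trace")
}

#' Quality control of a Follower trace
#'
#' Checks the signatures of a well-behaved lattice metric on a trace from
#' [follower_trace()]: (near-)zero distance at both ends of the scan,
#' 1-Lipschitz continuity, and a count of slope-sign discontinuities
#' (legitimate ones occur only at boundary crossings, so the count should be
#' small). The distance is an exact 1-Lipschitz function of the point it is
#' evaluated at (every candidate map is an isometry), so the continuity bound
#' compares each jump `|d[i+1] - d[i]|` against the distance actually moved
#' by the evaluated sample points, `|r[i+1] - r[i]|`, floored at the raw
#' segment step. (When samples are Selling-reduced first — the default — the
#' evaluated points can move faster than the raw segment, because the
#' reduction matrices are non-orthogonal; `max_jump_step_ratio` reports how
#' much faster, as a diagnostic.) A two-sample trace is checked for endpoints
#' only; continuity is then vacuously true.
#'
#' @param trace A `follower_trace`.
#' @param tol Endpoint-zero tolerance (default 1e-8 times the start norm).
#' @return An object of class `follower_qc`: list with `endpoint_zero`,
#'   `max_jump`, `max_jump_step_ratio`, `lipschitz_ok`, `n_slope_breaks`,
#'   `pass`.
#' @export
follower_qc <- function(trace, tol = NULL) {
  d <- trace$samples$distance
  scale <- max(sqrt(sum(trace$start^2)), 1)
  if (is.null(tol)) tol <- 1e-8 * scale
  endpoint_zero <- d[1] <= tol && d[length(d)] <= tol
  jumps <- abs(diff(d))
  max_jump <- if (length(jumps)) max(jumps) else 0
  point_steps <- if (!is.null(trace$points)) {
    sqrt(rowSums((trace$points[-1, , drop = FALSE] -
                  trace$points[-nrow(trace$points), , drop = FALSE])^2))
  } else {
    rep(trace$step_length, length(jumps))
  }
  bounds <- 1.0001 * pmax(point_steps, trace$step_length) + 1e-12 * scale
  lipschitz_ok <- length(d) <= 2 || all(jumps <= bounds)
  max_jump_step_ratio <- if (trace$step_length > 0) max_jump / trace$step_length else 0
  slopes <- diff(d)
  slopes[abs(slopes) <= 1e-9 * scale] <- 0
  sgn <- sign(slopes)
  sgn <- sgn[sgn != 0]
  n_breaks <- if (length(sgn) > 1) sum(diff(sgn) != 0) else 0L
  structure(list(
    endpoint_zero = endpoint_zero,
    endpoint_values = c(d[1], d[length(d)]),
    tol = tol,
    max_jump = max_jump,
    max_jump_step_ratio = max_jump_step_ratio,
    lipschitz_ok = lipschitz_ok,
    n_slope_breaks = n_breaks,
    pass = endpoint_zero && lipschitz_ok
  ), class = "follower_qc")
}

#' @export
print.follower_qc <- function(x, ...) {
  cat("<follower_qc> ", if (x$pass) "PASS" else "FAIL", "\n", sep = "")
  cat(sprintf("  endpoint zero: %s (values %.3g, %.3g; tol %.3g)\n",
              x$endpoint_zero, x$endpoint_values[1], x$endpoint_values[2], x$tol))
  cat(sprintf("  continuity: %s (max jump %.4g, %.3g x segment step)\n",
              if (x$lipschitz_ok) "ok" else "violated", x$max_jump, x$max_jump_step_ratio))
  cat("  slope-sign breaks:", x$n_slope_breaks, "\n")
  invisible(x)
}

#' @export
print.follower_trace <- function(x, ...) {
  cat("<follower_trace> ", nrow(x$samples), " samples, strategy ", x$strategy, "\n", sep = "")
  print(head(x$samples, 4))
  invisible(x)
}

#' @export
tidy.follower_trace <- function(x, ...) x$samples

#' @export
glance.follower_trace <- function(x, ...) {
  qc <- follower_qc(x)
  tibble::tibble(n_samples = nrow(x$samples), strategy = x$strategy,
                 step_length = x$step_length, max_distance = max(x$samples$distance),
                 endpoint_zero = qc$endpoint_zero, lipschitz_ok = qc$lipschitz_ok,
                 n_slope_breaks = qc$n_slope_breaks)
}

#' @export
autoplot.follower_trace <- function(object, ...) {
  ggplot2::ggplot(object$samples, ggplot2::aes(x = .data$t, y = .data$distance)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = "position along segment (t)",
                  y = expression("distance to endpoint (" * ring(A)^2 * ")"),
                  title = paste0("Follower trace (", object$strategy, ")")) +
    ggplot2::theme_minimal()
}
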