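#' Parameters for the synthetic FRC network generator
#'
#' The reticular network is grown as a set of random-walk fibres: seed points
#' are scattered uniformly, each fibre advances in fixed micrometre steps with
#' Gaussian angular jitter, and at every step it may spawn a daughter branch
#' at roughly 60 degrees. A walk terminates when it leaves the field, exhausts
#' its exponential length budget, or would come within merging distance of a
#' fibre it does not belong to (collision avoidance keeps the generative graph
#' and the rasterized network topologically consistent).
#'
#' @param field_size_px integer pair (rows, cols), both >= 32.
#' @param pixel_size_um pixel edge length, micrometres.
#' @param fiber_density expected number of fibre seeds per 100 x 100 um tile.
#' @param branch_length_scale_um mean of the exponential length budget of a
#'   walk, micrometres.
#' @param fiber_width_px rendered fibre width (odd positive integer).
#' @param branch_prob per-step probability of spawning a daughter branch.
#' @param step_um walk step length, micrometres.
#' @param angle_jitter_sd per-step direction jitter, radians.
#' @param seed integer seed; fully determines the output.
#' @return a `network_params` list.
#' @export
network_params <- function(field_size_px = c(512L, 512L), pixel_size_um = 1,
                           fiber_density = 2, branch_length_scale_um = 60,
                           fiber_width_px = 3L, branch_prob = 0.05,
                           step_um = 2, angle_jitter_sd = 0.25, seed = 1L) {
  if (length(field_size_px) != 2L || any(field_size_px < 32))
    stop_param("field_size_px must be a pair of integers >= 32")
  check_number(pixel_size_um, "pixel_size_um", 0, strict = TRUE)
  check_number(fiber_density, "fiber_density", 0)
  check_number(branch_length_scale_um, "branch_length_scale_um", 0, strict = TRUE)
  if (fiber_width_px < 1 || fiber_width_px %% 2 != 1)
    stop_param("fiber_width_px must be a positive odd integer")
  structure(list(field_size_px = as.integer(field_size_px),
                 pixel_size_um = pixel_size_um, fiber_density = fiber_density,
                 branch_length_scale_um = branch_length_scale_um,
                 fiber_width_px = as.integer(fiber_width_px),
                 branch_prob = branch_prob, step_um = step_um,
                 angle_jitter_sd = angle_jitter_sd, seed = as.integer(seed)),
            class = "network_params")
}

# paint the pixels of a segment (um coords) into an occupancy matrix; returns
# the linear indices painted. Sampling at 0.4 px guarantees 8-connectivity.
segment_pixels <- function(p0, p1, nrow_px, ncol_px, pixel_size_um) {
  len_px <- sqrt(sum((p1 - p0)^2)) / pixel_size_um
  n <- max(2L, ceiling(len_px / 0.4) + 1L)
  t <- seq(0, 1, length.out = n)
  r <- pmin(pmax(round((p0[1] + t * (p1[1] - p0[1])) / pixel_size_um + 0.5), 1), nrow_px)
  c <- pmin(pmax(round((p0[2] + t * (p1[2] - p0[2])) / pixel_size_um + 0.5), 1), ncol_px)
  unique(r + (c - 1L) * nrow_px)
}

#' Generate a synthetic FRC fibre network with ground truth
#'
#' Grows the random-walk fibre system of [network_params()], rasterizes it at
#' the requested width, and reports the morphometry of the generative graph
#' *before* rasterization: branch count (maximal paths between endpoints and
#' branch points), junction count, and total fibre length.
#'
#' @param params a [network_params()].
#' @return a list with `raster` (0/1 integer matrix), `truth` (tibble-free
#'   list: `n_branches`, `n_junctions`, `total_length_um`,
#'   `mean_branch_length_um`, `n_fibers`), and `params`.
#' @export
generate_frc_network <- function(params) {
  stopifnot(inherits(params, "network_params"))
  withr::with_seed(params$seed, generate_frc_network_impl(params))
}

generate_frc_network_impl <- function(params) {
  nr <- params$field_size_px[1]; nc <- params$field_size_px[2]
  px <- params$pixel_size_um
  h_um <- nr * px; w_um <- nc * px
  n_seeds <- stats::rpois(1, params$fiber_density * h_um * w_um / 1e4)

  occ <- matrix(0L, nr, nc)            # centreline occupancy: walk id
  # generative graph: vertices are step points; edges join consecutive points
  vx <- numeric(0); vy <- numeric(0)
  edge_a <- integer(0); edge_b <- integer(0); edge_len <- numeric(0)
  n_v <- 0L
  merge_dist_px <- params$fiber_width_px + 1  # centrelines closer than this would fuse

  # queue of walks: list(start (um), angle, start_vertex (0 = new), parent_id)
  queue <- vector("list", 0)
  if (n_seeds > 0) {
    for (i in seq_len(n_seeds)) {
      queue[[length(queue) + 1L]] <- list(
        p = c(stats::runif(1, 0, h_um), stats::runif(1, 0, w_um)),
        ang = stats::runif(1, 0, 2 * pi), v0 = 0L, parent = 0L)
    }
  }
  max_walks <- max(1L, n_seeds) * 8L
  walk_id <- 0L
  win <- ceiling(merge_dist_px)  # collision search window (px)

  collides <- function(r, c, self_id, parent_id, ignore_parent) {
    r0 <- max(1L, r - win); r1 <- min(nr, r + win)
    c0 <- max(1L, c - win); c1 <- min(nc, c + win)
    block <- occ[r0:r1, c0:c1]
    ids <- block[block != 0L]
    if (!length(ids)) return(FALSE)
    ids <- ids[ids != self_id]
    if (ignore_parent) ids <- ids[ids != parent_id]
    if (!length(ids)) return(FALSE)
    # exact distance check within the window
    idx <- which(block != 0L & block != self_id &
                   (!ignore_parent | block != parent_id), arr.ind = TRUE)
    if (!nrow(idx)) return(FALSE)
    dr <- idx[, 1] + r0 - 1L - r; dc <- idx[, 2] + c0 - 1L - c
    any(dr * dr + dc * dc < merge_dist_px^2)
  }

  qi <- 1L
  while (qi <= length(queue) && length(queue) <= max_walks) {
    w <- queue[[qi]]; qi <- qi + 1L
    walk_id <- walk_id + 1L
    p <- w$p; ang <- w$ang
    budget <- stats::rexp(1, 1 / params$branch_length_scale_um)
    budget <- max(budget, 4 * params$step_um)   # avoid degenerate stubs
    n_steps <- ceiling(budget / params$step_um)
    r <- min(max(round(p[1] / px + 0.5), 1L), nr)
    c <- min(max(round(p[2] / px + 0.5), 1L), nc)
    # a seed landing on an existing fibre would silently fuse; drop it
    if (w$v0 == 0L && collides(r, c, walk_id, 0L, ignore_parent = FALSE)) next
    # register the start vertex
    if (w$v0 == 0L) {
      n_v <- n_v + 1L; vx[n_v] <- p[1]; vy[n_v] <- p[2]; v_prev <- n_v
    } else v_prev <- w$v0
    if (occ[r, c] == 0L) occ[r, c] <- walk_id
    edge_start <- length(edge_a)
    v_start <- n_v
    accepted <- 0L
    for (s in seq_len(n_steps)) {
      ang <- ang + stats::rnorm(1, 0, params$angle_jitter_sd)
      p_new <- p + params$step_um * c(cos(ang), sin(ang))
      if (p_new[1] < 0 || p_new[1] > h_um || p_new[2] < 0 || p_new[2] > w_um) break
      r_new <- min(max(round(p_new[1] / px + 0.5), 1L), nr)
      c_new <- min(max(round(p_new[2] / px + 0.5), 1L), nc)
      if (collides(r_new, c_new, walk_id, w$parent, ignore_parent = s <= 3L)) break
      # accept the step: vertex, edge, paint centreline pixels
      n_v <- n_v + 1L; vx[n_v] <- p_new[1]; vy[n_v] <- p_new[2]
      edge_a <- c(edge_a, v_prev); edge_b <- c(edge_b, n_v)
      edge_len <- c(edge_len, params$step_um)
      pix <- segment_pixels(p, p_new, nr, nc, px)
      pix <- pix[occ[pix] == 0L]
      occ[pix] <- walk_id
      # maybe spawn a daughter branch from the new vertex
      if (length(queue) < max_walks && accepted >= 2L &&
          stats::runif(1) < params$branch_prob && s < n_steps) {
        side <- sample(c(-1, 1), 1)
        queue[[length(queue) + 1L]] <- list(
          p = p_new, ang = ang + side * (pi / 3 + stats::rnorm(1, 0, 0.1)),
          v0 = n_v, parent = walk_id)
      }
      p <- p_new; v_prev <- n_v
      accepted <- accepted + 1L
    }
    # a daughter killed before establishing itself would plant a junction in
    # the truth graph that pruning removes from the skeleton; roll it back
    if (w$parent != 0L && accepted < 2L) {
      keep <- seq_len(edge_start)
      edge_a <- edge_a[keep]; edge_b <- edge_b[keep]; edge_len <- edge_len[keep]
      n_v <- v_start
      occ[occ == walk_id] <- 0L
    }
  }

  truth <- graph_truth(n_v, edge_a, edge_b, edge_len, n_fibers = walk_id)
  raster <- matrix(0L, nr, nc)
  raster[occ != 0L] <- 1L
  if (params$fiber_width_px > 1 && any(raster == 1L)) {
    brush <- EBImage::makeBrush(params$fiber_width_px, shape = "disc")
    raster <- matrix(as.integer(EBImage::dilate(raster, brush) > 0), nr, nc)
  }
  list(raster = raster, truth = truth, params = params)
}

# morphometry of the generative step-point graph: contracting degree-2
# vertices merges two incident edges into one, so for an acyclic graph the
# number of maximal branches is E - (#degree-2 vertices).
graph_truth <- function(n_v, edge_a, edge_b, edge_len, n_fibers) {
  if (n_v == 0L || length(edge_a) == 0L) {
    return(list(n_branches = 0L, n_junctions = 0L, total_length_um = 0,
                mean_branch_length_um = NA_real_, n_fibers = n_fibers))
  }
  deg <- tabulate(c(edge_a, edge_b), nbins = n_v)
  n_branches <- length(edge_a) - sum(deg == 2L)
  list(n_branches = as.integer(n_branches),
       n_junctions = sum(deg >= 3L),
       total_length_um = sum(edge_len),
       mean_branch_length_um = sum(edge_len) / max(n_branches, 1L),
       n_fibers = n_fibers)
}
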