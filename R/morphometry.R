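#' Morphological thinning (Zhang-Suen)
#'
#' Reduces a binary raster to an 8-connected, one-pixel-wide skeleton by the
#' classical two-subiteration thinning algorithm. The operation is idempotent:
#' thinning a skeleton returns it unchanged.
#'
#' @param mask binary matrix (anything nonzero is foreground).
#' @return 0/1 integer matrix of the same size.
#' @export
thin_skeleton <- function(mask) {
  m <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- as.integer(mask != 0)
  nr <- nrow(m); nc <- ncol(m)
  core_r <- 2:(nr - 1L); core_c <- 2:(nc - 1L)
  shift <- function(x, dr, dc) x[core_r + dr, core_c + dc]
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p <- m[core_r, core_c]
      p2 <- shift(m, -1L, 0L); p3 <- shift(m, -1L, 1L); p4 <- shift(m, 0L, 1L)
      p5 <- shift(m, 1L, 1L); p6 <- shift(m, 1L, 0L); p7 <- shift(m, 1L, -1L)
      p8 <- shift(m, 0L, -1L); p9 <- shift(m, -1L, -1L)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (p2 == 0L & p3 == 1L) + (p3 == 0L & p4 == 1L) +
           (p4 == 0L & p5 == 1L) + (p5 == 0L & p6 == 1L) +
           (p6 == 0L & p7 == 1L) + (p7 == 0L & p8 == 1L) +
           (p8 == 0L & p9 == 1L) + (p9 == 0L & p2 == 1L)
      if (step == 1) {
        cond <- p == 1L & B >= 2L & B <= 6L & A == 1L &
          p2 * p4 * p6 == 0L & p4 * p6 * p8 == 0L
      } else {
        cond <- p == 1L & B >= 2L & B <= 6L & A == 1L &
          p2 * p4 * p8 == 0L & p2 * p6 * p8 == 0L
      }
      if (any(cond)) {
        sub <- m[core_r, core_c]; sub[cond] <- 0L; m[core_r, core_c] <- sub
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m[core_r, core_c]
}

# Skeleton pixel adjacency uses m-adjacency: orthogonal neighbours always
# count; a diagonal neighbour counts only when the two shared orthogonal
# pixels are background. This removes the double links of staircase pixels
# that morphological thinning leaves behind, so chain pixels have degree 2.
neighbour_count <- function(sk) {
  m <- matrix(0L, nrow(sk) + 2L, ncol(sk) + 2L)
  m[2:(nrow(sk) + 1L), 2:(ncol(sk) + 1L)] <- sk
  core_r <- 2:(nrow(m) - 1L); core_c <- 2:(ncol(m) - 1L)
  sh <- function(dr, dc) m[core_r + dr, core_c + dc]
  out <- sh(-1, 0) + sh(1, 0) + sh(0, -1) + sh(0, 1)
  for (d in list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))) {
    diagn <- sh(d[1], d[2])
    out <- out + (diagn == 1L & sh(d[1], 0) == 0L & sh(0, d[2]) == 0L)
  }
  out
}

#' Skeletonize a binary network and extract its branch graph
#'
#' Thins the raster to a 1-px skeleton, then builds a graph whose nodes are
#' endpoints (one skeleton neighbour) and junctions (three or more; adjacent
#' junction pixels are merged into one node) and whose edges are the pixel
#' paths between them, with geodesic length (orthogonal step = 1 px,
#' diagonal = sqrt(2) px) in micrometres. Endpoint spurs shorter than
#' `prune_spur_um` are removed as rasterization artifacts and the graph is
#' rebuilt.
#'
#' @param mask binary matrix (e.g. the FRC class of a stroma map).
#' @param pixel_size_um pixel edge length in micrometres.
#' @param prune_spur_um prune endpoint branches shorter than this (0 disables).
#' @return a `skeleton_graph`: list with `nodes` (tibble: `id`, `row`, `col`,
#'   `kind`), `edges` (tibble: `node_a`, `node_b`, `length_um`, `path`
#'   list-column of pixel index matrices), `skeleton` (0/1 matrix),
#'   `pixel_size_um`. An empty mask gives an empty graph, not an error.
#' @export
skeletonize_network <- function(mask, pixel_size_um = 1, prune_spur_um = 3) {
  check_number(pixel_size_um, "pixel_size_um", 0, strict = TRUE)
  sk <- thin_skeleton(mask)
  g <- extract_graph(sk, pixel_size_um)
  if (prune_spur_um > 0) {
    for (it in 1:3) {
      spur <- g$edges$length_um < prune_spur_um &
        (node_kind(g, g$edges$node_a) == "endpoint" |
           node_kind(g, g$edges$node_b) == "endpoint")
      # never delete an isolated component entirely
      spur <- spur & !(node_kind(g, g$edges$node_a) == "endpoint" &
                         node_kind(g, g$edges$node_b) == "endpoint")
      if (!any(spur)) break
      sk2 <- g$skeleton
      for (i in which(spur)) {
        path <- g$edges$path[[i]]
        # drop path pixels plus the endpoint-node pixel, keep junction pixels
        drop <- path
        if (nrow(drop)) sk2[drop] <- 0L
        for (nid in c(g$edges$node_a[i], g$edges$node_b[i])) {
          if (node_kind(g, nid) == "endpoint") {
            nd <- g$nodes[g$nodes$id == nid, ]
            sk2[nd$row, nd$col] <- 0L
          }
        }
      }
      sk <- thin_skeleton(sk2)
      g <- extract_graph(sk, pixel_size_um)
    }
  }
  g
}

node_kind <- function(g, ids) g$nodes$kind[match(ids, g$nodes$id)]

extract_graph <- function(sk, pixel_size_um) {
  empty <- list(nodes = tibble(id = integer(), row = integer(), col = integer(),
                               kind = character()),
                edges = tibble(node_a = integer(), node_b = integer(),
                               length_um = numeric(), path = list()),
                skeleton = sk, pixel_size_um = pixel_size_um)
  class(empty) <- "skeleton_graph"
  if (!any(sk == 1L)) return(empty)
  nr <- nrow(sk)
  nb <- neighbour_count(sk)
  deg <- ifelse(sk == 1L, nb, 0L)
  # node pixels: endpoints (deg 1), junction pixels (deg >= 3), isolated (0)
  junc_mask <- sk == 1L & deg >= 3L
  endp_mask <- sk == 1L & deg == 1L
  iso_mask <- sk == 1L & deg == 0L
  # merge touching junction pixels into single nodes
  junc_lab <- if (any(junc_mask)) EBImage::bwlabel(junc_mask) else matrix(0L, nrow(sk), ncol(sk))
  node_of <- matrix(0L, nrow(sk), ncol(sk))   # node id per node pixel
  nodes <- list(); nid <- 0L
  n_junc <- max(junc_lab)
  if (n_junc > 0) {
    for (j in seq_len(n_junc)) {
      idx <- which(junc_lab == j, arr.ind = TRUE)
      nid <- nid + 1L
      node_of[idx] <- nid
      nodes[[nid]] <- tibble(id = nid, row = round(mean(idx[, 1])),
                             col = round(mean(idx[, 2])), kind = "junction")
    }
  }
  for (idx in list(which(endp_mask, arr.ind = TRUE))) {
    if (nrow(idx)) for (i in seq_len(nrow(idx))) {
      nid <- nid + 1L
      node_of[idx[i, 1], idx[i, 2]] <- nid
      nodes[[nid]] <- tibble(id = nid, row = idx[i, 1], col = idx[i, 2],
                             kind = "endpoint")
    }
  }
  nodes_df <- if (length(nodes)) dplyr::bind_rows(nodes) else empty$nodes

  offs <- cbind(dr = rep(-1:1, each = 3), dc = rep(-1:1, 3))
  offs <- offs[!(offs[, 1] == 0 & offs[, 2] == 0), ]
  step_len <- sqrt(offs[, 1]^2 + offs[, 2]^2)
  at <- function(r, c) r >= 1 & r <= nrow(sk) & c >= 1 & c <= ncol(sk) &
    sk[cbind(pmin(pmax(r, 1L), nrow(sk)), pmin(pmax(c, 1L), ncol(sk)))] == 1L
  neighbours <- function(r, c) {
    rr <- r + offs[, 1]; cc <- c + offs[, 2]
    keep <- at(rr, cc)
    diag_ <- offs[, 1] != 0L & offs[, 2] != 0L
    # m-adjacency: drop diagonal links bridged by an orthogonal pixel
    keep[diag_] <- keep[diag_] & !at(r + offs[diag_, 1], rep(c, sum(diag_))) &
      !at(rep(r, sum(diag_)), c + offs[diag_, 2])
    cbind(rr, cc, step_len)[keep, , drop = FALSE]
  }

  edges <- list(); ekeys <- character(0)
  visited <- matrix(FALSE, nrow(sk), ncol(sk))  # traversed path pixels
  node_px <- which(node_of != 0L, arr.ind = TRUE)
  add_edge <- function(a, b, len, path) {
    key <- paste(sort(c(a, b)), collapse = "-",
                 sep = "")
    key <- paste0(key, "|", paste(sort(path[, 1] + (path[, 2] - 1) * nr),
                                  collapse = ","))
    if (key %in% ekeys) return(invisible())
    ekeys <<- c(ekeys, key)
    edges[[length(edges) + 1L]] <<- tibble(node_a = a, node_b = b,
                                           length_um = len * pixel_size_um,
                                           path = list(path))
  }
  if (nrow(node_px)) for (i in seq_len(nrow(node_px))) {
    r0 <- node_px[i, 1]; c0 <- node_px[i, 2]; a <- node_of[r0, c0]
    nbrs <- neighbours(r0, c0)
    if (!nrow(nbrs)) next
    for (k in seq_len(nrow(nbrs))) {
      r <- nbrs[k, 1]; cc <- nbrs[k, 2]
      if (node_of[r, cc] != 0L) {
        b <- node_of[r, cc]
        if (b != a) add_edge(a, b, nbrs[k, 3],
                             matrix(integer(0), 0, 2))
        next
      }
      if (visited[r, cc]) next
      # walk along degree-2 pixels
      len <- nbrs[k, 3]
      path_r <- r; path_c <- cc
      pr <- r0; pc <- c0
      repeat {
        visited[r, cc] <- TRUE
        nb2 <- neighbours(r, cc)
        # prefer a node pixel among neighbours (excluding where we came from)
        cand <- nb2[!(nb2[, 1] == pr & nb2[, 2] == pc), , drop = FALSE]
        if (!nrow(cand)) { # dead end without endpoint node (shouldn't happen)
          b <- NA_integer_; break
        }
        is_node <- node_of[cand[, 1:2, drop = FALSE]] != 0L
        if (any(is_node)) {
          j <- which(is_node)[1]
          len <- len + cand[j, 3]
          b <- node_of[cand[j, 1], cand[j, 2]]
          break
        }
        # continue along the unvisited degree-2 pixel
        nxt <- cand[!visited[cand[, 1:2, drop = FALSE]], , drop = FALSE]
        if (!nrow(nxt)) { b <- NA_integer_; break }
        len <- len + nxt[1, 3]
        pr <- r; pc <- cc
        r <- nxt[1, 1]; cc <- nxt[1, 2]
        path_r <- c(path_r, r); path_c <- c(path_c, cc)
      }
      if (!is.na(b)) add_edge(a, b, len, cbind(path_r, path_c))
    }
  }
  # isolated cycles: degree-2 pixels never visited and not nodes
  left <- which(sk == 1L & node_of == 0L & !visited, arr.ind = TRUE)
  if (nrow(left)) {
    comp <- EBImage::bwlabel(sk == 1L & node_of == 0L & !visited)
    for (j in seq_len(max(comp))) {
      idx <- which(comp == j, arr.ind = TRUE)
      if (!nrow(idx)) next
      nid <- nid + 1L
      nodes_df <- dplyr::bind_rows(nodes_df,
        tibble(id = nid, row = idx[1, 1], col = idx[1, 2], kind = "junction"))
      # cycle length: each pixel contributes one step; approximate using
      # mean neighbour step of ring pixels
      len <- 0
      for (i in seq_len(nrow(idx))) {
        nb2 <- neighbours(idx[i, 1], idx[i, 2])
        len <- len + sum(nb2[, 3]) / 2
      }
      edges[[length(edges) + 1L]] <- tibble(node_a = nid, node_b = nid,
                                            length_um = len * pixel_size_um,
                                            path = list(idx))
    }
  }
  out <- list(nodes = nodes_df,
              edges = if (length(edges)) dplyr::bind_rows(edges) else empty$edges,
              skeleton = sk, pixel_size_um = pixel_size_um)
  class(out) <- "skeleton_graph"
  out
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("<skeleton_graph> %d nodes (%d junctions), %d branches, total %.1f um\n",
              nrow(x$nodes), sum(x$nodes$kind == "junction"),
              nrow(x$edges), sum(x$edges$length_um)))
  invisible(x)
}

#' Branch statistics of a skeleton graph
#'
#' Per-field-of-view summary: a branch is a skeleton edge between two nodes
#' (junction or endpoint).
#'
#' @param graph a [skeletonize_network()] result.
#' @return tibble with `n_branches`, `mean_branch_length_um` (NA when there
#'   are no branches), `n_junctions`, `total_length_um`.
#' @export
branch_statistics <- function(graph) {
  stopifnot(inherits(graph, "skeleton_graph"))
  n <- nrow(graph$edges)
  tibble(n_branches = n,
         mean_branch_length_um = if (n) mean(graph$edges$length_um) else NA_real_,
         n_junctions = sum(graph$nodes$kind == "junction"),
         total_length_um = sum(graph$edges$length_um))
}

#' Gap analysis: tile the network background with maximal empty circles
#'
#' Greedy extraction of maximal inscribed circles: the Euclidean distance
#' transform of the background (fibres and the field border act as obstacles)
#' is computed, its global maximum becomes a circle, the circle's disk is
#' added to the obstacles, and the process repeats until the largest empty
#' circle falls below `min_radius_um` or `max_circles` have been taken.
#' Circle radii therefore form a non-increasing sequence and every interior
#' is fibre-free.
#'
#' @param mask binary fibre raster.
#' @param pixel_size_um pixel edge length in micrometres.
#' @param min_radius_um stop once the largest empty circle is smaller than this.
#' @param max_circles cap on the number of circles extracted.
#' @return a `gap_set`: tibble with `center_row`, `center_col` (pixel coords)
#'   and `radius_um`, largest first; attributes `min_radius_um`,
#'   `pixel_size_um`, and `summary` (mean/median radius).
#' @export
gap_analysis <- function(mask, pixel_size_um = 1, min_radius_um = 5,
                         max_circles = 200L) {
  check_number(pixel_size_um, "pixel_size_um", 0, strict = TRUE)
  nr <- nrow(mask); nc <- ncol(mask)
  # pad with a 1-px obstacle frame so the border bounds every circle
  bg <- matrix(0, nr + 2L, nc + 2L)
  bg[2:(nr + 1L), 2:(nc + 1L)] <- as.numeric(mask == 0)
  circles <- list()
  min_radius_px <- min_radius_um / pixel_size_um
  while (length(circles) < max_circles) {
    if (!any(bg > 0)) break
    d <- EBImage::distmap(bg)
    rmax <- max(d)
    if (rmax < min_radius_px) break
    pos <- which(d == rmax)[1]          # column-major first: deterministic
    r0 <- (pos - 1L) %% nrow(d) + 1L
    c0 <- (pos - 1L) %/% nrow(d) + 1L
    circles[[length(circles) + 1L]] <-
      tibble(center_row = r0 - 1L, center_col = c0 - 1L,
             radius_um = rmax * pixel_size_um)
    # carve the disk out of the background
    rr <- pmax(1L, floor(r0 - rmax)):pmin(nrow(d), ceiling(r0 + rmax))
    ccv <- pmax(1L, floor(c0 - rmax)):pmin(ncol(d), ceiling(c0 + rmax))
    sub <- expand.grid(r = rr, c = ccv)
    inside <- (sub$r - r0)^2 + (sub$c - c0)^2 <= rmax^2
    bg[cbind(sub$r[inside], sub$c[inside])] <- 0
  }
  out <- if (length(circles)) dplyr::bind_rows(circles) else
    tibble(center_row = integer(), center_col = integer(), radius_um = numeric())
  out <- dplyr::arrange(out, dplyr::desc(.data$radius_um))
  attr(out, "min_radius_um") <- min_radius_um
  attr(out, "pixel_size_um") <- pixel_size_um
  attr(out, "summary") <- tibble(n_circles = nrow(out),
                                 mean_radius_um = mean(out$radius_um),
                                 median_radius_um = stats::median(out$radius_um))
  class(out) <- c("gap_set", class(out))
  out
}

#' Per-component fibre shape features
#'
#' Connected components (8-connectivity) of the fibre raster are measured
#' for area, ellipse axis lengths from second moments, elongation
#' (minor/major, 1 for a disk), and skeleton complexity (branch points,
#' endpoints, skeleton length).
#'
#' @param mask binary fibre raster.
#' @param pixel_size_um pixel edge length in micrometres.
#' @return tibble, one row per component: `component`, `area_um2`,
#'   `major_axis_um`, `minor_axis_um`, `elongation`, `branchpoint_count`,
#'   `endpoint_count`, `skeleton_length_um`.
#' @export
fiber_shape_features <- function(mask, pixel_size_um = 1) {
  lab <- EBImage::bwlabel(mask != 0)
  n <- max(lab)
  if (n == 0) return(tibble(component = integer(), area_um2 = numeric(),
                            major_axis_um = numeric(), minor_axis_um = numeric(),
                            elongation = numeric(), branchpoint_count = integer(),
                            endpoint_count = integer(),
                            skeleton_length_um = numeric()))
  idx <- which(lab > 0, arr.ind = TRUE)
  comp <- lab[idx]
  area <- tabulate(comp, n)
  mr <- tapply(idx[, 1], comp, mean); mc <- tapply(idx[, 2], comp, mean)
  v_rr <- tapply(idx[, 1], comp, function(v) mean(v^2)) - mr^2 + 1 / 12
  v_cc <- tapply(idx[, 2], comp, function(v) mean(v^2)) - mc^2 + 1 / 12
  v_rc <- numeric(n)
  for (j in seq_len(n)) {
    sel <- comp == j
    v_rc[j] <- mean(idx[sel, 1] * idx[sel, 2]) - mr[j] * mc[j]
  }
  tr <- v_rr + v_cc
  det_ <- v_rr * v_cc - v_rc^2
  disc <- sqrt(pmax(tr^2 / 4 - det_, 0))
  l1 <- tr / 2 + disc; l2 <- pmax(tr / 2 - disc, 0)
  major <- 4 * sqrt(l1) * pixel_size_um
  minor <- 4 * sqrt(l2) * pixel_size_um
  elong <- ifelse(major > 0, pmin(minor / major, 1), 1)

  g <- skeletonize_network(mask, pixel_size_um)
  bp <- integer(n); ep <- integer(n); slen <- numeric(n)
  if (nrow(g$nodes)) {
    node_comp <- lab[cbind(g$nodes$row, g$nodes$col)]
    deg <- tabulate(c(g$edges$node_a, g$edges$node_b),
                    nbins = max(g$nodes$id))
    # a branch point is real only when >= 3 branches actually meet there;
    # compact blobs thin to a junction-pixel cluster with no incident branch
    is_bp <- g$nodes$kind == "junction" & deg[g$nodes$id] >= 3
    bp <- tabulate(node_comp[is_bp], n)
    ep <- tabulate(node_comp[g$nodes$kind == "endpoint"], n)
  }
  if (nrow(g$edges)) {
    edge_comp <- map_int(seq_len(nrow(g$edges)), function(i) {
      p <- g$edges$path[[i]]
      if (nrow(p)) lab[p[1, 1], p[1, 2]]
      else lab[g$nodes$row[match(g$edges$node_a[i], g$nodes$id)],
               g$nodes$col[match(g$edges$node_a[i], g$nodes$id)]]
    })
    sl <- tapply(g$edges$length_um, factor(edge_comp, levels = seq_len(n)), sum)
    slen <- ifelse(is.na(sl), 0, sl)
  }
  tibble(component = seq_len(n), area_um2 = area * pixel_size_um^2,
         major_axis_um = as.numeric(major), minor_axis_um = as.numeric(minor),
         elongation = as.numeric(elong),
         branchpoint_count = as.integer(bp), endpoint_count = as.integer(ep),
         skeleton_length_um = as.numeric(slen))
}

#' Cluster fibre components into shape classes c15-c18
#'
#' k-means on standardized (elongation, branch point count), with cluster ids
#' relabelled deterministically by ascending mean elongation then ascending
#' branch points, so c15 is the most elongated-simple class and c18 the most
#' compact-complex, stable across runs. With fewer components than `k`, the
#' function falls back to quantile binning on elongation with a warning.
#'
#' @param features tibble with at least `elongation` and `branchpoint_count`
#'   (e.g. from [fiber_shape_features()]).
#' @param k number of shape classes (default 4 -> labels c15..c18).
#' @param seed k-means seed.
#' @return `features` with a `shape_cluster` factor column (levels c15..c(14+k)).
#' @export
classify_fiber_shapes <- function(features, k = 4L, seed = 1L) {
  check_columns(features, c("elongation", "branchpoint_count"), "shape features")
  labels_all <- paste0("c", 14 + seq_len(k))
  n <- nrow(features)
  if (n == 0) stop_degenerate("no fibre components to classify")
  X <- cbind(features$elongation, features$branchpoint_count)
  if (n < k || nrow(unique(X)) < k) {
    warn("fewer distinct components than k; falling back to quantile binning on elongation")
    q <- stats::quantile(features$elongation, probs = seq(0, 1, length.out = k + 1))
    bins <- cut(features$elongation, breaks = unique(q), include.lowest = TRUE)
    cl <- as.integer(bins)
    cl[is.na(cl)] <- 1L
  } else {
    Xs <- scale(X)
    Xs[, apply(X, 2, stats::sd) == 0] <- 0
    cl <- withr::with_seed(seed,
      stats::kmeans(Xs, centers = k, nstart = 10, iter.max = 100)$cluster)
  }
  grp <- sort(unique(cl))
  fcl <- factor(cl, levels = grp)
  ord <- grp[order(tapply(features$elongation, fcl, mean),
                   tapply(features$branchpoint_count, fcl, mean))]
  relabel <- integer(max(grp)); relabel[ord] <- seq_along(ord)
  features$shape_cluster <- factor(labels_all[relabel[cl]], levels = labels_all)
  features
}
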