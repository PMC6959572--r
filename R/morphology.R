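#' Neuron tree from SWC-style node table
#'
#' Builds a dendritic tree from SWC records (id, type, x, y, z, radius,
#' parent; parent -1 marks the root). The root must be the soma; the
#' graph must be acyclic (each node one parent). Branches are maximal
#' unbranched paths; branch order starts at 1 for branches leaving the
#' soma and increases after each branch point.
#'
#' @param nodes data.frame with columns `id`, `type`, `x`, `y`, `z`,
#'   `radius`, `parent` (um coordinates).
#' @return a `NeuronTree`: `nodes`, `soma_id`, `branches` (list of node
#'   id vectors), `branch_order` (per branch).
#' @export
neuron_tree <- function(nodes) {
  req <- c("id", "x", "y", "z", "parent")
  if (!all(req %in% names(nodes))) {
    stop("nodes need columns: ", paste(req, collapse = ", "))
  }
  idmap <- match(nodes$parent, nodes$id)   # NA for root
  root <- which(nodes$parent < 0 | is.na(idmap))
  if (length(root) != 1L) stop("tree must have exactly one root (soma)")
  # cycle check: walking up from every node must reach the root
  for (i in seq_len(nrow(nodes))) {
    seen <- 0L; j <- i
    while (!is.na(idmap[j])) {
      j <- idmap[j]
      seen <- seen + 1L
      if (seen > nrow(nodes)) stop("cyclic input: not a tree")
    }
  }
  children <- split(seq_len(nrow(nodes))[-root], idmap[-root])
  n_children <- integer(nrow(nodes))
  n_children[as.integer(names(children))] <- lengths(children)
  # decompose into maximal unbranched paths starting at the soma or at
  # branch points
  branches <- list(); order_of <- integer(0)
  walk <- function(start, ord) {
    path <- start
    cur <- start
    repeat {
      kids <- children[[as.character(cur)]]
      if (is.null(kids) || length(kids) != 1L) break
      cur <- kids
      path <- c(path, cur)
    }
    branches[[length(branches) + 1L]] <<- path
    order_of[length(branches)] <<- ord
    kids <- children[[as.character(cur)]]
    if (!is.null(kids) && length(kids) >= 2L) {
      for (k in kids) walk(k, ord + 1L)
    }
  }
  for (k in children[[as.character(root)]]) walk(k, 1L)
  structure(list(nodes = nodes, root = root, branches = branches,
                 branch_order = order_of, n_children = n_children),
            class = "NeuronTree")
}

#' Read an SWC reconstruction
#'
#' @param path SWC file (7 whitespace-separated columns; `#` comments).
#' @return a `NeuronTree`.
#' @export
read_swc <- function(path) {
  df <- utils::read.table(path, comment.char = "#",
                          col.names = c("id", "type", "x", "y", "z",
                                        "radius", "parent"))
  neuron_tree(df)
}

# Segment list (x1 y1 z1 x2 y2 z2) of every internode edge.
.tree_segments <- function(tree) {
  nd <- tree$nodes
  idmap <- match(nd$parent, nd$id)
  has_parent <- !is.na(idmap) & nd$parent >= 0
  i <- which(has_parent); p <- idmap[i]
  cbind(x1 = nd$x[p], y1 = nd$y[p], z1 = nd$z[p],
        x2 = nd$x[i], y2 = nd$y[i], z2 = nd$z[i])
}

#' Sholl analysis
#'
#' Counts crossings of concentric spheres around the soma at fixed
#' radius increments (default 10 um). Each straight internode segment
#' contributes one crossing for every radius its soma-distance passes
#' through; a segment whose distance dips and rises (closest approach
#' inside the segment) is split at the closest point so re-entrant
#' crossings are counted separately, matching the dense-sampling
#' definition.
#'
#' @param tree a `NeuronTree`.
#' @param radius_step_um increment (default 10).
#' @param max_radius_um outermost radius (default: past the farthest
#'   node).
#' @return data.frame `radius_um`, `intersections`, plus attribute
#'   `sum` (total intersections over all radii).
#' @export
sholl <- function(tree, radius_step_um = 10, max_radius_um = NULL) {
  nd <- tree$nodes
  soma <- c(nd$x[tree$root], nd$y[tree$root], nd$z[tree$root])
  seg <- .tree_segments(tree)
  dist_to <- function(x, y, z) sqrt((x - soma[1L])^2 + (y - soma[2L])^2 +
                                      (z - soma[3L])^2)
  if (is.null(max_radius_um)) {
    max_radius_um <- max(dist_to(nd$x, nd$y, nd$z)) + radius_step_um
  }
  radii <- seq(radius_step_um, max_radius_um, by = radius_step_um)
  counts <- integer(length(radii))
  if (nrow(seg)) {
    for (s in seq_len(nrow(seg))) {
      a <- seg[s, 1:3]; b <- seg[s, 4:6]
      # closest point of the (infinite) line to the soma, clamped
      ab <- b - a
      tt <- sum((soma - a) * ab) / sum(ab * ab)
      pieces <- if (is.finite(tt) && tt > 0 && tt < 1) {
        m <- a + tt * ab
        list(c(a, m), c(m, b))
      } else list(c(a, b))
      for (pc in pieces) {
        d1 <- dist_to(pc[1L], pc[2L], pc[3L])
        d2 <- dist_to(pc[4L], pc[5L], pc[6L])
        lo <- min(d1, d2); hi <- max(d1, d2)
        counts <- counts + (radii > lo & radii <= hi)
      }
    }
  }
  out <- data.frame(radius_um = radii, intersections = counts)
  attr(out, "sum") <- sum(counts)
  out
}

#' Dendritic tree metrics
#'
#' Total dendritic length (all branches), number of branches, branch
#' points, end tips, and maximum branch order.
#'
#' @param tree a `NeuronTree`.
#' @return list with `total_length_um`, `n_branches`, `n_branch_points`,
#'   `n_end_tips`, `max_branch_order`.
#' @export
tree_metrics <- function(tree) {
  seg <- .tree_segments(tree)
  len <- if (nrow(seg)) sum(sqrt((seg[, 4L] - seg[, 1L])^2 +
                                   (seg[, 5L] - seg[, 2L])^2 +
                                   (seg[, 6L] - seg[, 3L])^2)) else 0
  tips <- sum(tree$n_children == 0L &
                seq_along(tree$n_children) != tree$root)
  bp <- sum(tree$n_children >= 2L & seq_along(tree$n_children) != tree$root)
  list(total_length_um = len,
       n_branches = length(tree$branches),
       n_branch_points = bp,
       n_end_tips = tips,
       max_branch_order = if (length(tree$branch_order))
         max(tree$branch_order) else 0L)
}

#' Soma area and diameter from a single-plane mask
#'
#' Area is the mask pixel count times the pixel area. The diameter is
#' measured perpendicular to the apical axis: the extent of the mask
#' along the perpendicular direction through the mask centroid.
#'
#' @param mask logical matrix (single z-plane soma mask).
#' @param geom a `PixelGeometry`.
#' @param apical_angle_rad direction of the apical axis (radians,
#'   image coordinates; 0 = +x).
#' @param band_px half-thickness of the centroid band used for the
#'   extent (default 0.5 px).
#' @return list with `area_um2`, `diameter_um`.
#' @export
soma_metrics <- function(mask, geom, apical_angle_rad, band_px = 0.5) {
  idx <- which(mask)
  if (!length(idx)) stop("empty soma mask")
  ny <- nrow(mask)
  i <- (idx - 1L) %% ny + 1L
  j <- (idx - 1L) %/% ny + 1L
  # u along apical axis, v perpendicular
  ca <- cos(apical_angle_rad); sa <- sin(apical_angle_rad)
  u <- ca * j + sa * i
  v <- -sa * j + ca * i
  uc <- mean(u)
  band <- abs(u - uc) <= band_px
  if (!any(band)) band <- abs(u - uc) <= 1
  diameter_px <- diff(range(v[band])) + 1
  list(area_um2 = pixels_to_um2(length(idx), geom),
       diameter_um = pixels_to_um(diameter_px, geom))
}
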