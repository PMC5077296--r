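#' Assign branch orders to a dendritic tree
#'
#' The n-th dendritic order is the portion of the dendritic tree between the
#' (n-1)-th and n-th branching nodes, or the dendritic end: order 1 runs
#' from the soma to the first branching node; the order increments at every
#' branching node (a node with two or more dendritic children — at a
#' trifurcation all children increment once); unbranched continuation nodes
#' do not increment the order.
#'
#' @param tree A \code{\link{morph_tree}} whose dendrites are rooted at a
#'   soma node (type code 1).
#' @param primary_from Convention for the proximal end of first-order
#'   segments: \code{"soma_center"} (default; the first-order length runs
#'   from the soma center to the first branching node, the convention that
#'   is most reproducible across reconstructions) or \code{"soma_edge"}
#'   (from the first dendritic node, i.e. the soma edge).
#'
#' @return A data.frame of dendritic segments with columns \code{order},
#'   \code{start} and \code{end} (node row indices), \code{length_um}
#'   (summed 3-D inter-node path length) and \code{is_tip}.
#' @export
assign_branch_orders <- function(tree, primary_from = c("soma_center",
                                                        "soma_edge")) {
  primary_from <- match.arg(primary_from)
  nd <- tree$nodes
  n <- nrow(nd)
  if (!length(tree$soma_ids)) stop("dendrite not rooted at soma: no type-1 node")
  soma_set <- tree$soma_ids
  soma_center <- colMeans(nd[soma_set, c("x", "y", "z"), drop = FALSE])

  children <- vector("list", n)
  for (i in seq_len(n)) {
    p <- nd$parent[i]
    if (!is.na(p)) children[[p]] <- c(children[[p]], i)
  }
  dend_children <- lapply(children, function(ch) ch[!(ch %in% soma_set)])

  xyz <- cbind(nd$x, nd$y, nd$z)
  dist3 <- function(a, b) {
    sqrt(sum((xyz[a, ] - xyz[b, ])^2))
  }

  segs <- list()
  # one segment = walk from a segment-start node until a branch point or tip
  walk <- function(start_parent, first_node, order) {
    len <- if (start_parent %in% soma_set) {
      if (primary_from == "soma_center") {
        sqrt(sum((xyz[first_node, ] - soma_center)^2))
      } else 0
    } else {
      dist3(start_parent, first_node)
    }
    cur <- first_node
    repeat {
      ch <- dend_children[[cur]]
      if (length(ch) == 1) {
        len <- len + dist3(cur, ch)
        cur <- ch
      } else {
        segs[[length(segs) + 1L]] <<- list(order = order,
                                           start = first_node, end = cur,
                                           length_um = len,
                                           is_tip = length(ch) == 0)
        if (length(ch) >= 2) {
          for (c2 in ch) walk(cur, c2, order + 1L)
        }
        break
      }
    }
  }

  for (s in soma_set) {
    for (c1 in dend_children[[s]]) walk(s, c1, 1L)
  }
  # any dendrite node not reached from the soma indicates a detached subtree
  reach <- logical(n)
  reach[soma_set] <- TRUE
  queue <- soma_set
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    ch <- children[[cur]]
    ch <- ch[!reach[ch]]
    reach[ch] <- TRUE
    queue <- c(queue, ch)
  }
  if (!all(reach)) {
    stop("dendrite not rooted at soma: node(s) ",
         paste(tree$original_ids[!reach], collapse = ", "),
         " unreachable from the soma")
  }
  if (!length(segs)) {
    return(data.frame(order = integer(0), start = integer(0),
                      end = integer(0), length_um = numeric(0),
                      is_tip = logical(0)))
  }
  do.call(rbind, lapply(segs, as.data.frame))
}

#' Morphometric features of a dendritic tree
#'
#' Computes the ten primary features used by the active/silent classifier —
#' total dendritic length, total length per branch order 1-7, number of
#' primary dendrites and number of dendritic endings — plus the derived
#' branching index (endings / primaries), complexity index
#' ((sum of branch-tip orders + number of tips) x (total dendritic length /
#' number of primary dendrites)) and, when per-order spine densities are
#' supplied, the estimated total spine count (sum over orders of density x
#' order length). Orders beyond 7 contribute to the total length but have no
#' dedicated per-order slot. Lengths are used as-is, with no shrinkage
#' correction.
#'
#' @param tree A \code{\link{morph_tree}}.
#' @param spine_densities Optional numeric vector of spine densities per
#'   micrometer, named or indexed by branch order.
#' @param primary_from See \code{\link{assign_branch_orders}}.
#' @return An object of class \code{morph_features}: list with
#'   \code{total_length}, \code{order1}..\code{order7}, \code{n_primary},
#'   \code{n_endings}, \code{branching_index}, \code{complexity_index},
#'   \code{max_order} and optionally \code{est_total_spines}.
#' @export
morph_features <- function(tree, spine_densities = NULL,
                           primary_from = "soma_center") {
  segs <- assign_branch_orders(tree, primary_from = primary_from)
  n_primary <- sum(segs$order == 1L)
  if (n_primary == 0) stop("tree has no primary dendrites")
  total <- sum(segs$length_um)
  max_ord <- max(segs$order)
  by_order <- vapply(seq_len(max(7L, max_ord)), function(k) {
    sum(segs$length_um[segs$order == k])
  }, numeric(1))
  tips <- segs[segs$is_tip, ]
  out <- c(
    list(total_length = total),
    stats::setNames(as.list(by_order[1:7]), paste0("order", 1:7)),
    list(
      n_primary = n_primary,
      n_endings = nrow(tips),
      branching_index = nrow(tips) / n_primary,
      complexity_index = (sum(tips$order) + nrow(tips)) * (total / n_primary),
      max_order = max_ord
    )
  )
  if (!is.null(spine_densities)) {
    ords <- if (!is.null(names(spine_densities))) {
      as.integer(names(spine_densities))
    } else {
      seq_along(spine_densities)
    }
    len_at <- vapply(ords, function(k) sum(segs$length_um[segs$order == k]),
                     numeric(1))
    out$est_total_spines <- sum(as.numeric(spine_densities) * len_at)
  }
  class(out) <- "morph_features"
  out
}

#' @export
print.morph_features <- function(x, ...) {
  cat(sprintf(paste0("<morph_features> total %.0f um over %d orders; ",
                     "%d primaries, %d endings, branching index %.2f\n"),
              x$total_length, x$max_order, x$n_primary, x$n_endings,
              x$branching_index))
  invisible(x)
}

#' Relative soma position within the granule-cell layer
#'
#' Relative distance of the soma center between the two anatomical borders
#' of the layer: 0 at the deep border (hilar side), 1 at the superficial
#' border (molecular-layer side). Computed as d_deep / (d_deep + d_sup)
#' where each distance is the minimum distance from the soma center to the
#' border polyline. A soma outside the band is clamped to 0 or 1 with a
#' warning.
#'
#' @param tree A \code{\link{morph_tree}}.
#' @param layer_borders List with elements \code{deep} and
#'   \code{superficial}, each an n x 2 polyline matrix in the tree's
#'   coordinate frame (x, y).
#' @return A value in [0, 1].
#' @export
soma_layer_position <- function(tree, layer_borders) {
  stopifnot(all(c("deep", "superficial") %in% names(layer_borders)))
  nd <- tree$nodes
  soma <- colMeans(nd[tree$soma_ids, c("x", "y"), drop = FALSE])
  near <- function(poly) {
    poly <- as.matrix(poly)
    best <- c(Inf, NA, NA)
    for (i in seq_len(nrow(poly) - 1)) {
      a <- poly[i, ]; b <- poly[i + 1, ]
      ab <- b - a
      t_ <- sum((soma - a) * ab) / sum(ab^2)
      t_ <- min(max(t_, 0), 1)
      pt <- a + t_ * ab
      d <- sqrt(sum((soma - pt)^2))
      if (d < best[1]) best <- c(d, pt)
    }
    if (nrow(poly) == 1) {
      best <- c(sqrt(sum((soma - poly[1, ])^2)), poly[1, ])
    }
    list(d = best[1], pt = best[2:3])
  }
  nd_deep <- near(layer_borders$deep)
  nd_sup <- near(layer_borders$superficial)
  # same-side test: if the directions to both borders agree, the soma is
  # outside the band
  v1 <- nd_deep$pt - soma
  v2 <- nd_sup$pt - soma
  if (sum(v1 * v2) > 1e-9) {
    warning("soma outside the layer band; position clamped")
    return(if (nd_deep$d < nd_sup$d) 0 else 1)
  }
  if (nd_deep$d + nd_sup$d == 0) return(0.5)
  nd_deep$d / (nd_deep$d + nd_sup$d)
}

#' Per-feature group comparison (two-sided Mann-Whitney)
#'
#' Compares each morphometric feature between active and silent cells with
#' the two-sided Mann-Whitney test and reports box-plot summaries (median,
#' IQR, 1.5-IQR whiskers, outliers) per group.
#'
#' @param features_active,features_silent Numeric matrices or data.frames
#'   (cells in rows, features in columns, matching column names), >= 2 rows
#'   each.
#' @return A data.frame with one row per feature: \code{U}, \code{p},
#'   medians, quartiles, whisker ends and outlier counts per group.
#' @export
compare_groups <- function(features_active, features_silent) {
  A <- as.matrix(features_active)
  S <- as.matrix(features_silent)
  stopifnot(nrow(A) >= 2, nrow(S) >= 2, ncol(A) == ncol(S))
  feat <- colnames(A)
  if (is.null(feat)) feat <- paste0("f", seq_len(ncol(A)))
  box <- function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    iqr <- q[3] - q[1]
    lw <- min(v[v >= q[1] - 1.5 * iqr])
    uw <- max(v[v <= q[3] + 1.5 * iqr])
    c(q1 = q[1], median = q[2], q3 = q[3], whisker_lo = lw,
      whisker_hi = uw, n_outliers = sum(v < lw | v > uw))
  }
  rows <- lapply(seq_along(feat), function(j) {
    mw <- mannwhitney_2s(A[, j], S[, j])
    c(list(feature = feat[j], U = mw$U, p = mw$p),
      as.list(stats::setNames(box(A[, j]), paste0("active_", names(box(A[, j]))))),
      as.list(stats::setNames(box(S[, j]), paste0("silent_", names(box(S[, j]))))))
  })
  do.call(rbind, lapply(rows, as.data.frame))
}
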