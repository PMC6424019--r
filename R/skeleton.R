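#' Skeletonize a silhouette and build its branch graph
#'
#' Topology-preserving Zhang-Suen thinning of the binary mask (8-connected
#' skeleton), followed by graph construction: skeleton pixels with one
#' 8-neighbour are endpoints, pixels with three or more are junction pixels
#' (adjacent junction pixels are merged into one junction node), and the
#' maximal paths between nodes are the branches. Spur branches shorter than
#' `prune_px` are removed iteratively, since unpruned spurs double-count
#' boundary noise in the branch count.
#'
#' @param s a [silhouette()] carrying a mask, or a binary matrix. A
#'   silhouette without a mask is rasterized from its polygon at
#'   `px_per_mm`.
#' @param prune_px prune spur branches shorter than this many pixels
#'   (default 3); 0 disables pruning.
#' @param px_per_mm rasterization resolution when no mask is stored
#'   (default 20).
#' @return object of class `skeleton_graph`: list with `skeleton` (logical
#'   matrix), `nodes` (data.frame: `row`, `col`, `type` in
#'   endpoint/junction), `edges` (data.frame: `from`, `to`, `n_pixels`),
#'   and `n_branches`.
#' @export
skeletonize <- function(s, prune_px = 3, px_per_mm = 20) {
  mask <- if (inherits(s, "silhouette")) {
    if (!is.null(s$mask)) s$mask
    else polygon_to_mask(s$polygon, scale = 1 / px_per_mm)$mask
  } else s != 0
  if (!any(mask)) stopf("empty mask: nothing to skeletonize")
  sk <- thin_zhang_suen(mask)
  g <- skeleton_graph(sk)
  if (prune_px > 0) {
    repeat {
      spur <- which(g$edges$n_pixels < prune_px &
                    (g$nodes$type[g$edges$from] == "endpoint" |
                     g$nodes$type[g$edges$to] == "endpoint") &
                    g$nodes$type[g$edges$from] != g$nodes$type[g$edges$to])
      if (!length(spur) || nrow(g$edges) <= 1) break
      drop_px <- unlist(g$edge_pixels[spur])
      # also drop the spur's endpoint node pixel
      for (e in spur) {
        for (nd in c(g$edges$from[e], g$edges$to[e]))
          if (g$nodes$type[nd] == "endpoint")
            drop_px <- c(drop_px, g$node_pixels[[nd]])
      }
      sk[drop_px] <- FALSE
      g <- skeleton_graph(sk)
    }
  }
  structure(list(skeleton = sk, nodes = g$nodes, edges = g$edges,
                 n_branches = g$n_branches), class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf(
    "Skeleton graph: %d px, %d endpoints, %d junctions, %d branch(es)\n",
    sum(x$skeleton), sum(x$nodes$type == "endpoint"),
    sum(x$nodes$type == "junction"), x$n_branches))
  invisible(x)
}

# Zhang-Suen two-subiteration thinning, vectorized over the whole image.
thin_zhang_suen <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  img <- matrix(FALSE, nr + 2, nc + 2)
  img[2:(nr + 1), 2:(nc + 1)] <- mask
  shift <- function(m, dr, dc) {
    out <- matrix(FALSE, nrow(m), ncol(m))
    rsrc <- seq_len(nrow(m)) - dr
    csrc <- seq_len(ncol(m)) - dc
    okr <- rsrc >= 1 & rsrc <= nrow(m)
    okc <- csrc >= 1 & csrc <= ncol(m)
    out[okr, okc] <- m[rsrc[okr], csrc[okc]]
    out
  }
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p2 <- shift(img, -1, 0);  p3 <- shift(img, -1, 1)
      p4 <- shift(img, 0, 1);   p5 <- shift(img, 1, 1)
      p6 <- shift(img, 1, 0);   p7 <- shift(img, 1, -1)
      p8 <- shift(img, 0, -1);  p9 <- shift(img, -1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
           (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      cond <- img & b >= 2 & b <= 6 & a == 1
      if (step == 1) {
        cond <- cond & !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- cond & !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) {
        img[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img[2:(nr + 1), 2:(nc + 1)]
}

# 8-neighbour count for each pixel of a logical matrix.
neighbour_count <- function(sk) {
  nr <- nrow(sk); nc <- ncol(sk)
  z <- matrix(0L, nr + 2, nc + 2)
  z[2:(nr + 1), 2:(nc + 1)] <- sk
  acc <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    acc <- acc + z[2:(nr + 1) + dr, 2:(nc + 1) + dc]
  }
  acc
}

# Build the node/edge decomposition of a 1-px-wide skeleton.
skeleton_graph <- function(sk) {
  nr <- nrow(sk)
  deg <- neighbour_count(sk)
  px <- which(sk)
  if (!length(px)) stopf("empty skeleton")
  # adjacency edge list among skeleton pixels (8-connectivity)
  adj_pairs <- function(idx) {
    offs <- c(-1L, nr - 1L, nr, nr + 1L)  # half the neighbourhood, no doubles
    res <- vector("list", length(offs))
    npix <- length(sk)
    r <- ((idx - 1L) %% nr) + 1L
    for (k in seq_along(offs)) {
      j <- idx + offs[k]
      ok <- j >= 1L & j <= npix
      dr <- abs((((pmin(pmax(j, 1L), npix) - 1L) %% nr) + 1L) - r)
      ok <- ok & dr <= 1L
      ok[ok] <- sk[j[ok]]
      res[[k]] <- cbind(idx[ok], j[ok])
    }
    do.call(rbind, res)
  }
  pairs <- adj_pairs(px)

  is_node_px <- sk & (deg != 2)           # endpoints (1) and junctions (>=3)
  # lone pixels (deg 0) and pure cycles (all deg 2) handled below
  node_px <- which(is_node_px)

  # merge adjacent junction pixels into junction nodes; endpoints are their
  # own nodes
  comp_of <- integer(length(sk))
  n_nodes <- 0L
  node_pixels <- list()
  node_type <- character()
  if (length(node_px)) {
    jn <- node_px[deg[node_px] >= 3]
    en <- node_px[deg[node_px] <= 1]
    if (length(jn)) {
      sub <- pairs[pairs[, 1] %in% jn & pairs[, 2] %in% jn, , drop = FALSE]
      g <- igraph::graph_from_data_frame(
        data.frame(from = as.character(sub[, 1]), to = as.character(sub[, 2])),
        directed = FALSE,
        vertices = data.frame(name = as.character(jn)))
      mem <- igraph::components(g)$membership
      for (cid in sort(unique(mem))) {
        n_nodes <- n_nodes + 1L
        pix <- as.integer(names(mem)[mem == cid])
        node_pixels[[n_nodes]] <- pix
        node_type[n_nodes] <- "junction"
        comp_of[pix] <- n_nodes
      }
    }
    for (p in en) {
      n_nodes <- n_nodes + 1L
      node_pixels[[n_nodes]] <- p
      node_type[n_nodes] <- "endpoint"
      comp_of[p] <- n_nodes
    }
  }

  # path pixels: degree-2 pixels not in any node; their connected components
  # are the branch interiors
  path_px <- px[!is_node_px[px]]
  edges <- data.frame(from = integer(), to = integer(), n_pixels = integer())
  edge_pixels <- list()
  if (length(path_px)) {
    sub <- pairs[pairs[, 1] %in% path_px & pairs[, 2] %in% path_px, , drop = FALSE]
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(sub[, 1]), to = as.character(sub[, 2])),
      directed = FALSE,
      vertices = data.frame(name = as.character(path_px)))
    mem <- igraph::components(g)$membership
    touch <- rbind(pairs[pairs[, 1] %in% path_px & comp_of[pairs[, 2]] > 0,
                         , drop = FALSE],
                   pairs[pairs[, 2] %in% path_px & comp_of[pairs[, 1]] > 0,
                         c(2, 1), drop = FALSE])
    for (cid in sort(unique(mem))) {
      pix <- as.integer(names(mem)[mem == cid])
      ends <- unique(comp_of[touch[touch[, 1] %in% pix, 2]])
      if (length(ends) == 0) ends <- c(NA_integer_, NA_integer_)  # isolated cycle
      if (length(ends) == 1) ends <- c(ends, ends)                # loop branch
      edge_pixels[[nrow(edges) + 1L]] <- pix
      edges[nrow(edges) + 1L, ] <- c(ends[1], ends[2], length(pix))
    }
  }
  # direct node-node contacts with no interior path pixel
  jj <- pairs[comp_of[pairs[, 1]] > 0 & comp_of[pairs[, 2]] > 0, , drop = FALSE]
  if (nrow(jj)) {
    a <- comp_of[jj[, 1]]; b <- comp_of[jj[, 2]]
    keep <- a != b
    if (any(keep)) {
      uab <- unique(t(apply(cbind(a[keep], b[keep]), 1, sort)))
      for (i in seq_len(nrow(uab))) {
        edge_pixels[[nrow(edges) + 1L]] <- integer()
        edges[nrow(edges) + 1L, ] <- c(uab[i, 1], uab[i, 2], 0L)
      }
    }
  }
  if (nrow(edges) == 0) {
    # single pixel or tiny blob: count it as one degenerate branch
    edge_pixels[[1]] <- px
    edges[1, ] <- c(if (n_nodes) 1L else NA_integer_,
                    if (n_nodes) 1L else NA_integer_, length(px))
  }
  nodes <- data.frame(
    row = vapply(node_pixels, function(p) ((p[1] - 1L) %% nr) + 1L, 0L),
    col = vapply(node_pixels, function(p) ((p[1] - 1L) %/% nr) + 1L, 0L),
    type = node_type)
  list(nodes = nodes, edges = edges, n_branches = nrow(edges),
       node_pixels = node_pixels, edge_pixels = edge_pixels)
}
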