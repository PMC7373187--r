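#' Topology-preserving thinning of a binary mask
#'
#' Zhang-Suen iterative thinning: erodes a binary shape to a one-pixel-wide,
#' 8-connected skeleton while preserving its topology (connectivity, holes).
#' Used to reduce segmented molecules to centerline traces whose branch
#' points mark junctions.
#'
#' @param mask Logical (or 0/1) matrix.
#' @return Logical matrix of the same shape.
#' @export
thin_mask <- function(mask) {
  img <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  img[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- as.integer(mask != 0)
  nr <- nrow(mask); nc <- ncol(mask)
  ri <- 2:(nr + 1L); ci <- 2:(nc + 1L)
  nb <- function(P) list(
    p2 = P[ri - 1L, ci], p3 = P[ri - 1L, ci + 1L], p4 = P[ri, ci + 1L],
    p5 = P[ri + 1L, ci + 1L], p6 = P[ri + 1L, ci], p7 = P[ri + 1L, ci - 1L],
    p8 = P[ri, ci - 1L], p9 = P[ri - 1L, ci - 1L])
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      v <- nb(img)
      B <- v$p2 + v$p3 + v$p4 + v$p5 + v$p6 + v$p7 + v$p8 + v$p9
      A <- (v$p2 < v$p3) + (v$p3 < v$p4) + (v$p4 < v$p5) + (v$p5 < v$p6) +
           (v$p6 < v$p7) + (v$p7 < v$p8) + (v$p8 < v$p9) + (v$p9 < v$p2)
      core <- img[ri, ci] == 1L & B >= 2L & B <= 6L & A == 1L
      del <- if (sub == 1)
        core & (v$p2 * v$p4 * v$p6 == 0L) & (v$p4 * v$p6 * v$p8 == 0L)
      else
        core & (v$p2 * v$p4 * v$p8 == 0L) & (v$p2 * v$p6 * v$p8 == 0L)
      if (any(del)) {
        blk <- img[ri, ci]
        blk[del] <- 0L
        img[ri, ci] <- blk
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img[ri, ci] == 1L
}

## Length of an ordered pixel path, measured along chords spanning `k`
## pixels. Exact on straight axial/diagonal paths (where it equals the
## 1 / sqrt(2) step metric) while suppressing the staircase inflation that
## step counting suffers on oblique digitized curves.
chord_length <- function(coords, k = 3L) {
  m <- nrow(coords)
  if (m < 2) return(0)
  idx <- unique(c(seq(1L, m, by = k), m))
  sum(sqrt(diff(coords[idx, 1])^2 + diff(coords[idx, 2])^2))
}

## Trace length of a set of skeleton pixels forming one path component:
## greedy nearest-unvisited walk from `start_idx` (jumping across touching
## folds only when no adjacent pixel is left), measured with chord sampling.
## Unlike a graph shortest path, the walk visits every pixel, so folds of a
## tightly wiggling molecule that touch in the raster are not shortcut.
comp_walk_length <- function(co, start_idx, k = 3L) {
  np <- nrow(co)
  if (np <= 1) return(0)
  d2m <- outer(co[, 1], co[, 1], "-")^2 + outer(co[, 2], co[, 2], "-")^2
  visited <- rep(FALSE, np)
  ord <- integer(np)
  cur <- start_idx
  for (i in seq_len(np)) {
    ord[i] <- cur
    visited[cur] <- TRUE
    cand <- which(!visited & d2m[cur, ] <= 2)
    if (!length(cand)) cand <- which(!visited)
    if (!length(cand)) break
    cur <- cand[which.min(d2m[cur, cand])]
  }
  chord_length(co[ord[ord > 0L], , drop = FALSE], k)
}

## Weighted 8-adjacency edge list among TRUE pixels of a logical matrix.
## Returns list(coord = (row, col) per pixel, edges = (i, j, w) by pixel rank).
skeleton_adjacency <- function(sk) {
  nr <- nrow(sk); nc <- ncol(sk)
  fg <- which(sk)
  rank <- integer(nr * nc); rank[fg] <- seq_along(fg)
  r <- ((fg - 1L) %% nr) + 1L
  cc <- ((fg - 1L) %/% nr) + 1L
  offs <- list(list(c(0L, 1L), 1), list(c(1L, 0L), 1),
               list(c(1L, 1L), sqrt(2)), list(c(-1L, 1L), sqrt(2)))
  el <- list()
  for (o in offs) {
    r2 <- r + o[[1]][1]; c2 <- cc + o[[1]][2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nbr <- rank[(c2[ok] - 1L) * nr + r2[ok]]
    sel <- nbr > 0L
    if (any(sel))
      el[[length(el) + 1L]] <- cbind(rank[fg[ok]][sel], nbr[sel], o[[2]])
  }
  edges <- if (length(el)) do.call(rbind, el) else matrix(0, 0, 3)
  list(coord = cbind(row = r, col = cc), edges = edges)
}

#' Skeletonize a segmented component into a topological graph
#'
#' Thins the component mask to a one-pixel skeleton, then builds the
#' node/edge graph the tracing stages work on: skeleton pixels with three or
#' more skeleton neighbours are clustered (single linkage, radius `r_merge`)
#' into branch nodes — a pixelated crossing often thins into two nearby
#' degree-3 pixels, which merge into one degree-4 node — degree-1 pixels are
#' endpoints, and edges are the maximal node-free pixel paths, measured in
#' pixel steps (1 axial, sqrt(2) diagonal). A ring component with neither
#' endpoints nor branches becomes a single cyclic edge flagged as a closed
#' loop.
#'
#' Skeletons of real (noisy, several pixels wide) molecules sprout short
#' spurious side branches wherever the mask boundary is ragged; edges shorter
#' than `prune_len` that dead-end at an endpoint are therefore pruned and the
#' graph re-simplified (pass-through nodes merged) until stable, so only
#' genuine topology remains.
#'
#' @param mask Logical matrix, TRUE on the component.
#' @param component_id Identifier carried through to outputs.
#' @param r_merge Branch-pixel merge radius in px.
#' @param prune_len Maximum length (px) of a dead-end spur to prune; 0
#'   disables pruning.
#' @return A `skeleton_graph`: `nodes` (`id, row, col, kind, degree`),
#'   `edges` (`from, to, length_px, n_px, closed_loop`), `pixels` (skeleton
#'   coordinates), `component_id`.
#' @export
skeletonize_component <- function(mask, component_id = NA_integer_,
                                  r_merge = 4, prune_len = 6) {
  sk <- thin_mask(mask)
  adj <- skeleton_adjacency(sk)
  np <- nrow(adj$coord)
  nodes <- data.frame(id = integer(0), row = numeric(0), col = numeric(0),
                      kind = character(0), degree = integer(0))
  edges <- data.frame(from = integer(0), to = integer(0),
                      length_px = numeric(0), n_px = integer(0),
                      closed_loop = logical(0))
  gobj <- function() structure(
    list(nodes = nodes, edges = edges, pixels = adj$coord,
         component_id = component_id, r_merge = r_merge,
         total_length_px = 0), class = "skeleton_graph")
  if (np == 0) return(gobj())
  g <- igraph::make_graph(t(adj$edges[, 1:2, drop = FALSE]), n = np,
                          directed = FALSE)
  igraph::E(g)$weight <- adj$edges[, 3]
  deg <- igraph::degree(g)
  is_branch <- deg >= 3L
  is_end <- deg == 1L

  node_id <- 0L
  pix_node <- integer(np)        # node id attached AT a pixel (endpoints)
  branch_cluster <- integer(np)  # cluster id per branch pixel
  cl_nodes <- list()             # cluster centroids
  cl_pix <- list()               # cluster pixel coordinates
  if (any(is_branch)) {
    bidx <- which(is_branch)
    co <- adj$coord[bidx, , drop = FALSE]
    nb <- length(bidx)
    ## only touching branch pixels form one node here; nearby-but-separate
    ## branch nodes are merged into single junctions by detect_junctions()
    memb <- if (nb == 1) 1L else {
      d2 <- outer(co[, 1], co[, 1], "-")^2 + outer(co[, 2], co[, 2], "-")^2
      prox <- which(d2 <= 2 & upper.tri(d2), arr.ind = TRUE)
      pg <- igraph::make_graph(t(prox), n = nb, directed = FALSE)
      igraph::components(pg)$membership
    }
    for (k in sort(unique(memb))) {
      node_id <- node_id + 1L
      sel <- memb == k
      cl_nodes[[node_id]] <- c(mean(co[sel, 1]), mean(co[sel, 2]))
      cl_pix[[node_id]] <- co[sel, , drop = FALSE]
      nodes <- rbind(nodes, data.frame(
        id = node_id, row = mean(co[sel, 1]), col = mean(co[sel, 2]),
        kind = "branch", degree = 0L))
      branch_cluster[bidx[sel]] <- node_id
    }
  }
  for (e in which(is_end)) {
    node_id <- node_id + 1L
    nodes <- rbind(nodes, data.frame(
      id = node_id, row = adj$coord[e, 1], col = adj$coord[e, 2],
      kind = "endpoint", degree = 0L))
    pix_node[e] <- node_id
  }

  path_px <- which(!is_branch)
  if (length(path_px)) {
    sub <- igraph::induced_subgraph(g, path_px)
    comp <- igraph::components(sub)$membership
    ## branch-cluster attachments of each path pixel, from cross edges
    ee <- adj$edges
    cross1 <- ee[!is_branch[ee[, 1]] & is_branch[ee[, 2]], 1:2, drop = FALSE]
    cross2 <- ee[is_branch[ee[, 1]] & !is_branch[ee[, 2]], c(2, 1),
                 drop = FALSE]
    cross <- rbind(cross1, cross2)  # (path pixel, branch pixel)
    for (pc in sort(unique(comp))) {
      sel_sub <- which(comp == pc)
      pix <- path_px[sel_sub]
      ## terminals: (pixel, node id, connection length beyond the path)
      term <- list()
      for (p in pix[is_end[pix]])
        term[[length(term) + 1L]] <- list(pix = p, node = pix_node[p],
                                          extra = 0)
      if (nrow(cross)) {
        att <- cross[cross[, 1] %in% pix, , drop = FALSE]
        if (nrow(att)) {
          cl <- branch_cluster[att[, 2]]
          for (u in unique(paste(att[, 1], cl))) {
            w <- which(paste(att[, 1], cl) == u)[1]
            p <- att[w, 1]; nd <- cl[w]
            ## connection length: step to the nearest pixel of the cluster
            ## (a centroid can sit far away when the cluster is spread out)
            cp <- cl_pix[[nd]]
            term[[length(term) + 1L]] <- list(
              pix = p, node = nd,
              extra = sqrt(min((adj$coord[p, 1] - cp[, 1])^2 +
                               (adj$coord[p, 2] - cp[, 2])^2)))
          }
        }
      }
      if (length(term) == 0L) {
        ## closed loop: cycle length = total weight of in-component edges
        wsum <- sum(igraph::E(sub)$weight[
          apply(igraph::as_edgelist(sub, names = FALSE), 1,
                function(x) all(x %in% sel_sub))])
        node_id <- node_id + 1L
        nodes <- rbind(nodes, data.frame(
          id = node_id, row = adj$coord[pix[1], 1],
          col = adj$coord[pix[1], 2], kind = "loop", degree = 0L))
        edges <- rbind(edges, data.frame(
          from = node_id, to = node_id, length_px = wsum,
          n_px = length(pix), closed_loop = TRUE))
      } else if (length(pix) <= 3L &&
                 length(unique(vapply(term, `[[`, integer(1), "node"))) == 1L &&
                 nodes$kind[nodes$id == term[[1]]$node] == "branch") {
        next  # crumb fragment hugging one branch cluster: absorb, no edge
      } else if (length(term) == 1L) {
        t1 <- term[[1]]
        edges <- rbind(edges, data.frame(
          from = t1$node, to = t1$node, length_px = 2 * t1$extra,
          n_px = length(pix), closed_loop = FALSE))
      } else {
        ## pick the two terminals farthest apart along the path (a pixel can
        ## carry several terminals, e.g. an endpoint also touching a cluster)
        tp <- vapply(term, function(t) match(t$pix, path_px), integer(1))
        up <- unique(tp)
        dm <- if (length(up) == 1) matrix(0, length(tp), length(tp)) else {
          du <- igraph::distances(sub, v = up, to = up)
          du[match(tp, up), match(tp, up), drop = FALSE]
        }
        pairs <- which(upper.tri(dm), arr.ind = TRUE)
        best <- pairs[which.max(dm[pairs]), ]
        t1 <- term[[best[1]]]; t2 <- term[[best[2]]]
        co_pc <- adj$coord[pix, , drop = FALSE]
        plen <- comp_walk_length(co_pc, match(t1$pix, pix))
        edges <- rbind(edges, data.frame(
          from = t1$node, to = t2$node,
          length_px = plen + t1$extra + t2$extra,
          n_px = length(pix), closed_loop = FALSE))
      }
    }
  }
  ## total trace length over every skeleton pixel: the node/edge table above
  ## captures topology, but in fold-contaminated skeletons its path pixels
  ## cover only part of the trace, so length is measured by a full walk
  start <- which(deg == 1L)
  start <- if (length(start)) start[1] else 1L
  total_len <- comp_walk_length(adj$coord, start)
  g2 <- structure(list(nodes = nodes, edges = edges, pixels = adj$coord,
                       component_id = component_id, r_merge = r_merge,
                       total_length_px = total_len),
                  class = "skeleton_graph")
  g2 <- simplify_skeleton_graph(g2)
  if (prune_len > 0) g2 <- prune_spurs(g2, prune_len)
  g2
}

## Recompute node degrees (self-edges count twice), drop unused nodes,
## re-kind degree-1 former branch nodes as endpoints, and merge the two
## incident edges of any degree-2 branch node into one pass-through edge.
simplify_skeleton_graph <- function(graph) {
  nodes <- graph$nodes; edges <- graph$edges
  repeat {
    ends <- c(edges$from, edges$to)
    nodes$degree <- vapply(nodes$id, function(id) sum(ends == id), integer(1))
    drop <- nodes$degree == 0L & nrow(edges) > 0L
    if (any(drop)) nodes <- nodes[!drop, , drop = FALSE]
    rek <- nodes$kind == "branch" & nodes$degree == 1L
    if (any(rek)) nodes$kind[rek] <- "endpoint"
    pass <- which(nodes$kind == "branch" & nodes$degree == 2L)
    if (length(pass) == 0L) break
    id <- nodes$id[pass[1]]
    inc <- which(edges$from == id | edges$to == id)
    if (length(inc) == 1L) {
      ## lone self-loop through a former branch: an isolated ring
      nodes$kind[nodes$id == id] <- "loop"
      edges$closed_loop[inc] <- TRUE
      ends <- c(edges$from, edges$to)
      nodes$degree <- vapply(nodes$id, function(i) sum(ends == i), integer(1))
      break
    }
    e1 <- edges[inc[1], ]; e2 <- edges[inc[2], ]
    o1 <- if (e1$from == id) e1$to else e1$from
    o2 <- if (e2$from == id) e2$to else e2$from
    merged <- data.frame(from = o1, to = o2,
                         length_px = e1$length_px + e2$length_px,
                         n_px = e1$n_px + e2$n_px,
                         closed_loop = o1 == o2 && o1 == id)
    edges <- rbind(edges[-inc, , drop = FALSE], merged)
    nodes <- nodes[nodes$id != id, , drop = FALSE]
  }
  graph$nodes <- nodes
  graph$edges <- edges
  graph
}

## Iteratively remove dead-end spur edges shorter than prune_len px, then
## re-simplify; repeats until no spur remains.
prune_spurs <- function(graph, prune_len) {
  repeat {
    nodes <- graph$nodes; edges <- graph$edges
    if (nrow(edges) <= 1L) break
    kind <- stats::setNames(nodes$kind, nodes$id)
    is_spur <- !edges$closed_loop & edges$length_px < prune_len &
      xor(kind[as.character(edges$from)] == "endpoint",
          kind[as.character(edges$to)] == "endpoint") &
      (kind[as.character(edges$from)] == "branch" |
       kind[as.character(edges$to)] == "branch")
    if (!any(is_spur)) break
    gone_ends <- unique(c(
      edges$from[is_spur][kind[as.character(edges$from[is_spur])] == "endpoint"],
      edges$to[is_spur][kind[as.character(edges$to[is_spur])] == "endpoint"]))
    graph$edges <- edges[!is_spur, , drop = FALSE]
    graph$nodes <- nodes[!(nodes$id %in% gone_ends), , drop = FALSE]
    graph <- simplify_skeleton_graph(graph)
  }
  graph
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf(
    "<skeleton_graph> component %s: %d px, %d endpoints, %d branch nodes, %d edges%s\n",
    x$component_id, nrow(x$pixels), sum(x$nodes$kind == "endpoint"),
    sum(x$nodes$kind == "branch"), nrow(x$edges),
    if (any(x$edges$closed_loop)) " (closed loop)" else ""))
  invisible(x)
}
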