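#' Contour length of a skeletonized molecule
#'
#' Length of the skeleton trace — 1 pixel step for axial moves, sqrt(2) for
#' diagonal moves along the traced path — converted to nm. This is the
#' automated counterpart of measuring a molecule with a freehand line tool.
#' The trace walks every skeleton pixel of the component (see
#' [skeletonize_component()]), so touching folds of a tightly curved molecule
#' are measured along the molecule rather than shortcut across.
#'
#' @param graph A [skeletonize_component()] result.
#' @param pixel_size_nm Pixel size in nm.
#' @return Length in nm.
#' @export
contour_length_nm <- function(graph, pixel_size_nm) {
  stopifnot(inherits(graph, "skeleton_graph"))
  if (nrow(graph$pixels) == 0) stop("empty skeleton graph")
  graph$total_length_px * pixel_size_nm
}

#' Detect junctions in a skeleton graph
#'
#' One junction per group of branch nodes: branch nodes within `r_merge` px
#' of each other (single linkage) merge into a single junction, because a
#' pixelated X typically thins into two nearby degree-3 nodes that represent
#' one crossing. The merged junction's degree is the number of skeleton paths
#' leaving the group (the summed node degrees minus twice the internal
#' edges).
#'
#' @param graph A `skeleton_graph`.
#' @param r_merge Merge radius in px; defaults to the radius the graph was
#'   built with.
#' @return Data frame: `row`, `col` (px, possibly fractional centroids),
#'   `degree`, `component_id`.
#' @export
detect_junctions <- function(graph, r_merge = NULL) {
  stopifnot(inherits(graph, "skeleton_graph"))
  if (is.null(r_merge)) r_merge <- if (!is.null(graph$r_merge)) graph$r_merge else 4
  b <- graph$nodes[graph$nodes$kind == "branch", , drop = FALSE]
  if (nrow(b) == 0)
    return(data.frame(row = numeric(0), col = numeric(0),
                      degree = integer(0), component_id = integer(0)))
  memb <- if (nrow(b) == 1) 1L else {
    d2 <- outer(b$row, b$row, "-")^2 + outer(b$col, b$col, "-")^2
    prox <- which(d2 <= r_merge^2 & upper.tri(d2), arr.ind = TRUE)
    g <- igraph::make_graph(t(prox), n = nrow(b), directed = FALSE)
    igraph::components(g)$membership
  }
  ed <- graph$edges
  out <- lapply(sort(unique(memb)), function(k) {
    ids <- b$id[memb == k]
    internal <- sum(ed$from %in% ids & ed$to %in% ids)
    data.frame(row = mean(b$row[memb == k]), col = mean(b$col[memb == k]),
               degree = max(3L, sum(b$degree[memb == k]) - 2L * internal),
               component_id = graph$component_id)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify the junctions of a component as intra- or intermolecular
#'
#' Component-level rule based on endpoint count and total contour length
#' relative to the nominal single-molecule length `L0`: two endpoints with
#' length within `tol` of `L0` means one molecule crossing itself (intra);
#' three or four endpoints with length within `tol` of `2 L0` means two
#' bridged molecules (inter); components that are closed loops are
#' self-associations (intra); anything else is ambiguous.
#'
#' @param graph A `skeleton_graph`.
#' @param L0 Nominal single-molecule contour length, nm (340 for 1-kbp DNA).
#' @param tol Relative length tolerance (default 0.25).
#' @param pixel_size_nm Pixel size used to convert skeleton length to nm.
#' @return Character vector, one entry per junction of the component
#'   (`"intra"`, `"inter"` or `"ambiguous"`); attribute `component_class`
#'   carries the component-level label even when there are no junctions.
#' @export
classify_junction <- function(graph, L0, tol = 0.25, pixel_size_nm) {
  stopifnot(inherits(graph, "skeleton_graph"))
  if (L0 <= 0) stop("`L0` must be > 0")
  if (tol <= 0 || tol >= 1) stop("`tol` must be in (0, 1)")
  n_end <- sum(graph$nodes$kind == "endpoint")
  L <- graph$total_length_px * pixel_size_nm
  cls <-
    if (nrow(graph$edges) && n_end == 0L) "intra"  # closed loop
    else if (n_end == 2L && L >= (1 - tol) * L0 && L <= (1 + tol) * L0) "intra"
    else if (n_end %in% c(3L, 4L) && L >= (1 - tol) * 2 * L0 &&
             L <= (1 + tol) * 2 * L0) "inter"
    else "ambiguous"
  n_j <- sum(graph$nodes$kind == "branch")
  structure(rep(cls, n_j), component_class = cls)
}

## Local feature height: max of the map within window_r px of a point —
## the automated analogue of reading a feature with a cursor.
feature_height <- function(h, row, col, window_r) {
  nr <- nrow(h); nc <- ncol(h)
  rl <- max(1L, floor(row - window_r)); ru <- min(nr, ceiling(row + window_r))
  cl <- max(1L, floor(col - window_r)); cu <- min(nc, ceiling(col + window_r))
  win <- h[rl:ru, cl:cu, drop = FALSE]
  dwin <- outer((rl:ru) - row, (cl:cu) - col, function(a, b) a^2 + b^2)
  max(win[dwin <= window_r^2])
}

#' Detect junctions as elevated skeleton regions
#'
#' The height-based junction detector: a junction — two duplexes crossing,
#' with or without bound protein — raises the surface by roughly one duplex
#' height, so skeleton pixels whose height exceeds the component's own ridge
#' median by more than `min_height_excess` mark overlap regions. Connected
#' clusters of such pixels (single linkage within `link_r` px, at least
#' `min_px` pixels) each count as one junction, positioned at the cluster's
#' highest pixel. This catches steep crossings (compact elevated disc around
#' a branch point) and shallow-angle overlaps (an elevated stretch whose
#' branch points sit at the merge ends, away from the elevation) alike, and
#' rejects skeleton branch artifacts where ribbons merge laterally without
#' crossing.
#'
#' @param map The (flattened) [height_map()] heights are read from.
#' @param graph The component's `skeleton_graph`.
#' @param min_height_excess Minimum height excess (nm) over the component's
#'   median skeleton height.
#' @param min_px Minimum cluster size in pixels.
#' @param link_r Single-linkage clustering radius in px.
#' @return Data frame: `row`, `col` (peak pixel), `degree` (of the nearest
#'   branch node within 8 px, NA when the skeleton shows no branching there),
#'   `component_id`, `n_px`.
#' @export
detect_junction_regions <- function(map, graph, min_height_excess = 0.4,
                                    min_px = 2L, link_r = 2) {
  stopifnot(inherits(map, "height_map"), inherits(graph, "skeleton_graph"))
  empty <- data.frame(row = numeric(0), col = numeric(0), degree = integer(0),
                      component_id = integer(0), n_px = integer(0))
  px <- graph$pixels
  if (nrow(px) == 0) return(empty)
  hpx <- map$heights[px]
  ref <- stats::median(hpx)
  elev <- which(hpx > ref + min_height_excess)
  if (length(elev) == 0) return(empty)
  co <- px[elev, , drop = FALSE]
  n <- length(elev)
  memb <- if (n == 1) 1L else {
    d2 <- outer(co[, 1], co[, 1], "-")^2 + outer(co[, 2], co[, 2], "-")^2
    prox <- which(d2 <= link_r^2 & upper.tri(d2), arr.ind = TRUE)
    g <- igraph::make_graph(t(prox), n = n, directed = FALSE)
    igraph::components(g)$membership
  }
  keep <- which(tabulate(memb) >= min_px)
  if (length(keep) == 0) return(empty)
  bn <- detect_junctions(graph)
  out <- lapply(keep, function(k) {
    sel <- memb == k
    peak <- which.max(hpx[elev][sel])
    pr <- co[sel, 1][peak]; pc <- co[sel, 2][peak]
    deg <- NA_integer_
    if (nrow(bn)) {
      db <- sqrt((bn$row - pr)^2 + (bn$col - pc)^2)
      if (min(db) <= 8) deg <- bn$degree[which.min(db)]
    }
    data.frame(row = pr, col = pc, degree = deg,
               component_id = graph$component_id, n_px = sum(sel))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Height difference between a junction and protein-free DNA
#'
#' The reproducible analogue of comparing an arrow-marked junction with an
#' asterisk-marked free stretch. The same local feature-height measure — the
#' maximum height within `window_r` px of a point — is read at the junction
#' and at free-DNA reference points (skeleton pixels of the same component
#' farther than `excl_r` px from every junction); the difference of the
#' junction reading and the median free-DNA reading is returned. Using the
#' identical local-max statistic on both sides makes the noise-extremum bias
#' of a windowed maximum cancel, so the estimator recovers the injected
#' height excess without systematic offset. Requires at least 20 free-DNA
#' pixels; otherwise the junction is skipped (NA, with a warning).
#'
#' @param map The (flattened) [height_map()].
#' @param junction One row of [detect_junctions()] output.
#' @param graph The component's `skeleton_graph`.
#' @param window_r Feature window radius, px (applied at the junction and at
#'   every free-DNA reference point alike).
#' @param excl_r Junction exclusion radius for free DNA, px.
#' @param n_ref Maximum number of free-DNA reference points (evenly
#'   subsampled from the free skeleton).
#' @param exclude Data frame of centers (`row`, `col`) to exclude around when
#'   picking free DNA; defaults to the graph's branch nodes.
#' @return Height difference in nm, or `NA` if there is insufficient free
#'   DNA.
#' @export
junction_height_difference <- function(map, junction, graph,
                                       window_r = 3, excl_r = 8,
                                       n_ref = 40L, exclude = NULL) {
  stopifnot(inherits(map, "height_map"), inherits(graph, "skeleton_graph"))
  h <- map$heights
  peak <- feature_height(h, junction$row, junction$col, window_r)
  jall <- if (is.null(exclude)) detect_junctions(graph) else exclude
  px <- graph$pixels
  d2min <- rep(Inf, nrow(px))
  for (q in seq_len(nrow(jall)))
    d2min <- pmin(d2min,
                  (px[, 1] - jall$row[q])^2 + (px[, 2] - jall$col[q])^2)
  free <- px[d2min > excl_r^2, , drop = FALSE]
  if (nrow(free) < 20L) {
    warning("insufficient free DNA (", nrow(free),
            " px beyond the exclusion radius); junction skipped")
    return(NA_real_)
  }
  sel <- unique(as.integer(round(seq(1L, nrow(free),
                                     length.out = min(n_ref, nrow(free))))))
  refs <- vapply(sel, function(i)
    feature_height(h, free[i, 1], free[i, 2], window_r), numeric(1))
  peak - stats::median(refs)
}

#' Trace and quantify all molecules in one image
#'
#' Per-image driver for the post-segmentation analysis: skeletonizes every
#' labelled component, measures contour lengths, detects and classifies
#' junctions, and profiles junction heights against protein-free DNA.
#' Components touching the image border are flagged clipped and excluded from
#' intra/inter classification (only whole molecules are classified).
#'
#' Two measures keep skeleton artifacts out of the junction table: the
#' segmentation mask is built from a lightly smoothed copy of the image
#' (`smooth_sigma_px`), and detected branch points whose height excess over
#' free DNA falls below `min_height_excess` are discarded — where two duplex
#' ribbons merely run close enough to merge laterally, the skeleton branches
#' but the surface shows no overlap elevation, whereas a genuine crossing is
#' elevated by roughly one duplex height. All heights are measured on the
#' unsmoothed input map.
#'
#' @param map A flattened [height_map()].
#' @param comps Optional [label_components()] result; computed with the
#'   default automatic threshold (on the smoothed copy) when omitted.
#' @param k,min_area_px Threshold multiplier and minimum component area, used
#'   when `comps` is omitted.
#' @param smooth_sigma_px Gaussian sigma (px) for the mask-building copy;
#'   0 disables smoothing.
#' @param min_height_excess Minimum junction height excess (nm) for a branch
#'   point to count as a junction; 0 keeps every branch point.
#' @param L0 Nominal molecule contour length, nm.
#' @param tol Relative tolerance of the length-based classification.
#' @param r_merge,window_r,excl_r Tracing radii in px (branch merging,
#'   junction height window, free-DNA exclusion).
#' @param prune_len Spur-pruning length in px (see [skeletonize_component()]).
#' @return List with `molecules` (one row per component: endpoints, length,
#'   junction count, class, estimated molecule count, clipped flag) and
#'   `junctions` (one row per junction: position, degree, type, height
#'   difference in nm).
#' @export
analyze_image <- function(map, comps = NULL, k = 3, min_area_px = 30L,
                          smooth_sigma_px = 1, min_height_excess = 0.4,
                          L0 = 340, tol = 0.25, r_merge = 4,
                          window_r = 3, excl_r = 8, prune_len = 6) {
  stopifnot(inherits(map, "height_map"))
  if (is.null(comps)) {
    mask_map <- if (smooth_sigma_px > 0)
      smooth_height_map(map, smooth_sigma_px) else map
    comps <- label_components(mask_map, choose_threshold(map, k), min_area_px)
  }
  nr <- nrow(map$heights); nc <- ncol(map$heights)
  px_nm <- map$pixel_size_nm
  mols <- list(); juns <- list()
  for (i in seq_len(nrow(comps$components))) {
    id <- comps$components$id[i]
    mask <- comps$label_grid == id
    graph <- skeletonize_component(mask, id, r_merge = r_merge,
                                   prune_len = prune_len)
    if (nrow(graph$pixels) == 0) next
    clipped <- comps$components$row_min[i] == 1L ||
      comps$components$col_min[i] == 1L ||
      comps$components$row_max[i] == nr ||
      comps$components$col_max[i] == nc
    jd <- detect_junction_regions(map, graph,
                                  min_height_excess = min_height_excess)
    L <- graph$total_length_px * px_nm
    n_end <- sum(graph$nodes$kind == "endpoint")
    types <- classify_junction(graph, L0, tol, px_nm)
    cls <- if (clipped) "clipped" else attr(types, "component_class")
    jtype <- if (clipped) "ambiguous" else attr(types, "component_class")
    jtab <- NULL
    if (nrow(jd)) {
      hd <- vapply(seq_len(nrow(jd)), function(q)
        suppressWarnings(
          junction_height_difference(map, jd[q, ], graph,
                                     window_r = window_r, excl_r = excl_r,
                                     exclude = jd)),
        numeric(1))
      jtab <- data.frame(
        component_id = id, row = jd$row, col = jd$col,
        x_nm = jd$col * px_nm, y_nm = jd$row * px_nm,
        degree = jd$degree,
        jtype = rep(jtype, nrow(jd)),
        height_diff_nm = hd)
    }
    n_j <- if (is.null(jtab)) 0L else nrow(jtab)
    n_mol <- if (cls == "inter") 2L
      else if (cls == "ambiguous") max(1L, as.integer(round(L / L0)))
      else 1L
    mols[[length(mols) + 1L]] <- data.frame(
      component_id = id, n_px = comps$components$n_px[i],
      n_endpoints = n_end, contour_length_nm = L,
      n_junctions = n_j, class = cls, est_n_molecules = n_mol,
      clipped = clipped)
    if (!is.null(jtab)) juns[[length(juns) + 1L]] <- jtab
  }
  molecules <- if (length(mols)) do.call(rbind, mols) else data.frame(
    component_id = integer(0), n_px = integer(0), n_endpoints = integer(0),
    contour_length_nm = numeric(0), n_junctions = integer(0),
    class = character(0), est_n_molecules = integer(0), clipped = logical(0))
  junctions <- if (length(juns)) do.call(rbind, juns) else data.frame(
    component_id = integer(0), row = numeric(0), col = numeric(0),
    x_nm = numeric(0), y_nm = numeric(0), degree = integer(0),
    jtype = character(0), height_diff_nm = numeric(0))
  list(molecules = molecules, junctions = junctions, components = comps)
}
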