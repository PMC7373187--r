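#' Bridging configuration
#'
#' Probabilities controlling junction formation when a scene is assembled:
#' `p_intra` is the per-chain probability of forcing a self-crossing (loop),
#' `p_inter` the per-chain probability of being bridged onto an earlier chain,
#' and `p_protein` the probability that any resulting junction carries a bound
#' protein (which adds height on rendering).
#'
#' @param p_intra,p_inter,p_protein Probabilities in \[0, 1\].
#' @export
bridging_config <- function(p_intra = 0.2, p_inter = 0.1, p_protein = 0.5) {
  p <- c(p_intra = p_intra, p_inter = p_inter, p_protein = p_protein)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("bridging probabilities must lie in [0, 1]")
  as.list(p)
}

## Pairwise segment-segment intersections over all chains, vectorised with a
## bounding-box prefilter. Touching (shared endpoint) counts as a crossing;
## same-chain segment pairs closer than 2 indices apart are skipped.
find_crossings <- function(chains, merge_radius = 4) {
  segs <- do.call(rbind, lapply(seq_along(chains), function(i) {
    v <- chains[[i]]$vertices
    n <- nrow(v) - 1L
    cbind(chain = i, idx = seq_len(n),
          ax = v[1:n, 1], ay = v[1:n, 2],
          bx = v[2:(n + 1), 1], by = v[2:(n + 1), 2])
  }))
  m <- nrow(segs)
  if (m < 2) return(empty_junctions())
  xlo <- pmin(segs[, "ax"], segs[, "bx"]); xhi <- pmax(segs[, "ax"], segs[, "bx"])
  ylo <- pmin(segs[, "ay"], segs[, "by"]); yhi <- pmax(segs[, "ay"], segs[, "by"])
  ## candidate pairs: overlapping bounding boxes, i < j
  cand <- which(
    outer(xlo, xhi, "<=") & outer(xhi, xlo, ">=") &
    outer(ylo, yhi, "<=") & outer(yhi, ylo, ">=") &
    upper.tri(matrix(0, m, m)),
    arr.ind = TRUE)
  if (nrow(cand) == 0) return(empty_junctions())
  i <- cand[, 1]; j <- cand[, 2]
  same <- segs[i, "chain"] == segs[j, "chain"]
  keep <- !(same & abs(segs[i, "idx"] - segs[j, "idx"]) <= 1)
  i <- i[keep]; j <- j[keep]
  if (length(i) == 0) return(empty_junctions())
  r1x <- segs[i, "bx"] - segs[i, "ax"]; r1y <- segs[i, "by"] - segs[i, "ay"]
  r2x <- segs[j, "bx"] - segs[j, "ax"]; r2y <- segs[j, "by"] - segs[j, "ay"]
  qpx <- segs[j, "ax"] - segs[i, "ax"]; qpy <- segs[j, "ay"] - segs[i, "ay"]
  den <- r1x * r2y - r1y * r2x
  ok <- abs(den) > 1e-12
  tt <- (qpx * r2y - qpy * r2x) / den
  uu <- (qpx * r1y - qpy * r1x) / den
  tol <- 1e-9
  hit <- ok & tt >= -tol & tt <= 1 + tol & uu >= -tol & uu <= 1 + tol
  if (!any(hit)) return(empty_junctions())
  i <- i[hit]; j <- j[hit]; tt <- tt[hit]
  px <- segs[i, "ax"] + tt * (segs[i, "bx"] - segs[i, "ax"])
  py <- segs[i, "ay"] + tt * (segs[i, "by"] - segs[i, "ay"])
  c1 <- segs[i, "chain"]; c2 <- segs[j, "chain"]
  mol1 <- pmin(c1, c2); mol2 <- pmax(c1, c2)
  cluster_crossings(px, py, mol1, mol2, merge_radius)
}

empty_junctions <- function() {
  data.frame(x = numeric(0), y = numeric(0),
             type = character(0), mol1 = integer(0), mol2 = integer(0),
             protein_bound = logical(0), n_crossings = integer(0))
}

## Single-linkage clustering of raw intersection points: points belonging to
## the same molecule pair and within merge_radius collapse into one junction.
cluster_crossings <- function(px, py, mol1, mol2, merge_radius) {
  key <- paste(mol1, mol2)
  out <- lapply(unique(key), function(k) {
    sel <- key == k
    x <- px[sel]; y <- py[sel]
    n <- length(x)
    memb <- if (n == 1) 1L else {
      d2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
      adj <- which(d2 <= merge_radius^2 & upper.tri(d2), arr.ind = TRUE)
      g <- igraph::make_graph(t(adj), n = n, directed = FALSE)
      igraph::components(g)$membership
    }
    m1 <- mol1[sel][1]; m2 <- mol2[sel][1]
    data.frame(
      x = tapply(x, memb, mean), y = tapply(y, memb, mean),
      type = if (m1 == m2) "intra" else "inter",
      mol1 = m1, mol2 = m2,
      protein_bound = NA,
      n_crossings = as.integer(tabulate(memb)))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assemble a synthetic AFM scene of DNA chains with ground-truth junctions
#'
#' Places `n_chains` worm-like chains with uniform random positions and
#' orientations on a square field, optionally forcing self-crossings
#' (intramolecular junctions, by steering the regenerated distal part of a
#' chain back through one of its earlier vertices) and chain-chain bridges
#' (intermolecular junctions, by translating a chain so one of its vertices
#' coincides with a vertex of an earlier chain). Ground truth records every
#' crossing of the final polylines — forced or natural — found by an all-pairs
#' segment-intersection sweep; crossings of the same chain pair closer than
#' `capture_radius` merge into one junction. Each junction is independently
#' flagged protein-bound with probability `p_protein`.
#'
#' @param n_chains Number of molecules to place.
#' @param field_size_nm Side of the square field in nm (default 1000, the
#'   1 x 1 um scan size).
#' @param density_class Optional `"low"` (4-7 molecules/um^2) or `"high"`
#'   (8-15): if given, the implied density must fall in the class range.
#' @param bridging A [bridging_config()].
#' @param seed Integer seed (one stream for the whole scene assembly).
#' @param n_bp,persistence_length,segment_length Passed to
#'   [sample_wlc_chain()].
#' @param capture_radius Junction merge radius in nm (default 2 segment
#'   lengths).
#' @return A `scene_truth`: chains (each with `molecule_id` and a `clipped`
#'   flag for chains leaving the field), a junction table
#'   (`x, y, type, mol1, mol2, protein_bound, n_crossings`), field size,
#'   density and density class.
#' @export
place_molecules <- function(n_chains, field_size_nm = 1000,
                            density_class = NULL,
                            bridging = bridging_config(),
                            seed = NULL,
                            n_bp = 1000, persistence_length = 50,
                            segment_length = 2,
                            capture_radius = 2 * segment_length) {
  if (n_chains < 1) stop("`n_chains` must be >= 1")
  area_um2 <- (field_size_nm / 1000)^2
  density <- n_chains / area_um2
  cls <- density_class_of(density)
  if (!is.null(density_class)) {
    density_class <- match.arg(density_class, c("low", "high"))
    if (cls != density_class)
      stop(sprintf(
        "density %.3g /um^2 is outside the '%s' range (low: [4,7], high: [8,15])",
        density, density_class))
  }
  with_seed(seed, {
    chains <- vector("list", n_chains)
    for (i in seq_len(n_chains)) {
      ch <- sample_wlc_chain(n_bp, persistence_length, segment_length,
                             seed = NULL,
                             start = stats::runif(2, 0, field_size_nm))
      if (stats::runif(1) < bridging$p_intra)
        ch <- force_self_crossing(ch, persistence_length)
      if (i >= 2 && stats::runif(1) < bridging$p_inter) {
        partner <- chains[[sample.int(i - 1L, 1L)]]
        ch <- snap_to_chain(ch, partner)
      }
      ch$molecule_id <- i
      ch$clipped <- any(ch$vertices < 0 | ch$vertices > field_size_nm)
      chains[[i]] <- ch
    }
    junc <- find_crossings(chains, merge_radius = capture_radius)
    ## ground truth records only junctions inside the imaged field
    junc <- junc[junc$x >= 0 & junc$x <= field_size_nm &
                 junc$y >= 0 & junc$y <= field_size_nm, , drop = FALSE]
    rownames(junc) <- NULL
    junc$protein_bound <- if (nrow(junc)) {
      stats::runif(nrow(junc)) < bridging$p_protein
    } else logical(0)
    structure(
      list(chains = chains, junctions = junc,
           field_size_nm = field_size_nm, density_um2 = density,
           density_class = cls, capture_radius = capture_radius,
           bridging = bridging,
           params = list(n_bp = n_bp,
                         persistence_length = persistence_length,
                         segment_length = segment_length)),
      class = "scene_truth")
  })
}

## Regrow the distal part of a chain so that one segment passes exactly
## through an earlier vertex: steer toward the target with WLC-scale noise,
## then aim one step straight through it, then resume free growth. Segment
## lengths are preserved exactly.
force_self_crossing <- function(chain, persistence_length) {
  v <- chain$vertices
  n <- nrow(v)
  seg <- chain$segment_length
  sd_turn <- sqrt(seg / persistence_length)
  jt <- max(2L, as.integer(round(n * stats::runif(1, 0.15, 0.35))))
  ic <- min(n - 2L, as.integer(round(n * stats::runif(1, 0.55, 0.75))))
  if (ic <= jt + 2L) return(chain)
  target <- v[jt, ]
  pos <- v[ic, ]
  ang <- atan2(v[ic, 2] - v[ic - 1, 2], v[ic, 1] - v[ic - 1, 1])
  crossed <- FALSE
  for (s in (ic + 1L):n) {
    d <- sqrt(sum((target - pos)^2))
    if (!crossed && d <= seg) {
      ang <- atan2(target[2] - pos[2], target[1] - pos[1])
      crossed <- TRUE
    } else if (!crossed) {
      ang <- atan2(target[2] - pos[2], target[1] - pos[1]) +
        stats::rnorm(1, 0, sd_turn)
    } else {
      ang <- ang + stats::rnorm(1, 0, sd_turn)
    }
    pos <- pos + seg * c(cos(ang), sin(ang))
    v[s, ] <- pos
  }
  chain$vertices <- v
  chain
}

## Translate `chain` so a random vertex lands on a random vertex of `partner`.
snap_to_chain <- function(chain, partner) {
  vq <- chain$vertices[sample.int(nrow(chain$vertices), 1L), ]
  vp <- partner$vertices[sample.int(nrow(partner$vertices), 1L), ]
  chain$vertices <- sweep(chain$vertices, 2L, vp - vq, "+")
  chain
}

#' @export
print.scene_truth <- function(x, ...) {
  tab <- table(factor(x$junctions$type, levels = c("intra", "inter")))
  cat(sprintf(
    "<scene_truth> %d molecules on %g x %g nm (%.3g /um^2, %s density)\n",
    length(x$chains), x$field_size_nm, x$field_size_nm,
    x$density_um2, x$density_class))
  cat(sprintf("  junctions: %d intra, %d inter (%d protein-bound)\n",
              tab[["intra"]], tab[["inter"]],
              sum(x$junctions$protein_bound)))
  invisible(x)
}
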