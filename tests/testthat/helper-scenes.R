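# Shared fixtures: hand-built chains/scenes and an independent brute-force
# crossing oracle (plain scalar loops, no shared code with the package).

make_chain <- function(vertices, n_bp = 1000, molecule_id = 1L) {
  seg <- sqrt(sum((vertices[2, ] - vertices[1, ])^2))
  structure(list(vertices = vertices, segment_length = seg, n_bp = n_bp,
                 molecule_id = molecule_id, clipped = FALSE),
            class = "chain_trace")
}

# straight chain from `from` toward angle `ang`, n_seg segments of length seg
straight_chain <- function(from, ang, n_seg = 60, seg = 2, molecule_id = 1L) {
  v <- cbind(from[1] + (0:n_seg) * seg * cos(ang),
             from[2] + (0:n_seg) * seg * sin(ang))
  make_chain(v, n_bp = round(n_seg * seg / 0.34), molecule_id = molecule_id)
}

make_scene <- function(chains, junctions = NULL, field_size_nm = 500) {
  for (i in seq_along(chains)) chains[[i]]$molecule_id <- i
  if (is.null(junctions))
    junctions <- data.frame(x = numeric(0), y = numeric(0),
                            type = character(0), mol1 = integer(0),
                            mol2 = integer(0), protein_bound = logical(0),
                            n_crossings = integer(0))
  structure(list(chains = chains, junctions = junctions,
                 field_size_nm = field_size_nm,
                 density_um2 = length(chains) / (field_size_nm / 1000)^2,
                 density_class = "out_of_range", capture_radius = 4,
                 bridging = bridging_config(0, 0, 0),
                 params = list(n_bp = 1000, persistence_length = 50,
                               segment_length = 2)),
            class = "scene_truth")
}

# two straight chains crossing at right angles at `at`; the junction table is
# filled analytically; `diagonal` tilts both chains 45 degrees off the scan
# axes (so neither lies along a single scanline)
crossing_scene <- function(at = c(249, 249), protein_bound = FALSE,
                           field_size_nm = 500, n_seg = 80, seg = 2,
                           diagonal = FALSE) {
  a1 <- if (diagonal) pi / 4 else 0
  a2 <- a1 + pi / 2
  h <- straight_chain(at - n_seg / 2 * seg * c(cos(a1), sin(a1)),
                      a1, n_seg, seg, 1L)
  v <- straight_chain(at - n_seg / 2 * seg * c(cos(a2), sin(a2)),
                      a2, n_seg, seg, 2L)
  junc <- data.frame(x = at[1], y = at[2], type = "inter",
                     mol1 = 1L, mol2 = 2L, protein_bound = protein_bound,
                     n_crossings = 1L)
  make_scene(list(h, v), junc, field_size_nm)
}

# Independent brute-force crossing oracle: scalar double loop over all
# segment pairs; returns clustered crossing count per molecule pair.
oracle_crossings <- function(chains, field_size_nm, merge_radius) {
  pts <- list()
  nch <- length(chains)
  for (i in seq_len(nch)) for (j in i:nch) {
    vi <- chains[[i]]$vertices; vj <- chains[[j]]$vertices
    for (a in seq_len(nrow(vi) - 1)) {
      bs <- seq_len(nrow(vj) - 1)
      if (i == j) bs <- bs[bs > a + 1]
      for (b in bs) {
        p1 <- vi[a, ]; p2 <- vi[a + 1, ]; p3 <- vj[b, ]; p4 <- vj[b + 1, ]
        r <- p2 - p1; s <- p4 - p3
        den <- r[1] * s[2] - r[2] * s[1]
        if (abs(den) < 1e-12) next
        q <- p3 - p1
        tt <- (q[1] * s[2] - q[2] * s[1]) / den
        uu <- (q[1] * r[2] - q[2] * r[1]) / den
        if (tt < -1e-9 || tt > 1 + 1e-9 || uu < -1e-9 || uu > 1 + 1e-9) next
        pt <- p1 + tt * r
        if (any(pt < 0) || any(pt > field_size_nm)) next
        pts[[length(pts) + 1]] <- c(i, j, pt)
      }
    }
  }
  if (!length(pts)) return(0L)
  m <- do.call(rbind, pts)
  # single-linkage clustering within molecule pair
  n_j <- 0L
  for (key in unique(paste(m[, 1], m[, 2]))) {
    sub <- m[paste(m[, 1], m[, 2]) == key, , drop = FALSE]
    k <- nrow(sub)
    grp <- seq_len(k)
    repeat {
      changed <- FALSE
      for (a in seq_len(k)) for (b in seq_len(k)) {
        if (grp[a] != grp[b] &&
            sum((sub[a, 3:4] - sub[b, 3:4])^2) <= merge_radius^2) {
          grp[grp == grp[b]] <- grp[a]; changed <- TRUE
        }
      }
      if (!changed) break
    }
    n_j <- n_j + length(unique(grp))
  }
  n_j
}

# default-parameter scene/image stack, cached so several test files can share
# the expensive renders
.scene_cache <- new.env(parent = emptyenv())

default_stack <- function(seed, n_chains = NULL) {
  key <- paste0("s", seed)
  if (!is.null(.scene_cache[[key]])) return(.scene_cache[[key]])
  if (is.null(n_chains))
    n_chains <- with_fixed_seed(seed, sample(8:12, 1))
  scene <- place_molecules(n_chains, 1000, seed = seed)
  map <- render_height_map(scene, render_params(seed = seed + 1000))
  flat <- flatten_image(map)
  res <- analyze_image(flat)
  out <- list(scene = scene, map = map, flat = flat, res = res)
  .scene_cache[[key]] <- out
  out
}

with_fixed_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# collect truth-matched junction height differences from small two-chain
# crossing fields (250 px); pp = probability a junction is protein-bound
collect_height_diffs <- function(pp, n_target = 30, max_seeds = 200,
                                 field = 500) {
  hds <- c()
  sd_ <- 0
  while (length(hds) < n_target && sd_ < max_seeds) {
    sd_ <- sd_ + 1
    sc <- place_molecules(2, field_size_nm = field, seed = sd_,
                          bridging = bridging_config(0, 1, pp))
    sel <- if (pp >= 0.5) sc$junctions$protein_bound else !sc$junctions$protein_bound
    tj <- sc$junctions[sel, , drop = FALSE]
    if (nrow(tj) == 0) next
    map <- render_height_map(sc, render_params(pixel_size_nm = field / 256,
                                               seed = sd_ + 5000))
    flat <- flatten_image(map)
    res <- analyze_image(flat)
    dj <- res$junctions
    if (nrow(dj) == 0) next
    px <- flat$pixel_size_nm
    for (q in seq_len(nrow(tj))) {
      d <- sqrt((dj$row - tj$y[q] / px)^2 + (dj$col - tj$x[q] / px)^2)
      if (min(d) <= 4 && is.finite(dj$height_diff_nm[which.min(d)]))
        hds <- c(hds, dj$height_diff_nm[which.min(d)])
    }
  }
  hds[seq_len(min(n_target, length(hds)))]
}
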