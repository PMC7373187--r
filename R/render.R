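#' Rendering parameters for synthetic height maps
#'
#' Defaults emulate the imaging conditions of a 1 x 1 um fluid-AFM scan of
#' DNA at 512 px: an apparent duplex height of 1.0 nm, a crossing (overlap)
#' height excess of 0.86 nm and a bound-protein excess of 0.50 nm — so a bare
#' crossing sits 0.86 nm and a protein-occupied one 1.36 nm above free DNA —
#' Gaussian tip broadening of 3 nm, 0.08 nm pixel noise, and random
#' per-scanline polynomial background of orders 0-2.
#'
#' @param pixel_size_nm Lateral pixel size (nm/px); default 1000/512.
#' @param h_dna Apparent height of a single duplex, nm.
#' @param h_overlap_add Extra height where two duplex passes cross, nm.
#' @param h_protein_add Additional height of a bound protein at a junction, nm.
#' @param tip_sigma Gaussian tip-broadening width, nm.
#' @param noise_sigma I.i.d. pixel noise standard deviation, nm.
#' @param background_orders Polynomial orders (subset of 0:2) of the random
#'   per-scanline background.
#' @param background_coeff_scale Standard deviation of each background
#'   coefficient, nm.
#' @param seed Integer RNG seed for background and noise.
#' @export
render_params <- function(pixel_size_nm = 1000 / 512, h_dna = 1.0,
                          h_overlap_add = 0.86, h_protein_add = 0.50,
                          tip_sigma = 3.0, noise_sigma = 0.08,
                          background_orders = 0:2,
                          background_coeff_scale = 0.3, seed = 1L) {
  hs <- c(h_dna, h_overlap_add, h_protein_add, tip_sigma, noise_sigma,
          background_coeff_scale)
  if (any(!is.finite(hs)) || any(hs < 0))
    stop("heights, sigmas and background scale must all be >= 0")
  if (pixel_size_nm <= 0) stop("`pixel_size_nm` must be > 0")
  if (!all(background_orders %in% 0:2))
    stop("`background_orders` must be a subset of {0, 1, 2}")
  structure(list(pixel_size_nm = pixel_size_nm, h_dna = h_dna,
                 h_overlap_add = h_overlap_add, h_protein_add = h_protein_add,
                 tip_sigma = tip_sigma, noise_sigma = noise_sigma,
                 background_orders = background_orders,
                 background_coeff_scale = background_coeff_scale,
                 seed = seed),
            class = "render_params")
}

## Per-chain sweep helper: for one chain, computes on the full pixel grid the
## squared distance d1 to the nearest segment, the contour position s1 of
## that segment, and the squared distance d2 to the nearest segment lying
## more than `gap_nm` away along the contour from the locally nearest one
## (a second, distinct pass of the same chain).
chain_distance_fields <- function(v, seg_len, n, px, pad, centers, gap_nm) {
  d1 <- matrix(Inf, n, n); s1 <- matrix(0, n, n)
  nseg <- nrow(v) - 1L
  win <- function(s) {
    a <- v[s, ]; b <- v[s + 1L, ]
    cl <- max(1L, floor(min(a[1], b[1]) / px) - pad)
    cu <- min(n, ceiling(max(a[1], b[1]) / px) + pad)
    rl <- max(1L, floor(min(a[2], b[2]) / px) - pad)
    ru <- min(n, ceiling(max(a[2], b[2]) / px) + pad)
    if (cl > cu || rl > ru) return(NULL)
    xs <- centers[cl:cu]; ys <- centers[rl:ru]
    ab <- b - a
    len2 <- sum(ab^2)
    wx <- matrix(xs - a[1], nrow = length(ys), ncol = length(xs), byrow = TRUE)
    wy <- matrix(ys - a[2], nrow = length(ys), ncol = length(xs))
    tt <- if (len2 > 0) pmin(1, pmax(0, (wx * ab[1] + wy * ab[2]) / len2)) else 0
    list(rl = rl, ru = ru, cl = cl, cu = cu,
         dd = (wx - tt * ab[1])^2 + (wy - tt * ab[2])^2)
  }
  for (s in seq_len(nseg)) {
    w <- win(s)
    if (is.null(w)) next
    blk <- d1[w$rl:w$ru, w$cl:w$cu]
    closer <- w$dd < blk
    if (any(closer)) {
      blk[closer] <- w$dd[closer]
      d1[w$rl:w$ru, w$cl:w$cu] <- blk
      sblk <- s1[w$rl:w$ru, w$cl:w$cu]
      sblk[closer] <- (s - 0.5) * seg_len
      s1[w$rl:w$ru, w$cl:w$cu] <- sblk
    }
  }
  d2 <- matrix(Inf, n, n)
  for (s in seq_len(nseg)) {
    w <- win(s)
    if (is.null(w)) next
    far <- abs((s - 0.5) * seg_len - s1[w$rl:w$ru, w$cl:w$cu]) > gap_nm
    blk <- d2[w$rl:w$ru, w$cl:w$cu]
    upd <- far & w$dd < blk
    if (any(upd)) {
      blk[upd] <- w$dd[upd]
      d2[w$rl:w$ru, w$cl:w$cu] <- blk
    }
  }
  list(d1 = d1, d2 = d2)
}

#' Render a scene into a synthetic AFM height map
#'
#' Inverse imaging model: each pixel's base height is
#' `h_dna * exp(-d^2 / (2 tip_sigma^2))` with `d` the distance from the pixel
#' centre to the nearest chain segment (Gaussian tip broadening). Pixels
#' within `tip_sigma` of two or more distinct duplex passes — two different
#' chains, or contour-distant parts of one chain — get `h_overlap_add` added,
#' so crossings and extended shallow-angle overlaps alike sit about one
#' duplex height above free DNA. Pixels within `tip_sigma` of a protein-bound
#' junction get `h_protein_add` on top. A random polynomial background is
#' then added per scanline and i.i.d. Gaussian noise per pixel. Rendering is
#' deterministic given `(scene, params)`.
#'
#' @param scene A [place_molecules()] scene.
#' @param params A [render_params()].
#' @param pass_gap_nm Contour separation (nm) beyond which two parts of the
#'   same chain count as distinct passes.
#' @return A [height_map()] whose metadata records the parameters and seed.
#' @export
render_height_map <- function(scene, params = render_params(),
                              pass_gap_nm = 20) {
  stopifnot(inherits(scene, "scene_truth"), inherits(params, "render_params"))
  px <- params$pixel_size_nm
  n <- scene$field_size_nm / px
  if (abs(n - round(n)) > 1e-6)
    stop("field size must divide into whole pixels at this pixel size")
  n <- as.integer(round(n))
  sigma <- params$tip_sigma
  pad <- ceiling(4 * sigma / px) + 1L
  centers <- (seq_len(n) - 0.5) * px
  d2min <- matrix(Inf, n, n)      # over all chains
  n_near <- matrix(0L, n, n)      # chains within tip_sigma
  self_ov <- matrix(FALSE, n, n)  # same-chain double pass within tip_sigma
  for (ch in scene$chains) {
    f <- chain_distance_fields(ch$vertices, ch$segment_length, n, px, pad,
                               centers, pass_gap_nm)
    d2min <- pmin(d2min, f$d1)
    near <- f$d1 <= sigma^2
    n_near <- n_near + near
    self_ov <- self_ov | (near & f$d2 <= sigma^2)
  }
  h <- params$h_dna * exp(-d2min / (2 * sigma^2))
  h[d2min > (4 * sigma)^2] <- 0
  overlap <- n_near >= 2L | self_ov
  h[overlap] <- h[overlap] + params$h_overlap_add
  ## bound protein adds a local blob at protein-bound junctions
  jb <- scene$junctions[which(scene$junctions$protein_bound), , drop = FALSE]
  if (nrow(jb) && params$h_protein_add > 0) {
    for (q in seq_len(nrow(jb))) {
      jx <- jb$x[q]; jy <- jb$y[q]
      cl <- max(1L, floor((jx - sigma) / px)); cu <- min(n, ceiling((jx + sigma) / px) + 1L)
      rl <- max(1L, floor((jy - sigma) / px)); ru <- min(n, ceiling((jy + sigma) / px) + 1L)
      if (cl > cu || rl > ru) next
      xs <- centers[cl:cu]; ys <- centers[rl:ru]
      dj <- outer(ys - jy, xs - jx, function(dy, dx) dx^2 + dy^2)
      blk <- h[rl:ru, cl:cu]
      blk[dj <= sigma^2] <- blk[dj <= sigma^2] + params$h_protein_add
      h[rl:ru, cl:cu] <- blk
    }
  }
  ## per-scanline polynomial background + pixel noise, seeded
  with_seed(params$seed, {
    if (length(params$background_orders) && params$background_coeff_scale > 0) {
      xn <- seq(-1, 1, length.out = n)
      basis <- sapply(0:2, function(o) xn^o)
      for (r in seq_len(n)) {
        coef <- numeric(3)
        coef[params$background_orders + 1L] <-
          stats::rnorm(length(params$background_orders), 0,
                       params$background_coeff_scale)
        h[r, ] <- h[r, ] + drop(basis %*% coef)
      }
    }
    if (params$noise_sigma > 0)
      h <- h + matrix(stats::rnorm(n * n, 0, params$noise_sigma), n, n)
  })
  height_map(h, px, metadata = list(
    stage = "render", seed = params$seed,
    n_molecules = length(scene$chains),
    density_um2 = scene$density_um2,
    render_params = unclass(params)))
}

#' Rasterise chain centerlines into pixel coordinates
#'
#' Walks each chain polyline at quarter-pixel steps and returns the unique
#' in-field pixels its centerline passes through — the ground-truth footprint
#' used by the capture criterion.
#'
#' @param scene A `scene_truth`.
#' @param pixel_size_nm Pixel size of the target raster.
#' @return List (one per chain) of two-column matrices (row, col), 1-based.
#' @export
rasterize_centerlines <- function(scene, pixel_size_nm) {
  n <- as.integer(round(scene$field_size_nm / pixel_size_nm))
  lapply(scene$chains, function(ch) {
    v <- ch$vertices
    step <- pixel_size_nm / 4
    pts <- lapply(seq_len(nrow(v) - 1L), function(s) {
      a <- v[s, ]; b <- v[s + 1L, ]
      len <- sqrt(sum((b - a)^2))
      tt <- seq(0, 1, length.out = max(2L, ceiling(len / step) + 1L))
      cbind(a[1] + tt * (b[1] - a[1]), a[2] + tt * (b[2] - a[2]))
    })
    pts <- do.call(rbind, pts)
    rc <- cbind(row = ceiling(pts[, 2] / pixel_size_nm),
                col = ceiling(pts[, 1] / pixel_size_nm))
    rc <- rc[rc[, 1] >= 1 & rc[, 1] <= n & rc[, 2] >= 1 & rc[, 2] <= n, ,
             drop = FALSE]
    unique(rc)
  })
}
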