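#' @keywords internal
"_PACKAGE"

## Axial rise of B-form DNA, nm per base pair.
RISE_PER_BP <- 0.34

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# Derived substream seed, kept inside 32-bit integer range.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1000 + i) %% (2^31 - 1))
}

#' Sample a 2-D worm-like-chain DNA conformation
#'
#' Draws a discretised worm-like chain in the plane, the standard model for
#' DNA equilibrated on a surface. The chain is a sequence of straight segments
#' of equal length; successive turning angles are independent zero-mean
#' Gaussians with variance `segment_length / persistence_length`, the 2-D
#' convention under which the tangent correlation decays as
#' `exp(-s / (2 * persistence_length))` along the contour.
#'
#' The contour length is exactly `n_bp * 0.34` nm: the requested
#' `segment_length` is adjusted to the nearest value that divides the contour
#' into a whole number of segments.
#'
#' @param n_bp Number of base pairs (>= 2).
#' @param persistence_length Persistence length in nm (> 0); ~50 nm for
#'   double-stranded DNA.
#' @param segment_length Target discretisation step in nm, in
#'   `(0, persistence_length]`.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param start Numeric length-2 start position (nm).
#' @param start_angle Initial tangent direction in radians, or `NULL` to draw
#'   it uniformly.
#' @return A `chain_trace`: list with `vertices` (n+1 x 2 matrix, nm),
#'   `segment_length` (nm, the adjusted value), `n_bp`, `molecule_id`,
#'   `clipped` flag.
#' @examples
#' ch <- sample_wlc_chain(1000, seed = 1)
#' chain_contour_length(ch)  # exactly 340 nm
#' @export
sample_wlc_chain <- function(n_bp, persistence_length = 50,
                             segment_length = 2, seed = NULL,
                             start = c(0, 0), start_angle = NULL) {
  if (!is.numeric(n_bp) || n_bp < 2) stop("`n_bp` must be >= 2")
  if (persistence_length <= 0) stop("`persistence_length` must be > 0")
  if (segment_length <= 0 || segment_length > persistence_length)
    stop("`segment_length` must be in (0, persistence_length]")
  L0 <- n_bp * RISE_PER_BP
  n_seg <- max(1L, as.integer(round(L0 / segment_length)))
  seg <- L0 / n_seg
  with_seed(seed, {
    a0 <- if (is.null(start_angle)) stats::runif(1, 0, 2 * pi) else start_angle
    turns <- if (n_seg > 1)
      stats::rnorm(n_seg - 1, 0, sqrt(seg / persistence_length)) else numeric(0)
    ang <- a0 + c(0, cumsum(turns))
    vx <- start[1] + c(0, cumsum(seg * cos(ang)))
    vy <- start[2] + c(0, cumsum(seg * sin(ang)))
    structure(
      list(vertices = cbind(x = vx, y = vy), segment_length = seg,
           n_bp = n_bp, molecule_id = NA_integer_, clipped = FALSE),
      class = "chain_trace"
    )
  })
}

#' Contour length of a chain trace
#'
#' Sum of the Euclidean lengths of consecutive-vertex segments, in nm.
#' @param chain A `chain_trace`.
#' @export
chain_contour_length <- function(chain) {
  v <- chain$vertices
  sum(sqrt(diff(v[, 1])^2 + diff(v[, 2])^2))
}

#' @export
print.chain_trace <- function(x, ...) {
  cat(sprintf("<chain_trace> %d bp, %d segments of %.4g nm (contour %.4g nm)%s\n",
              x$n_bp, nrow(x$vertices) - 1L, x$segment_length,
              chain_contour_length(x),
              if (isTRUE(x$clipped)) ", clipped at field boundary" else ""))
  invisible(x)
}

#' Mean tangent-direction correlation of sampled chains
#'
#' Monte-Carlo estimate of the tangent correlation
#' \eqn{\langle \cos\theta(s) \rangle} at contour separation `s`, averaged
#' over chains; for a 2-D worm-like chain the closed form is
#' `exp(-s / (2 * persistence_length))`. Used to validate the sampler.
#'
#' @param chains List of `chain_trace` objects (equal segment length).
#' @param s_nm Contour separations (nm); rounded to whole segments.
#' @return Data frame with `s_nm`, `mean_cos`, `se`. Segment pairs within one
#'   chain are correlated, so the standard error is computed across chains
#'   (the independent units), not across pairs.
#' @export
tangent_correlation <- function(chains, s_nm) {
  seg <- chains[[1]]$segment_length
  out <- lapply(s_nm, function(s) {
    k <- max(1L, as.integer(round(s / seg)))
    per_chain <- vapply(chains, function(ch) {
      v <- ch$vertices
      dx <- diff(v[, 1]); dy <- diff(v[, 2])
      ang <- atan2(dy, dx)
      n <- length(ang)
      if (n <= k) return(NA_real_)
      mean(cos(ang[(1 + k):n] - ang[1:(n - k)]))
    }, numeric(1))
    per_chain <- per_chain[is.finite(per_chain)]
    data.frame(s_nm = k * seg, mean_cos = mean(per_chain),
               se = stats::sd(per_chain) / sqrt(length(per_chain)))
  })
  do.call(rbind, out)
}
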