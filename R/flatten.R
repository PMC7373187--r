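#' Per-scanline polynomial background flattening
#'
#' Removes instrument background from each scanline (image row) independently
#' by least-squares polynomial fitting, the standard first processing step for
#' AFM raster images. Because molecules bias a naive fit, the fit is iterated
#' with foreground masking: after each fit, pixels whose residual exceeds
#' `mask_k` times the robust residual scale (median absolute deviation scaled
#' by 1.4826) are excluded from the next fit. The final fit is subtracted from
#' the whole line, so the output minus the input is, per scanline, exactly a
#' polynomial of the requested order.
#'
#' @param map A [height_map()].
#' @param order Polynomial order, one of 0, 1, 2.
#' @param n_iter Number of masked refit iterations (>= 1).
#' @param mask_k Foreground mask threshold in robust sigmas (> 0).
#' @return A flattened [height_map()]; `metadata$flatten` logs the call.
#' @seealso [flatten_image()] for the conventional sequential 0, 1, 2 pass.
#' @export
flatten_scanlines <- function(map, order, n_iter = 3L, mask_k = 3) {
  stopifnot(inherits(map, "height_map"))
  if (!order %in% 0:2) stop("`order` must be 0, 1 or 2")
  if (n_iter < 1) stop("`n_iter` must be >= 1")
  if (mask_k <= 0) stop("`mask_k` must be > 0")
  h <- map$heights
  nc <- ncol(h)
  xn <- seq(-1, 1, length.out = nc)
  X <- stats::poly(xn, degree = max(order, 1), raw = TRUE)
  X <- cbind(1, X)[, seq_len(order + 1L), drop = FALSE]
  fell_back <- 0L
  for (r in seq_len(nrow(h))) {
    y <- h[r, ]
    keep <- rep(TRUE, nc)
    fit <- numeric(nc)
    for (it in seq_len(n_iter)) {
      if (sum(keep) < order + 1L) {
        ## too few background pixels for this order: order-0 fallback
        fell_back <- fell_back + 1L
        base <- if (any(keep)) stats::median(y[keep]) else stats::median(y)
        fit <- rep(base, nc)
      } else {
        cf <- stats::lm.fit(X[keep, , drop = FALSE], y[keep])$coefficients
        cf[is.na(cf)] <- 0
        fit <- drop(X %*% cf)
      }
      resid <- y - fit
      s <- stats::mad(resid[keep])
      ## one-sided mask: molecules only add height
      keep <- if (s > 0) resid <= mask_k * s else rep(TRUE, nc)
      if (!any(keep)) keep <- rep(TRUE, nc)
    }
    h[r, ] <- y - fit
  }
  if (fell_back > 0L)
    warning(fell_back, " scanline(s) had too few background pixels; ",
            "fell back to order-0 on those lines")
  md <- map$metadata
  md$flatten <- c(md$flatten,
                  list(list(order = order, n_iter = n_iter, mask_k = mask_k)))
  height_map(h, map$pixel_size_nm, md)
}

#' Sequential order-0, 1, 2 scanline flattening
#'
#' Applies [flatten_scanlines()] for each order in turn (default 0, then 1,
#' then 2), the conventional flattening sequence for AFM height images.
#'
#' @inheritParams flatten_scanlines
#' @param orders Orders to apply, in order.
#' @export
flatten_image <- function(map, orders = c(0, 1, 2), n_iter = 3L, mask_k = 3) {
  for (o in orders) map <- flatten_scanlines(map, o, n_iter = n_iter,
                                             mask_k = mask_k)
  map
}
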