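# Spinal centerline fitting and inflection-based segmentation.
#
# The centerline is modeled as x(y) (the spine is assumed roughly vertical in
# the image).  Moving least squares with a local quadratic basis and a
# Gaussian kernel smooths the vertebra centroids onto a dense grid; a global
# polynomial fitted to that grid supplies an analytic second derivative whose
# sign changes mark the inflection points separating oppositely bending
# segments.

#' Fit the spinal centerline by moving least squares
#'
#' At every grid ordinate `y` the fitted lateral position `x(y)` is the value
#' at `y` of the local quadratic minimizing
#' `sum_i w(y_i - y) (x_i - q(y_i))^2` over the vertebra centroids
#' `(x_i, y_i)`, with Gaussian weights `w(d) = exp(-(d / h)^2)`.
#' A quadratic basis reproduces any straight line or parabola exactly,
#' whatever the bandwidth.  Weights are rescaled so the nearest centroid has
#' weight 1 and floored at 1e-8, which keeps the weighted least-squares
#' system well conditioned even for bandwidths far below the centroid
#' spacing; should the local system still be rank deficient the fit falls
#' back to a local linear — and ultimately locally constant — model and a
#' warning is recorded.
#'
#' @param annotation A [spine_annotation()] with >= 4 vertebrae.
#' @param bandwidth Gaussian kernel width `h` in pixels, or `"auto"`
#'   (2 x median inter-centroid y spacing).
#' @param grid_size Number of grid samples spanning
#'   `[min centroid y, max centroid y]`.
#' @return Object of class `centerline_fit` with fields `sample_y`,
#'   `sample_x`, `bandwidth`, `grid_size` (and, after
#'   [second_derivative_poly()], `poly_coeffs`, `poly_degree`,
#'   `second_derivative`).
#' @export
fit_centerline_mls <- function(annotation, bandwidth = "auto", grid_size = 200) {
  stopifnot(inherits(annotation, "spine_annotation"))
  cent <- annotation_centroids(annotation)
  xs <- cent[, 1]
  ys <- cent[, 2]
  if (length(ys) < 4L) {
    stop("insufficient data: moving least squares needs >= 4 centroids",
         call. = FALSE)
  }
  if (identical(bandwidth, "auto")) {
    bandwidth <- 2 * stats::median(diff(ys))
  }
  bandwidth <- as.numeric(bandwidth)
  if (!is.finite(bandwidth) || bandwidth <= 0) {
    stop("bandwidth must be > 0 (or \"auto\")", call. = FALSE)
  }
  grid <- seq(min(ys), max(ys), length.out = as.integer(grid_size))
  fell_back <- FALSE
  fit_x <- vapply(grid, function(u) {
    d <- ys - u
    e <- (d / bandwidth)^2
    w <- pmax(exp(-(e - min(e))), 1e-8)  # nearest weight 1; underflow-safe
    sw <- sqrt(w)
    dscale <- max(abs(d))
    if (dscale == 0) dscale <- 1
    ds <- d / dscale   # column scaling; q(u) is still the constant term
    for (deg in 2:0) {
      B <- outer(ds, 0:deg, `^`) * sw
      qrB <- qr(B)
      if (qrB$rank == deg + 1L) {
        beta <- qr.coef(qrB, sw * xs)
        if (all(is.finite(beta))) {
          if (deg < 2) fell_back <<- TRUE
          return(beta[1])
        }
      }
    }
    fell_back <<- TRUE
    sum(w * xs) / sum(w)
  }, numeric(1))
  if (fell_back) {
    warning("MLS bandwidth too small for a local quadratic at some grid points; ",
            "fell back to a lower-order local fit", call. = FALSE)
  }
  structure(list(sample_y = grid, sample_x = fit_x, bandwidth = bandwidth,
                 grid_size = as.integer(grid_size), poly_coeffs = NULL,
                 poly_degree = NULL, second_derivative = NULL),
            class = "centerline_fit")
}

# Coefficients (ascending powers) of the product of two polynomials.
poly_mul <- function(a, b) {
  out <- rep(0, length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  }
  out
}

# Rewrite sum_j b_j ((y - mu)/s)^j as coefficients in plain powers of y.
rescale_poly <- function(b, mu, s) {
  out <- 0
  zpow <- 1                      # ((y - mu)/s)^0
  lin <- c(-mu / s, 1 / s)       # (y - mu)/s
  for (j in seq_along(b)) {
    out <- c(out, rep(0, max(0, length(zpow) - length(out)))) +
      c(b[j] * zpow, rep(0, max(0, length(out) - length(zpow))))
    zpow <- poly_mul(zpow, lin)
  }
  out
}

#' Global polynomial fit and analytic second derivative
#'
#' Fits a least-squares polynomial of the given degree to the MLS curve
#' samples and augments the fit with the polynomial's exact analytic second
#' derivative on the sample grid.  The regression is performed on a centered
#' and scaled ordinate for conditioning; reported coefficients are converted
#' back to the original pixel coordinates.
#'
#' @param fit A `centerline_fit` from [fit_centerline_mls()].
#' @param degree Polynomial degree (>= 2 and < number of grid samples).
#' @return The input fit with `poly_coeffs` (ascending powers of y, original
#'   coordinates), `poly_degree` and `second_derivative` filled in.
#' @export
second_derivative_poly <- function(fit, degree = 6) {
  stopifnot(inherits(fit, "centerline_fit"))
  degree <- as.integer(degree)
  n <- length(fit$sample_y)
  if (degree < 2L || degree >= n) {
    stop("degree must be >= 2 and < number of grid samples", call. = FALSE)
  }
  mu <- mean(fit$sample_y)
  s <- stats::sd(fit$sample_y)
  if (!is.finite(s) || s <= 0) {
    stop("degenerate design: grid ordinates have zero spread", call. = FALSE)
  }
  z <- (fit$sample_y - mu) / s
  X <- outer(z, 0:degree, `^`)
  qrX <- qr(X)
  if (qrX$rank < degree + 1L) {
    stop("degenerate design matrix in polynomial fit (rank ", qrX$rank,
         " < ", degree + 1L, ")", call. = FALSE)
  }
  b <- qr.coef(qrX, fit$sample_x)
  # d2x/dy2 = (1/s^2) * sum_{j>=2} j (j-1) b_j z^(j-2)
  j <- 2:degree
  d2 <- if (degree >= 2L) {
    as.vector(outer(z, j - 2, `^`) %*% (j * (j - 1) * b[j + 1L])) / s^2
  } else {
    rep(0, n)
  }
  fit$poly_coeffs <- rescale_poly(b, mu, s)
  fit$poly_degree <- degree
  fit$second_derivative <- d2
  fit
}

#' Split a spine into bending segments at inflection points
#'
#' Boundaries are placed at the sign changes of the fitted second derivative
#' (position linearly interpolated between grid points); each vertebra joins
#' the segment containing its centroid y.  Values with `|x''|` below an
#' absolute dead band of 1e-12 px^-1 are treated as zero and never produce a
#' crossing, so numerically straight spines yield a single segment.  Segments
#' holding fewer than two vertebrae are merged into the adjacent segment with
#' the larger mean curvature magnitude; same-direction neighbours created by
#' a merge are coalesced, so the result always partitions the vertebrae into
#' runs of >= 2 with alternating bending direction.
#'
#' @param fit A `centerline_fit` carrying a second derivative.
#' @param annotation The [spine_annotation()] the fit came from.
#' @return List of `curve_segment` objects, each with `vertebra_indices`
#'   (contiguous, 1-based), `direction` (+1/-1) and `boundary_y`.
#' @export
segment_by_inflection <- function(fit, annotation) {
  stopifnot(inherits(fit, "centerline_fit"))
  if (is.null(fit$second_derivative)) {
    stop("fit carries no second derivative; run second_derivative_poly() first",
         call. = FALSE)
  }
  d2 <- fit$second_derivative
  yy <- fit$sample_y
  dead_band <- 1e-12
  s <- sign(d2)
  s[abs(d2) < dead_band] <- 0

  # crossing positions, linearly interpolated between grid points
  crossings <- numeric()
  last_sign <- 0
  last_idx <- NA_integer_
  for (i in seq_along(s)) {
    if (s[i] == 0) next
    if (last_sign != 0 && s[i] != last_sign) {
      y1 <- yy[last_idx]; y2 <- yy[i]
      v1 <- d2[last_idx]; v2 <- d2[i]
      crossings <- c(crossings, y1 - v1 * (y2 - y1) / (v2 - v1))
    }
    last_sign <- s[i]
    last_idx <- i
  }

  cy <- annotation_centroids(annotation)[, 2]
  member <- findInterval(cy, c(-Inf, crossings, Inf), left.open = TRUE)

  # mean |x''| and sign per interval, for directions and merge decisions
  grid_member <- findInterval(yy, c(-Inf, crossings, Inf), left.open = TRUE)
  n_int <- length(crossings) + 1L
  info <- lapply(seq_len(n_int), function(g) {
    v <- d2[grid_member == g]
    if (!length(v)) v <- 0
    list(mean_abs = mean(abs(v)),
         direction = if (mean(v) >= 0) 1L else -1L)
  })
  bounds <- c(min(yy), crossings, max(yy))

  segs <- lapply(seq_len(n_int), function(g) {
    list(indices = which(member == g),
         direction = info[[g]]$direction,
         mean_abs = info[[g]]$mean_abs,
         y_start = bounds[g], y_end = bounds[g + 1L])
  })

  merge_into <- function(segs, from, into) {
    keep <- segs[[into]]
    keep$indices <- sort(union(keep$indices, segs[[from]]$indices))
    keep$y_start <- min(keep$y_start, segs[[from]]$y_start)
    keep$y_end <- max(keep$y_end, segs[[from]]$y_end)
    keep$mean_abs <- max(keep$mean_abs, segs[[from]]$mean_abs)
    segs[[into]] <- keep
    segs[-from]
  }

  repeat {
    sizes <- vapply(segs, function(s) length(s$indices), integer(1))
    if (length(segs) <= 1L) break
    # coalesce same-direction neighbours first
    same <- which(vapply(seq_len(length(segs) - 1L), function(i) {
      segs[[i]]$direction == segs[[i + 1L]]$direction
    }, logical(1)))
    if (length(same)) {
      segs <- merge_into(segs, same[1] + 1L, same[1])
      next
    }
    small <- which(sizes < 2L)
    if (!length(small)) break
    i <- small[1]
    neighbours <- intersect(c(i - 1L, i + 1L), seq_along(segs))
    target <- neighbours[which.max(vapply(neighbours, function(j) {
      segs[[j]]$mean_abs
    }, numeric(1)))]
    segs <- merge_into(segs, i, target)
  }

  lapply(segs, function(s) {
    structure(list(vertebra_indices = s$indices,
                   direction = s$direction,
                   boundary_y = c(s$y_start, s$y_end)),
              class = "curve_segment")
  })
}
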