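# Parametric synthetic spines with analytically known curve angles.
#
# The centerline is a sum of sinusoids x(y) = sum_i A_i sin(k_i y + phi_i)
# over y in [0, L]; vertebra centroids sit on it at equal y spacing and each
# vertebra is a rigid rectangle whose endplates are exactly perpendicular to
# the local tangent.  The true Cobb angle of a bending segment is therefore
# the max-minus-min of the tangent angles atan(dx/dy) over the member
# centroids, which is known in closed form.

#' Synthetic spine shape parameters
#'
#' @param n_vertebrae Number of vertebrae (>= 4); the default 17 matches a
#'   full thoracolumbar spine (T1-L5).
#' @param centerline List of sinusoid terms, each a numeric vector
#'   `c(amplitude, wavenumber, phase)` (pixels, 1/pixels, radians) defining
#'   the lateral displacement `x(y) = sum A * sin(k * y + phi)`.
#' @param length Craniocaudal span L of the centroid column, pixels.
#' @param vertebra_height,vertebra_width Rectangle size in pixels.
#' @param keypoint_noise_sd SD of i.i.d. Gaussian noise added to every corner
#'   coordinate, pixels (0 = noiseless).
#' @param seed Integer seed controlling the corner noise.
#' @return Validated object of class `spine_shape_params`.
#' @examples
#' p <- spine_shape_params(centerline = list(c(40, pi / 800, 0)))
#' @export
spine_shape_params <- function(n_vertebrae = 17,
                               centerline = list(c(40, pi / 800, 0)),
                               length = 800,
                               vertebra_height = 40,
                               vertebra_width = 60,
                               keypoint_noise_sd = 0,
                               seed = 1L) {
  centerline <- lapply(centerline, function(term) {
    term <- as.numeric(term)
    if (base::length(term) != 3L || !all(is.finite(term))) {
      stop("each centerline term must be c(amplitude, wavenumber, phase)",
           call. = FALSE)
    }
    names(term) <- c("amplitude", "wavenumber", "phase")
    term
  })
  p <- structure(
    list(n_vertebrae = as.integer(n_vertebrae), centerline = centerline,
         length = as.numeric(length),
         vertebra_height = as.numeric(vertebra_height),
         vertebra_width = as.numeric(vertebra_width),
         keypoint_noise_sd = as.numeric(keypoint_noise_sd),
         seed = as.integer(seed)),
    class = "spine_shape_params")
  if (p$n_vertebrae < 4L) stop("n_vertebrae must be >= 4", call. = FALSE)
  if (p$length <= 0) stop("length must be > 0", call. = FALSE)
  if (p$vertebra_height * p$n_vertebrae > 1.2 * p$length) {
    stop("vertebrae grossly overlap: need vertebra_height * n_vertebrae <= 1.2 * length",
         call. = FALSE)
  }
  if (p$keypoint_noise_sd < 0) stop("keypoint_noise_sd must be >= 0", call. = FALSE)
  p
}

#' Single-curve parameters with a target true Cobb angle
#'
#' Convenience constructor: a half-period sinusoid whose maximum slope
#' magnitude is `tan(angle/2)`, so the discrete true Cobb angle between the
#' two extreme vertebrae (which sit at the slope extrema y = 0 and y = L)
#' is exactly `angle` degrees.
#'
#' @param angle Target true Cobb angle, degrees.
#' @param phase Phase offset in radians (default 0: pure half period).
#' @inheritParams spine_shape_params
#' @param ... Passed to [spine_shape_params()].
#' @return A `spine_shape_params` object.
#' @export
spine_shape_for_angle <- function(angle, length = 800, phase = 0, ...) {
  k <- pi / length
  a <- tan(angle * pi / 360) / k   # A * k = tan(angle / 2)
  spine_shape_params(centerline = list(c(a, k, phase)), length = length, ...)
}

# Centerline and derivatives in the generator's own (unshifted) frame.
centerline_x <- function(params, y) {
  Reduce(`+`, lapply(params$centerline, function(t) {
    t[["amplitude"]] * sin(t[["wavenumber"]] * y + t[["phase"]])
  }), accumulate = FALSE, init = rep(0, length(y)))
}

centerline_dx <- function(params, y) {
  Reduce(`+`, lapply(params$centerline, function(t) {
    t[["amplitude"]] * t[["wavenumber"]] * cos(t[["wavenumber"]] * y + t[["phase"]])
  }), init = rep(0, length(y)))
}

centerline_d2x <- function(params, y) {
  Reduce(`+`, lapply(params$centerline, function(t) {
    -t[["amplitude"]] * t[["wavenumber"]]^2 * sin(t[["wavenumber"]] * y + t[["phase"]])
  }), init = rep(0, length(y)))
}

# Equal y spacing of centroids over [0, L], endpoints included, so the slope
# extrema of a pure half-period sinusoid carry vertebrae.
centroid_grid <- function(params) {
  seq(0, params$length, length.out = params$n_vertebrae)
}

# Zeros of x''(y) strictly inside (0, L), located by sign change on a dense
# grid and polished with uniroot.  An identically (near-)zero second
# derivative yields no inflections.
inflection_zeros <- function(params) {
  yy <- seq(0, params$length, length.out = 4096L)
  d2 <- centerline_d2x(params, yy)
  scale <- max(abs(d2))
  if (scale < 1e-15) return(numeric())
  s <- sign(d2)
  s[abs(d2) < 1e-9 * scale] <- 0
  zeros <- numeric()
  for (i in seq_len(length(yy) - 1L)) {
    if (s[i] != 0 && s[i + 1L] != 0 && s[i] != s[i + 1L]) {
      r <- stats::uniroot(function(y) centerline_d2x(params, y),
                          lower = yy[i], upper = yy[i + 1L],
                          tol = 1e-10 * params$length)
      zeros <- c(zeros, r$root)
    }
  }
  zeros[zeros > 1e-9 * params$length &
          zeros < params$length * (1 - 1e-9)]
}

# Assign each centroid y to the inflection interval containing it; a centroid
# exactly on a boundary belongs to the earlier (more cranial) interval.
interval_membership <- function(y_centroids, zeros, span) {
  breaks <- c(-Inf, zeros, Inf)
  findInterval(y_centroids, breaks, left.open = TRUE)
}

#' Generate a synthetic spine annotation with ground truth
#'
#' Places `n_vertebrae` rigid rectangles on the parametric centerline
#' (centroids at equal y spacing, endplates perpendicular to the local
#' tangent), optionally perturbs every corner with i.i.d. Gaussian noise, and
#' returns both the annotation and the ground truth computed from the
#' unperturbed geometry.
#'
#' The whole construction is shifted into the positive quadrant (a fixed
#' margin depending only on the parameters) so that annotation invariants on
#' pixel coordinates hold.
#'
#' @param params A [spine_shape_params()] object.
#' @param subject_id Subject identifier for the annotation.
#' @return List with components `annotation` (a [spine_annotation()]) and
#'   `truth`, itself a list: `orientation_deg` (true tangent angle at each
#'   centroid, degrees), `inflection_y` (inflection y positions in annotation
#'   pixel coordinates), `segments` (data frame: member vertebra range and
#'   true Cobb angle per bending segment with >= 2 vertebrae).
#' @examples
#' gs <- generate_spine(spine_shape_for_angle(30))
#' gs$truth$segments
#' @export
generate_spine <- function(params, subject_id = "synthetic") {
  stopifnot(inherits(params, "spine_shape_params"))
  yc <- centroid_grid(params)
  if (any(diff(yc) <= 0)) {
    stop("generated centroids are not monotone in y; use a smaller amplitude",
         call. = FALSE)
  }
  xc <- centerline_x(params, yc)
  slope <- centerline_dx(params, yc)          # dx/dy at each centroid
  orientation <- atan(slope) * 180 / pi

  # fixed margin keeping all (noisy) corners non-negative
  amp <- sum(vapply(params$centerline, function(t) abs(t[["amplitude"]]),
                    numeric(1)))
  half_diag <- (params$vertebra_width + params$vertebra_height) / 2
  margin <- half_diag + 10 + 6 * params$keypoint_noise_sd
  x0 <- amp + margin
  y0 <- margin

  h2 <- params$vertebra_height / 2
  w2 <- params$vertebra_width / 2
  corners <- lapply(seq_len(params$n_vertebrae), function(i) {
    s <- slope[i]
    nrm <- sqrt(1 + s^2)
    tvec <- c(s, 1) / nrm        # tangent, pointing caudally
    evec <- c(1, -s) / nrm       # endplate direction, positive x
    c0 <- c(x0 + xc[i], y0 + yc[i])
    rbind(UL = c0 - h2 * tvec - w2 * evec,
          UR = c0 - h2 * tvec + w2 * evec,
          LR = c0 + h2 * tvec + w2 * evec,
          LL = c0 + h2 * tvec - w2 * evec)
  })

  if (params$keypoint_noise_sd > 0) {
    corners <- with_seed(params$seed, {
      lapply(corners, function(m) {
        m <- m + matrix(stats::rnorm(8, sd = params$keypoint_noise_sd), 4, 2)
        pmax(m, 0)
      })
    })
  }

  vertebrae <- lapply(seq_along(corners), function(i) {
    vertebra_keypoints(label = i - 1L, corners = corners[[i]])
  })
  annotation <- spine_annotation(subject_id = subject_id, vertebrae = vertebrae)

  zeros <- inflection_zeros(params)
  member <- interval_membership(yc, zeros, params$length)
  seg_ids <- sort(unique(member))
  segs <- do.call(rbind, lapply(seg_ids, function(g) {
    idx <- which(member == g)
    if (length(idx) < 2L) return(NULL)
    data.frame(first = min(idx), last = max(idx),
               angle = max(orientation[idx]) - min(orientation[idx]))
  }))
  if (is.null(segs)) {
    segs <- data.frame(first = integer(), last = integer(), angle = numeric())
  }

  list(annotation = annotation,
       truth = list(orientation_deg = orientation,
                    inflection_y = zeros + y0,
                    segments = segs))
}

#' Analytic per-segment Cobb angles of a parametric spine
#'
#' Splits the centerline at the sign changes of its closed-form second
#' derivative and returns, for every maximal interval containing at least two
#' vertebra centroids, the max-minus-min of the true tangent angles over the
#' member centroids, in degrees.  Corner noise is ignored (this is the
#' noiseless oracle).  A straight spine returns a single 0-degree segment.
#'
#' @param params A [spine_shape_params()] object.
#' @return Numeric vector of per-segment true Cobb angles, degrees, in
#'   cranial-to-caudal segment order.
#' @export
analytic_cobb <- function(params) {
  stopifnot(inherits(params, "spine_shape_params"))
  yc <- centroid_grid(params)
  orientation <- atan(centerline_dx(params, yc)) * 180 / pi
  zeros <- inflection_zeros(params)
  member <- interval_membership(yc, zeros, params$length)
  out <- vapply(sort(unique(member)), function(g) {
    idx <- which(member == g)
    if (length(idx) < 2L) return(NA_real_)
    max(orientation[idx]) - min(orientation[idx])
  }, numeric(1))
  out <- out[!is.na(out)]
  if (!length(out)) out <- 0
  out
}

#' Simulate paired Cobb-angle measurements around known truths
#'
#' Each measurement is `truth + subject effect + method bias + N(0, sd^2)`
#' noise, drawn independently per replicate; the per-subject effect
#' (`N(0, subject_sd^2)`) is drawn once per subject and shared by all of that
#' subject's measurements.  Draws below 0 are clamped to 0 (angles are
#' non-negative) and the number of clamped values is reported in the
#' `"n_clamped"` attribute.
#'
#' @param truths Numeric vector of true angles, degrees; one per subject.
#' @param methods Data frame with columns `name`, `bias`, `sd` (degrees), one
#'   row per measurement method (or rater, when simulating rater panels).
#' @param n_replicates Replicates per subject x method.
#' @param subject_sd SD of the shared per-subject deviation, degrees.
#' @param seed Integer seed; the output is deterministic given the seed.
#' @return A [paired_measurements()] data frame (rater fixed at `"r1"`), with
#'   attribute `n_clamped`.
#' @export
simulate_paired_measurements <- function(truths, methods, n_replicates = 1,
                                         subject_sd = 0, seed = 1L) {
  methods <- as.data.frame(methods)
  stopifnot(all(c("name", "bias", "sd") %in% names(methods)),
            all(methods$sd >= 0), subject_sd >= 0)
  n <- length(truths)
  subjects <- sprintf("s%0*d", nchar(n), seq_len(n))
  with_seed(seed, {
    subj_eff <- stats::rnorm(n, 0, subject_sd)
    rows <- list()
    for (m in seq_len(nrow(methods))) {
      for (r in seq_len(n_replicates)) {
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = subjects,
          method = methods$name[m],
          rater = "r1",
          replicate = r,
          angle = truths + subj_eff + methods$bias[m] +
            stats::rnorm(n, 0, methods$sd[m]))
      }
    }
    df <- do.call(rbind, rows)
    n_clamped <- sum(df$angle < 0)
    df$angle <- pmax(df$angle, 0)
    out <- paired_measurements(df)
    attr(out, "n_clamped") <- n_clamped
    out
  })
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
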