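# Shared fixture builders and independent oracles.  The oracles work
# directly on corner coordinates with atan2 arithmetic and never call the
# production angle/search code they are used to check.

# Corners (UL, UR, LR, LL) of a w x h rectangle centred at (cx, cy), rotated
# by `tilt` degrees (positive = clockwise in image coordinates, i.e. the
# right edge moves caudally).
make_rect <- function(cx, cy, w = 60, h = 40, tilt = 0) {
  th <- tilt * pi / 180
  e <- c(cos(th), sin(th))        # endplate direction
  t <- c(-sin(th), cos(th))       # cranio-caudal direction
  c0 <- c(cx, cy)
  rbind(UL = c0 - h / 2 * t - w / 2 * e,
        UR = c0 - h / 2 * t + w / 2 * e,
        LR = c0 + h / 2 * t + w / 2 * e,
        LL = c0 + h / 2 * t - w / 2 * e)
}

# A vertical stack of rectangles with per-vertebra tilts (degrees).
make_stack <- function(tilts, spacing = 50, w = 60, h = 40, x = 200, y0 = 100,
                       subject_id = "stack") {
  vertebrae <- lapply(seq_along(tilts), function(i) {
    vertebra_keypoints(i - 1L,
                       make_rect(x, y0 + (i - 1) * spacing, w, h, tilts[i]))
  })
  spine_annotation(subject_id, vertebrae)
}

# Oracle: angle of an edge line from horizontal, degrees in (-90, 90].
oracle_edge_angle <- function(corners, edge) {
  pts <- if (edge == "upper") corners[c("UL", "UR"), ] else corners[c("LL", "LR"), ]
  d <- pts[2, ] - pts[1, ]
  a <- as.numeric(atan2(d[2], d[1]) * 180 / pi)
  if (a > 90) a <- a - 180
  if (a <= -90) a <- a + 180
  a
}

# Oracle: intersection angle of two lines given their angles from
# horizontal, folded into [0, 90] degrees.
oracle_pair_angle <- function(a1, a2) {
  d <- abs(a1 - a2) %% 180
  min(d, 180 - d)
}

# Oracle: naive exhaustive search over all (upper edge of i, lower edge of j),
# i <= j, with the floor; ties broken by longest span then smallest i.
# Written independently of segment_cobb.
oracle_segment_cobb <- function(annotation, indices, floor = 5) {
  best <- NULL
  for (a in seq_along(indices)) {
    for (b in seq_along(indices)) {
      if (b < a) next
      ca <- annotation$vertebrae[[indices[a]]]$corners
      cb <- annotation$vertebrae[[indices[b]]]$corners
      theta <- oracle_pair_angle(oracle_edge_angle(ca, "upper"),
                                 oracle_edge_angle(cb, "lower"))
      if (theta < floor) next
      cand <- list(angle = theta, a = a, b = b, span = b - a)
      if (is.null(best)) { best <- cand; next }
      if (theta > best$angle) { best <- cand; next }
      if (theta == best$angle &&
          (cand$span > best$span || (cand$span == best$span && a < best$a))) {
        best <- cand
      }
    }
  }
  if (is.null(best)) return(NULL)
  list(angle = best$angle,
       upper = annotation$vertebrae[[indices[best$a]]]$label,
       lower = annotation$vertebrae[[indices[best$b]]]$label)
}

# Random valid annotation for round-trip property tests.
random_annotation <- function(subject_id = "rand") {
  n <- sample(4:12, 1)
  tilts <- runif(n, -25, 25)
  make_stack(tilts, spacing = runif(1, 45, 70), w = runif(1, 50, 70),
             h = runif(1, 30, 45), x = runif(1, 150, 400),
             y0 = runif(1, 60, 140), subject_id = subject_id)
}

# Minimal cobb_report carrying one (major) measurement, for offset-table
# tests that do not need the full pipeline.
make_report <- function(subject_id, upper, lower, angle = 30) {
  m <- structure(list(angle = angle, upper_end_vertebra = upper,
                      lower_end_vertebra = lower),
                 class = "cobb_measurement")
  structure(list(subject_id = subject_id, measurements = list(m),
                 major_angle = angle, minor_angle = NA_real_,
                 severity = classify_severity(angle), n_segments = 1L),
            class = "cobb_report")
}
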