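# Endplate-line fitting, the exhaustive angle search with the 5-degree
# floor, and major/minor report assembly.

#' Fit an endplate line to a vertebra edge
#'
#' The superior endplate is the line through the UL and UR corners, the
#' inferior endplate the line through the LL and LR corners.  With exactly
#' two points the fit is exact interpolation.  The direction vector is
#' normalized with `direction_x >= 0`; a vertical line gets direction (0, 1)
#' and an undefined slope.
#'
#' @param vertebra A [vertebra_keypoints()] object.
#' @param edge `"upper"` or `"lower"`.
#' @return Object of class `endplate_line` with `vertebra_label`, `edge`,
#'   `direction` (unit 2-vector), `slope` (`NA` when vertical) and `anchor`.
#' @export
fit_endplate_line <- function(vertebra, edge = c("upper", "lower")) {
  stopifnot(inherits(vertebra, "vertebra_keypoints"))
  edge <- match.arg(edge)
  pts <- if (edge == "upper") {
    vertebra$corners[c("UL", "UR"), ]
  } else {
    vertebra$corners[c("LL", "LR"), ]
  }
  d <- pts[2, ] - pts[1, ]
  len <- sqrt(sum(d^2))
  if (len == 0) {
    stop("degenerate ", edge, " edge (coincident corners) on vertebra '",
         format(vertebra$label), "'", call. = FALSE)
  }
  d <- d / len
  if (d[1] < 0) d <- -d
  slope <- if (d[1] == 0) NA_real_ else unname(d[2] / d[1])
  structure(list(vertebra_label = vertebra$label, edge = edge,
                 direction = unname(d), slope = slope,
                 anchor = unname(pts[1, ])),
            class = "endplate_line")
}

#' Angle between two endplate lines
#'
#' Computed from the unit direction vectors as
#' `theta = acos(|d1 . d2|)` in degrees, which equals the slope form
#' `atan(|(m1 - m2) / (1 + m1 m2)|)` whenever both slopes are defined and
#' `1 + m1 m2 != 0`, returns 90 when the lines are perpendicular, and remains
#' well defined for vertical lines.  The result is always in [0, 90].
#'
#' @param line1,line2 [fit_endplate_line()] objects.
#' @return Angle in degrees.
#' @export
angle_between <- function(line1, line2) {
  stopifnot(inherits(line1, "endplate_line"), inherits(line2, "endplate_line"))
  c_ <- abs(sum(line1$direction * line2$direction))
  acos(min(1, c_)) * 180 / pi
}

#' Cobb angle of one bending segment by exhaustive line search
#'
#' Enumerates every pair (superior endplate of vertebra i, inferior endplate
#' of vertebra j) with i <= j, both inside the segment, computes the
#' intersection angle of each pair, discards pairs below the floor (default
#' 5 degrees), and returns the pair with the maximal angle together with its
#' end-vertebra labels.  Ties are broken by the longest vertebral span
#' (largest j - i), then by the most cranial i.  When no pair survives the
#' floor the segment has no measurable curve and `NULL` is returned.
#'
#' @param segment A `curve_segment` from [segment_by_inflection()].
#' @param annotation The [spine_annotation()] it indexes into.
#' @param floor Minimum reportable angle, degrees.
#' @return Object of class `cobb_measurement` (fields `angle`,
#'   `upper_end_vertebra`, `lower_end_vertebra`, `upper_line`, `lower_line`,
#'   `segment`) or `NULL`.
#' @export
segment_cobb <- function(segment, annotation, floor = 5) {
  stopifnot(inherits(segment, "curve_segment"),
            inherits(annotation, "spine_annotation"))
  idx <- segment$vertebra_indices
  uppers <- lapply(annotation$vertebrae[idx], fit_endplate_line, edge = "upper")
  lowers <- lapply(annotation$vertebrae[idx], fit_endplate_line, edge = "lower")
  best <- NULL
  for (a in seq_along(idx)) {
    for (b in a:length(idx)) {
      theta <- angle_between(uppers[[a]], lowers[[b]])
      if (theta < floor) next
      span <- b - a
      if (is.null(best) || theta > best$angle ||
          (theta == best$angle &&
             (span > best$span || (span == best$span && a < best$a)))) {
        best <- list(angle = theta, a = a, b = b, span = span)
      }
    }
  }
  if (is.null(best)) return(NULL)
  structure(list(
    angle = best$angle,
    upper_end_vertebra = annotation$vertebrae[[idx[best$a]]]$label,
    lower_end_vertebra = annotation$vertebrae[[idx[best$b]]]$label,
    upper_line = uppers[[best$a]],
    lower_line = lowers[[best$b]],
    segment = segment),
    class = "cobb_measurement")
}

#' Severity grade of a Cobb angle
#'
#' Clinical bands: mild below 25 degrees, moderate from 25 to 45 degrees
#' inclusive, severe above 45 degrees.
#'
#' @param angle Cobb angle in degrees (>= 0).
#' @return `"mild"`, `"moderate"` or `"severe"`.
#' @examples
#' classify_severity(24.92)  # mild
#' classify_severity(45)     # moderate
#' @export
classify_severity <- function(angle) {
  if (!is.numeric(angle) || length(angle) != 1L || !is.finite(angle) || angle < 0) {
    stop("angle must be a single finite value >= 0", call. = FALSE)
  }
  if (angle < 25) "mild" else if (angle <= 45) "moderate" else "severe"
}

#' Measure all curves of a spine
#'
#' Runs the full pipeline: MLS centerline fit, polynomial second derivative,
#' inflection segmentation, and per-segment exhaustive endplate angle search.
#' The largest surviving angle is the major curve, the second largest the
#' minor; severity is graded from the major angle.  A spine on which no
#' segment survives the floor yields an empty report (no angles, severity
#' absent).
#'
#' @param annotation A [spine_annotation()].
#' @param bandwidth,grid_size Passed to [fit_centerline_mls()].
#' @param poly_degree Passed to [second_derivative_poly()].
#' @param floor Passed to [segment_cobb()].
#' @return Object of class `cobb_report` with `subject_id`, `measurements`
#'   (list of `cobb_measurement`, cranial-to-caudal segment order),
#'   `major_angle`, `minor_angle` (NA when absent), `severity` (NA when the
#'   report is empty), `n_segments`.
#' @examples
#' r <- measure_spine(generate_spine(spine_shape_for_angle(30))$annotation)
#' r$major_angle
#' @export
measure_spine <- function(annotation, bandwidth = "auto", poly_degree = 6,
                          grid_size = 200, floor = 5) {
  fit <- fit_centerline_mls(annotation, bandwidth = bandwidth,
                            grid_size = grid_size)
  fit <- second_derivative_poly(fit, degree = poly_degree)
  segments <- segment_by_inflection(fit, annotation)
  measurements <- Filter(Negate(is.null),
                         lapply(segments, segment_cobb,
                                annotation = annotation, floor = floor))
  angles <- vapply(measurements, `[[`, numeric(1), "angle")
  ord <- order(angles, decreasing = TRUE)
  major <- if (length(angles)) angles[ord[1]] else NA_real_
  minor <- if (length(angles) >= 2L) angles[ord[2]] else NA_real_
  structure(list(
    subject_id = annotation$subject_id,
    measurements = measurements,
    major_angle = major,
    minor_angle = minor,
    severity = if (is.na(major)) NA_character_ else classify_severity(major),
    n_segments = length(segments),
    fit = fit),
    class = "cobb_report")
}

#' @export
print.cobb_report <- function(x, ...) {
  if (is.na(x$major_angle)) {
    cat(sprintf("<cobb_report> subject '%s': no measurable curve\n", x$subject_id))
    return(invisible(x))
  }
  cat(sprintf("<cobb_report> subject '%s': major %.1f deg (%s)%s, %d curve(s)\n",
              x$subject_id, x$major_angle, x$severity,
              if (!is.na(x$minor_angle)) {
                sprintf(", minor %.1f deg", x$minor_angle)
              } else "",
              length(x$measurements)))
  for (m in x$measurements) {
    cat(sprintf("  %s..%s: %.2f deg\n", format(m$upper_end_vertebra),
                format(m$lower_end_vertebra), m$angle))
  }
  invisible(x)
}

# major measurement of a report (the one with the largest angle), or NULL
major_measurement <- function(report) {
  if (!length(report$measurements)) return(NULL)
  angles <- vapply(report$measurements, `[[`, numeric(1), "angle")
  report$measurements[[which.max(angles)]]
}

#' End-vertebra level-offset table between two methods
#'
#' For reports paired by subject, tabulates how far (in vertebral levels) the
#' major curve's end-vertebra choice of method A sits from method B's choice,
#' separately for the upper and the lower end vertebra.  Offsets are
#' `level(A) - level(B)`: negative means A chose a more cranial vertebra.
#' Counts and percentages are reported for offsets -2..+2 plus an `"other"`
#' bucket.
#'
#' @param reports_a,reports_b Lists of `cobb_report` objects; every subject
#'   in `reports_a` must appear in `reports_b` and both reports must carry a
#'   major measurement with level-resolvable labels.
#' @return List with data frames `upper` and `lower` (columns `offset`,
#'   `count`, `percent`) and `n` subjects.
#' @export
end_vertebra_offsets <- function(reports_a, reports_b) {
  ids_a <- vapply(reports_a, `[[`, character(1), "subject_id")
  ids_b <- vapply(reports_b, `[[`, character(1), "subject_id")
  missing <- setdiff(ids_a, ids_b)
  if (length(missing)) {
    stop("unpaired subject(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  offsets <- lapply(c(upper = "upper_end_vertebra", lower = "lower_end_vertebra"),
                    function(field) {
    vapply(seq_along(reports_a), function(i) {
      ma <- major_measurement(reports_a[[i]])
      mb <- major_measurement(reports_b[[which(ids_b == ids_a[i])[1]]])
      if (is.null(ma) || is.null(mb)) {
        stop("subject '", ids_a[i], "' lacks a major measurement", call. = FALSE)
      }
      la <- level_index(ma[[field]])
      lb <- level_index(mb[[field]])
      if (is.na(la) || is.na(lb)) {
        stop("subject '", ids_a[i],
             "': end-vertebra labels must be anatomical or integer levels",
             call. = FALSE)
      }
      la - lb
    }, numeric(1))
  })
  n <- length(reports_a)
  tab <- function(off) {
    levels <- c(-2, -1, 0, 1, 2)
    counts <- vapply(levels, function(l) sum(off == l), numeric(1))
    counts <- c(counts, other = n - sum(counts))
    data.frame(offset = c(as.character(levels), "other"),
               count = as.integer(counts),
               percent = 100 * counts / n,
               row.names = NULL)
  }
  list(upper = tab(offsets$upper), lower = tab(offsets$lower), n = n)
}
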