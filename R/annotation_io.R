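# Keypoint data model and annotation/measurement file I/O.
#
# Coordinate convention (fixed for the whole package): image pixel
# coordinates, origin at the top-left, y increasing caudally.  "Upper"
# (superior) structures therefore have the SMALLER y.  Corner order within a
# vertebra is fixed and validated: upper-left, upper-right, lower-right,
# lower-left.

CORNER_NAMES <- c("UL", "UR", "LR", "LL")

#' One vertebra's four corner keypoints
#'
#' Constructs and validates the detector-output contract for a single
#' vertebra: four corner points in pixel coordinates, in the fixed order
#' upper-left, upper-right, lower-right, lower-left (image coordinates,
#' origin top-left, y increasing caudally).
#'
#' @param label Anatomical level (`"T1"`..`"T12"`, `"L1"`..`"L5"`) or a
#'   non-negative integer index.
#' @param corners Numeric 4 x 2 matrix (columns x, y) of corner positions in
#'   pixels, rows ordered UL, UR, LR, LL.
#' @return An object of class `vertebra_keypoints`.
#' @examples
#' v <- vertebra_keypoints("T5", rbind(c(0, 0), c(60, 0), c(60, 40), c(0, 40)))
#' v$label
#' @export
vertebra_keypoints <- function(label, corners) {
  corners <- as.matrix(corners)
  if (!is.numeric(corners) || !identical(dim(corners), c(4L, 2L))) {
    stop("vertebra '", format(label), "': corners must be a 4 x 2 numeric matrix",
         call. = FALSE)
  }
  dimnames(corners) <- list(CORNER_NAMES, c("x", "y"))
  v <- structure(list(label = label, corners = corners),
                 class = "vertebra_keypoints")
  problems <- validate_vertebra(v)
  if (length(problems)) {
    stop("invalid vertebra '", format(label), "': ",
         paste(problems, collapse = "; "), call. = FALSE)
  }
  v
}

# Returns character vector of invariant violations (empty when valid).
validate_vertebra <- function(v) {
  p <- character()
  xy <- v$corners
  if (!all(is.finite(xy))) {
    return("corner coordinates must all be finite")
  }
  if (any(xy < 0)) p <- c(p, "corner coordinates must be non-negative")
  upper_y <- mean(xy[c("UL", "UR"), "y"])
  lower_y <- mean(xy[c("LR", "LL"), "y"])
  if (!(upper_y < lower_y)) {
    p <- c(p, "upper edge must be cranial to lower edge (smaller y)")
  }
  if (!is_simple_quad(xy)) {
    p <- c(p, "corners must form a simple (non-self-intersecting) quadrilateral")
  }
  p
}

# Proper-crossing test for segments p1-p2 and p3-p4 (shared endpoints do not
# count as a crossing).
segments_cross <- function(p1, p2, p3, p4) {
  orient <- function(a, b, c) {
    (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  }
  d1 <- orient(p3, p4, p1)
  d2 <- orient(p3, p4, p2)
  d3 <- orient(p1, p2, p3)
  d4 <- orient(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

# A quadrilateral UL-UR-LR-LL is simple iff its two pairs of opposite sides
# do not cross.
is_simple_quad <- function(xy) {
  !segments_cross(xy[1, ], xy[2, ], xy[3, ], xy[4, ]) &&
    !segments_cross(xy[2, ], xy[3, ], xy[4, ], xy[1, ])
}

#' Vertebra centroid
#'
#' Mean of the four corner keypoints, in pixels.
#'
#' @param v A [vertebra_keypoints()] object.
#' @return Named numeric vector `c(x =, y =)`.
#' @export
vertebra_centroid <- function(v) {
  colMeans(v$corners)
}

# Anatomical level -> ordinal index (T1..T12 -> 1..12, L1..L5 -> 13..17).
# Integer labels map to themselves; anything else is NA.
level_index <- function(label) {
  if (is.numeric(label)) return(as.numeric(label))
  label <- as.character(label)
  if (grepl("^T(1[0-2]|[1-9])$", label)) {
    return(as.numeric(sub("^T", "", label)))
  }
  if (grepl("^L[1-5]$", label)) {
    return(12 + as.numeric(sub("^L", "", label)))
  }
  NA_real_
}

#' Full-spine annotation
#'
#' An ordered cranial-to-caudal list of vertebra keypoint sets with optional
#' image metadata.  This is the input contract of the measurement pipeline;
#' at least 4 vertebrae are required (fewer cannot support curve segmentation
#' plus the endplate angle search) and centroids must strictly increase in y.
#'
#' @param subject_id Character scalar identifying the radiograph/subject.
#' @param vertebrae List of [vertebra_keypoints()] objects, cranial first.
#' @param image_size Optional `c(width, height)` in pixels.
#' @param pixel_spacing Optional mm/pixel scalar (metadata only; angles are
#'   unit free).
#' @return An object of class `spine_annotation`.
#' @export
spine_annotation <- function(subject_id, vertebrae, image_size = NULL,
                             pixel_spacing = NULL) {
  if (!is.character(subject_id) || length(subject_id) != 1L) {
    stop("subject_id must be a single character string", call. = FALSE)
  }
  if (!is.list(vertebrae) ||
      !all(vapply(vertebrae, inherits, logical(1), "vertebra_keypoints"))) {
    stop("vertebrae must be a list of vertebra_keypoints objects", call. = FALSE)
  }
  ann <- structure(list(subject_id = subject_id, vertebrae = vertebrae,
                        image_size = image_size, pixel_spacing = pixel_spacing),
                   class = "spine_annotation")
  problems <- validate_annotation(ann)
  if (length(problems)) {
    stop("invalid annotation '", subject_id, "': ",
         paste(problems, collapse = "; "), call. = FALSE)
  }
  ann
}

validate_annotation <- function(ann) {
  p <- character()
  n <- length(ann$vertebrae)
  if (n < 4L) {
    p <- c(p, sprintf("needs >= 4 vertebrae, got %d", n))
    return(p)
  }
  cy <- vapply(ann$vertebrae, function(v) vertebra_centroid(v)[["y"]], numeric(1))
  if (any(diff(cy) <= 0)) {
    bad <- which(diff(cy) <= 0)[1] + 1L
    p <- c(p, sprintf(
      "vertebra centroids must strictly increase in y (cranial->caudal); violated at vertebra '%s'",
      format(ann$vertebrae[[bad]]$label)))
  }
  labels <- lapply(ann$vertebrae, `[[`, "label")
  lv <- vapply(labels, level_index, numeric(1))
  anatomical <- vapply(labels, is.character, logical(1))
  if (any(anatomical)) {
    if (anyNA(lv[anatomical])) {
      bad <- labels[anatomical][which(is.na(lv[anatomical]))[1]]
      p <- c(p, sprintf("unknown anatomical label '%s'", bad))
    } else {
      if (anyDuplicated(unlist(labels[anatomical]))) {
        p <- c(p, "anatomical labels must be unique")
      }
      if (any(diff(lv[anatomical]) <= 0)) {
        p <- c(p, "anatomical labels must be in cranial->caudal order")
      }
    }
  }
  p
}

#' @export
print.spine_annotation <- function(x, ...) {
  cat(sprintf("<spine_annotation> subject '%s', %d vertebrae (%s .. %s)\n",
              x$subject_id, length(x$vertebrae),
              format(x$vertebrae[[1]]$label),
              format(x$vertebrae[[length(x$vertebrae)]]$label)))
  invisible(x)
}

#' Annotation centroids as a matrix
#'
#' @param annotation A [spine_annotation()].
#' @return n x 2 matrix of centroid (x, y) positions in pixels.
#' @export
annotation_centroids <- function(annotation) {
  t(vapply(annotation$vertebrae, vertebra_centroid, numeric(2)))
}

## ---- annotation JSON I/O ---------------------------------------------------

#' Read spine annotations from JSON
#'
#' Reads annotation files in the package's JSON schema:
#' `{"annotations": [{"subject_id", "image_size", "pixel_spacing",
#' "vertebrae": [{"label", "corners": [[x,y] x 4]}]}]}` (see
#' `system.file("extdata", "annotation-schema.json", package = "cobbangle")`).
#' Every annotation is validated on read; vertebra order is preserved.
#'
#' @param path Path to an annotation JSON file.
#' @return List of [spine_annotation()] objects.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  raw <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) {
      stop("malformed annotation JSON in '", path, "': ", conditionMessage(e),
           call. = FALSE)
    })
  if (is.null(raw$annotations)) {
    stop("annotation JSON must have a top-level 'annotations' array", call. = FALSE)
  }
  lapply(raw$annotations, function(a) {
    sid <- a$subject_id
    if (is.null(sid)) stop("annotation missing subject_id", call. = FALSE)
    vertebrae <- lapply(a$vertebrae, function(vj) {
      if (is.null(vj$corners) || length(vj$corners) != 4L) {
        stop("subject '", sid, "', vertebra '", format(vj$label),
             "': exactly 4 corners required", call. = FALSE)
      }
      corners <- do.call(rbind, lapply(vj$corners, function(pt) {
        if (length(pt) != 2L) {
          stop("subject '", sid, "', vertebra '", format(vj$label),
               "': corner must be an [x, y] pair", call. = FALSE)
        }
        as.numeric(pt)
      }))
      withCallingHandlers(
        vertebra_keypoints(parse_label(vj$label), corners),
        error = function(e) e)
    })
    tryCatch(
      spine_annotation(
        subject_id = as.character(sid),
        vertebrae = vertebrae,
        image_size = if (!is.null(a$image_size)) as.numeric(unlist(a$image_size)),
        pixel_spacing = if (!is.null(a$pixel_spacing)) as.numeric(a$pixel_spacing)),
      error = function(e) {
        stop("subject '", sid, "': ", conditionMessage(e), call. = FALSE)
      })
  })
}

parse_label <- function(label) {
  if (is.null(label)) stop("vertebra missing label", call. = FALSE)
  if (is.numeric(label)) return(as.integer(label))
  as.character(label)
}

#' Write spine annotations to JSON
#'
#' Lossless counterpart of [read_annotations()]: coordinates are serialized
#' at full double precision so that a write/read round trip reproduces the
#' input exactly.
#'
#' @param annotations List of [spine_annotation()] objects (may be empty).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_annotations <- function(annotations, path) {
  payload <- list(annotations = lapply(annotations, function(a) {
    stopifnot(inherits(a, "spine_annotation"))
    list(
      subject_id = a$subject_id,
      image_size = a$image_size,
      pixel_spacing = a$pixel_spacing,
      vertebrae = lapply(a$vertebrae, function(v) {
        list(label = v$label,
             corners = lapply(seq_len(4), function(i) unname(v$corners[i, ])))
      }))
  }))
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = I(17),
                           null = "null", pretty = TRUE)
  ok <- tryCatch({ writeLines(json, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write annotation file: ", path, call. = FALSE)
  invisible(path)
}

## ---- paired measurement tables ---------------------------------------------

MEASUREMENT_COLUMNS <- c("subject_id", "method", "rater", "replicate", "angle")

#' Long-format paired Cobb-angle measurements
#'
#' Validates a long-format table of repeated Cobb-angle measurements:
#' one row per (subject, method, rater, replicate), angle in degrees.
#'
#' @param df Data frame with columns `subject_id`, `method`, `rater`,
#'   `replicate`, `angle`.
#' @return The validated data frame with class `paired_measurements`.
#' @export
paired_measurements <- function(df) {
  missing_cols <- setdiff(MEASUREMENT_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("measurement table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df)[MEASUREMENT_COLUMNS]
  df$subject_id <- as.character(df$subject_id)
  df$method <- as.character(df$method)
  df$rater <- as.character(df$rater)
  df$replicate <- as.integer(df$replicate)
  df$angle <- as.numeric(df$angle)
  if (anyNA(df$angle) || any(!is.finite(df$angle)) || any(df$angle < 0)) {
    stop("angles must be finite and >= 0", call. = FALSE)
  }
  key <- paste(df$subject_id, df$method, df$rater, df$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df[which(duplicated(key))[1], ]
    stop(sprintf(
      "duplicate measurement key (subject '%s', method '%s', rater '%s', replicate %d)",
      dup$subject_id, dup$method, dup$rater, dup$replicate), call. = FALSE)
  }
  class(df) <- c("paired_measurements", "data.frame")
  df
}

#' Read paired measurements from CSV
#'
#' Expects a UTF-8 CSV with header
#' `subject_id,method,rater,replicate,angle` ('.' decimal separator).
#'
#' @param path Path to the CSV file.
#' @return A [paired_measurements()] data frame.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("measurement file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  paired_measurements(df)
}

#' Write paired measurements to CSV
#'
#' @param measurements A [paired_measurements()] data frame.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_measurements <- function(measurements, path) {
  stopifnot(inherits(measurements, "paired_measurements"))
  utils::write.csv(as.data.frame(measurements), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
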