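# Regions of interest: simple polygons in display-pixel coordinates
# (origin top-left, x rightward, y downward, 0-based pixel centres).

polygon_area <- function(vertices) {
  x <- vertices[, 1]; y <- vertices[, 2]
  j <- c(seq_len(nrow(vertices))[-1], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

polygon_centroid <- function(vertices) {
  x <- vertices[, 1]; y <- vertices[, 2]
  j <- c(seq_len(nrow(vertices))[-1], 1L)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))  # degenerate: vertex mean
  c(sum((x + x[j]) * cr), sum((y + y[j]) * cr)) / (6 * a)
}

segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

polygon_is_simple <- function(vertices) {
  n <- nrow(vertices)
  for (i in seq_len(n - 2L)) {
    for (j in seq(i + 2L, n)) {
      if (i == 1L && j == n) next  # adjacent through closure
      if (segments_cross(vertices[i, ], vertices[i %% n + 1L, ],
                         vertices[j, ], vertices[j %% n + 1L, ]))
        return(FALSE)
    }
  }
  TRUE
}

#' Define a pointing-target region of interest
#'
#' An ROI is a simple polygon in display-pixel coordinates marking either
#' the correct location of a prompted object feature (`kind = "correct"`)
#' or an incorrect feature that matches the target's local shape
#' properties (`kind = "local_distractor"`, used by the error taxonomy).
#'
#' @param image_id Image identifier.
#' @param target_id Target number (1 or 2).
#' @param vertices Two-column matrix of polygon vertices `(x, y)`,
#'   at least three, forming a simple polygon of positive area.
#' @param kind `"correct"` or `"local_distractor"`.
#' @return An object of class `"roi"` carrying `area_px2` (shoelace area).
#' @export
roi <- function(image_id, target_id, vertices,
                kind = c("correct", "local_distractor")) {
  kind <- match.arg(kind)
  vertices <- as.matrix(vertices)
  if (!is.numeric(vertices) || ncol(vertices) != 2L || nrow(vertices) < 3L)
    stop_invalid("vertices must be a numeric matrix with >= 3 rows and 2 columns")
  if (!all(is.finite(vertices))) stop_invalid("ROI vertices must be finite")
  a <- polygon_area(vertices)
  if (a <= 0) stop_invalid("ROI polygon must have positive area")
  if (!polygon_is_simple(vertices))
    stop_invalid("ROI polygon must be simple (non-self-intersecting)")
  structure(list(image_id = image_id, target_id = as.integer(target_id),
                 vertices = unname(vertices), area_px2 = a, kind = kind),
            class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("ROI [%s, target %d, %s]: %d vertices, area %.1f px^2\n",
              x$image_id, x$target_id, x$kind, nrow(x$vertices), x$area_px2))
  invisible(x)
}

# Vectorized boundary-inclusive even-odd membership test. Points within
# `eps` pixels of an edge count as inside (boundary touches are credited).
points_in_polygon <- function(px, py, vertices, eps = 1e-7) {
  n <- nrow(vertices)
  inside <- logical(length(px))
  on_boundary <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- vertices[i, 1]; yi <- vertices[i, 2]
    xj <- vertices[j, 1]; yj <- vertices[j, 2]
    len2 <- (xj - xi)^2 + (yj - yi)^2
    tt <- ((px - xi) * (xj - xi) + (py - yi) * (yj - yi)) / max(len2, eps^2)
    tt <- pmin(pmax(tt, 0), 1)
    d2 <- (px - (xi + tt * (xj - xi)))^2 + (py - (yi + tt * (yj - yi)))^2
    on_boundary <- on_boundary | d2 <= eps^2
    crosses <- ((yi > py) != (yj > py)) &
      (px < xi + (py - yi) * (xj - xi) / (yj - yi))
    inside <- xor(inside, crosses & !is.na(crosses))
    j <- i
  }
  inside | on_boundary
}

#' Test whether a touch falls inside an ROI
#'
#' Boundary-inclusive point-in-polygon test: touches on the polygon
#' boundary are scored as inside.
#'
#' @param touch Numeric length-2 vector `(x, y)` in display pixels.
#' @param roi An [roi()] object.
#' @return `TRUE` if the touch is inside or on the boundary.
#' @export
point_in_roi <- function(touch, roi) {
  stopifnot(inherits(roi, "roi"))
  if (length(touch) != 2L || any(!is.finite(touch)))
    stop_invalid("touch must be a finite (x, y) pair")
  points_in_polygon(touch[1], touch[2], roi$vertices)
}

#' Scale an ROI about its centroid by an area factor
#'
#' Produces the similar polygon with `area_factor` times the area, scaled
#' about the polygon centroid — used to build the "global error" region
#' (three times the correct ROI's area) of the pointing-error taxonomy.
#'
#' @param roi An [roi()] object.
#' @param area_factor Positive area multiplier (default 3).
#' @export
scale_roi <- function(roi, area_factor = 3) {
  stopifnot(inherits(roi, "roi"))
  if (area_factor <= 0) stop_invalid("area_factor must be positive")
  ctr <- polygon_centroid(roi$vertices)
  s <- sqrt(area_factor)
  v <- sweep(sweep(roi$vertices, 2, ctr), 2, c(s, s), `*`)
  v <- sweep(v, 2, ctr, `+`)
  out <- roi
  out$vertices <- v
  out$area_px2 <- polygon_area(v)
  out
}

# ROI sets ------------------------------------------------------------------

roi_key <- function(image_id, target_id, kind)
  paste(image_id, target_id, kind, sep = "|")

#' Bundle ROIs into a lookup set
#'
#' @param rois List of [roi()] objects.
#' @return A named list of class `"roi_set"` keyed by image, target and kind.
#' @export
roi_set <- function(rois) {
  stopifnot(all(vapply(rois, inherits, logical(1), "roi")))
  names(rois) <- vapply(rois, function(r)
    roi_key(r$image_id, r$target_id, r$kind), character(1))
  structure(rois, class = "roi_set")
}

roi_get <- function(rois, image_id, target_id, kind = "correct") {
  rois[[roi_key(image_id, target_id, kind)]]
}

#' Auto-generate an ROI layout for a synthetic experiment
#'
#' Places, for every image, `targets_per_image` well-separated correct
#' target polygons on the display, and for a fraction of targets an
#' equal-area local-distractor polygon far from the correct location
#' (outside the 3x-area global region), mirroring stimulus sets in which
#' only some targets have a shape-matching decoy.
#'
#' @param image_ids Character vector of image identifiers.
#' @param targets_per_image Targets per image (default 2).
#' @param geometry A [display_geometry()].
#' @param seed Integer seed.
#' @param local_fraction Fraction of targets given a local-distractor ROI.
#' @param roi_radius_px Mean polygon radius in pixels.
#' @return An `roi_set`.
#' @export
make_synthetic_rois <- function(image_ids, targets_per_image = 2L,
                                geometry = display_geometry(), seed = 1L,
                                local_fraction = 0.3, roi_radius_px = 28) {
  h <- geometry$image_height_px
  margin <- 4 * roi_radius_px
  polygon_at <- function(cx, cy, r) {
    nv <- sample(5:7, 1L)
    # near-regular angular spacing keeps every wedge < pi, so the star
    # polygon is guaranteed simple
    th <- (seq_len(nv) - 1L) * 2 * pi / nv + runif(nv, -0.25, 0.25) * 2 * pi / nv
    rad <- r * runif(nv, 0.75, 1.25)
    cbind(cx + rad * cos(th), cy + rad * sin(th))
  }
  with_seed(seed, {
    out <- list()
    for (img in image_ids) {
      # rejection-sample well-separated centres (targets + potential locals)
      n_slots <- 2L * targets_per_image
      ctrs <- matrix(NA_real_, 0, 2)
      while (nrow(ctrs) < n_slots) {
        cand <- runif(2, margin, h - margin)
        if (nrow(ctrs) == 0L ||
            min(sqrt(rowSums(sweep(ctrs, 2, cand)^2))) > 6 * roi_radius_px)
          ctrs <- rbind(ctrs, cand)
      }
      for (t in seq_len(targets_per_image)) {
        out[[length(out) + 1L]] <-
          roi(img, t, polygon_at(ctrs[t, 1], ctrs[t, 2], roi_radius_px),
              kind = "correct")
        if (runif(1) < local_fraction) {
          lc <- ctrs[targets_per_image + t, ]
          # match the correct ROI's area exactly (decoys are equal in area)
          lp <- polygon_at(lc[1], lc[2], roi_radius_px)
          a0 <- out[[length(out)]]$area_px2
          s <- sqrt(a0 / polygon_area(lp))
          lp <- sweep(sweep(lp, 2, lc), 2, c(s, s), `*`)
          lp <- sweep(lp, 2, lc, `+`)
          out[[length(out) + 1L]] <- roi(img, t, lp, kind = "local_distractor")
        }
      }
    }
    roi_set(out)
  })
}

#' Write an ROI set to JSON
#'
#' Schema: one object per image with a `targets` array of
#' `{target_id, kind, vertices: [[x, y], ...]}` entries; coordinates are
#' 0-based display pixels, origin top-left, y downward.
#'
#' @param rois An `roi_set`.
#' @param path Output JSON path.
#' @export
write_rois <- function(rois, path) {
  ids <- unique(vapply(rois, `[[`, character(1), "image_id"))
  body <- lapply(ids, function(img) {
    tg <- Filter(function(r) r$image_id == img, rois)
    list(image_id = img,
         targets = lapply(unname(tg), function(r)
           list(target_id = r$target_id, kind = r$kind,
                vertices = unname(apply(r$vertices, 1, as.numeric,
                                        simplify = FALSE)))))
  })
  jsonlite::write_json(body, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an ROI set from JSON
#'
#' @param path JSON path in the [write_rois()] schema.
#' @return An `roi_set`.
#' @export
read_rois <- function(path) {
  body <- jsonlite::read_json(path)
  out <- list()
  for (img in body) {
    for (tg in img$targets) {
      v <- do.call(rbind, lapply(tg$vertices, function(p)
        c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
      out[[length(out) + 1L]] <-
        roi(img$image_id, tg$target_id, v, kind = tg$kind)
    }
  }
  roi_set(out)
}
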