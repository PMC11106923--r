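#' @title 2-D lines, ellipses and the biometric geometry pipeline
#' @description Geometric primitives used by the cardiac-axis and
#'   cardiothoracic-ratio measurements. All point sets are `n x 2` matrices of
#'   `(row, col)` coordinates (1-based, pixel centers at integers).
#' @name geometry
NULL

#' Construct a 2-D line (point + unit direction)
#'
#' @param point Numeric `(row, col)`.
#' @param direction Numeric `(d_row, d_col)`; normalized to unit length.
#' @return A `line2d` object.
#' @export
line2d <- function(point, direction) {
  point <- as.numeric(point)
  direction <- as.numeric(direction)
  stopifnot(length(point) == 2L, length(direction) == 2L)
  nrm <- sqrt(sum(direction^2))
  if (!is.finite(nrm) || nrm < 1e-12) stop("line direction must be non-zero")
  structure(list(point = point, direction = direction / nrm), class = "line2d")
}

#' @export
print.line2d <- function(x, ...) {
  cat(sprintf("<line2d> through (%.3f, %.3f), direction (%.4f, %.4f)\n",
              x$point[1], x$point[2], x$direction[1], x$direction[2]))
  invisible(x)
}

#' Construct an ellipse
#'
#' @param center Numeric `(row, col)`.
#' @param major,minor Full axis lengths in pixels; `major >= minor > 0`.
#' @param rotation_deg Orientation of the major axis in degrees, measured from
#'   the +col axis toward the +row axis, reduced to `[0, 180)`.
#' @return An `ellipse` object.
#' @export
ellipse <- function(center, major, minor, rotation_deg) {
  stopifnot(length(center) == 2L, is.finite(major), is.finite(minor))
  if (!(major >= minor && minor > 0)) {
    stop("ellipse axes must satisfy major >= minor > 0 (got ", major, ", ", minor, ")")
  }
  structure(list(center = as.numeric(center), major = as.numeric(major),
                 minor = as.numeric(minor),
                 rotation_deg = as.numeric(rotation_deg) %% 180),
            class = "ellipse")
}

#' @export
print.ellipse <- function(x, ...) {
  cat(sprintf("<ellipse> center (%.2f, %.2f), axes (%.2f, %.2f), rotation %.2f deg\n",
              x$center[1], x$center[2], x$major, x$minor, x$rotation_deg))
  invisible(x)
}

#' Area of an ellipse
#'
#' @param e An [ellipse()].
#' @return `pi * major/2 * minor/2`, in squared pixels.
#' @export
ellipse_area <- function(e) {
  stopifnot(inherits(e, "ellipse"))
  pi * (e$major / 2) * (e$minor / 2)
}

#' Sample points on an ellipse boundary
#'
#' @param e An [ellipse()].
#' @param n Number of points, uniformly spaced in parameter angle.
#' @return `n x 2` matrix of `(row, col)` coordinates.
#' @export
ellipse_points <- function(e, n = 360) {
  stopifnot(inherits(e, "ellipse"))
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  th <- e$rotation_deg * pi / 180
  a <- e$major / 2; b <- e$minor / 2
  # rotation from +col toward +row; x = col, y = row
  x <- a * cos(t) * cos(th) - b * sin(t) * sin(th)
  y <- a * cos(t) * sin(th) + b * sin(t) * cos(th)
  cbind(row = e$center[1] + y, col = e$center[2] + x)
}

shift_mat <- function(x, dr, dc) {
  h <- nrow(x); w <- ncol(x)
  out <- matrix(FALSE, h, w)
  r1 <- max(1L, 1L - dr); r2 <- min(h, h - dr)
  c1 <- max(1L, 1L - dc); c2 <- min(w, w - dc)
  if (r1 <= r2 && c1 <= c2) {
    out[r1:r2, c1:c2] <- x[(r1 + dr):(r2 + dr), (c1 + dc):(c2 + dc)]
  }
  out
}

#' Skeletonize a binary mask
#'
#' Topological thinning (Zhang-Suen) of the largest 8-connected component to a
#' one-pixel-wide medial line. Every skeleton point lies inside the input mask.
#'
#' @param mask Non-empty logical matrix.
#' @param prune Keep only the longest geodesic path between skeleton endpoints
#'   (default `FALSE`; the cardiac-axis pipeline prunes explicitly).
#' @return `n x 2` integer matrix of skeleton `(row, col)` coordinates.
#' @export
skeletonize <- function(mask, prune = FALSE) {
  if (!any(mask)) stop("cannot skeletonize an empty mask")
  m <- largest_component(mask, connectivity = 8)
  # crop to bounding box (with 1-px pad) for speed
  rc <- which(m, arr.ind = TRUE)
  r0 <- min(rc[, 1]); r1 <- max(rc[, 1]); c0 <- min(rc[, 2]); c1 <- max(rc[, 2])
  sub <- matrix(FALSE, r1 - r0 + 3L, c1 - c0 + 3L)
  sub[2:(r1 - r0 + 2L), 2:(c1 - c0 + 2L)] <- m[r0:r1, c0:c1]
  sub <- thin_zhang_suen(sub)
  pts <- which(sub, arr.ind = TRUE)
  pts <- cbind(row = pts[, 1] + r0 - 2L, col = pts[, 2] + c0 - 2L)
  if (prune) pts <- prune_skeleton(pts)
  pts
}

thin_zhang_suen <- function(m) {
  offs <- list(c(-1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L),
               c(1L, 0L), c(1L, -1L), c(0L, -1L), c(-1L, -1L))  # P2..P9
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      P <- lapply(offs, function(o) shift_mat(m, o[1], o[2]))
      B <- Reduce(`+`, P)
      seqP <- c(P, P[1])
      A <- Reduce(`+`, lapply(1:8, function(i) !seqP[[i]] & seqP[[i + 1]]))
      if (sub == 1L) {
        cond <- !(P[[1]] & P[[3]] & P[[5]]) & !(P[[3]] & P[[5]] & P[[7]])
      } else {
        cond <- !(P[[1]] & P[[3]] & P[[7]]) & !(P[[1]] & P[[5]] & P[[7]])
      }
      del <- m & B >= 2 & B <= 6 & A == 1 & cond
      if (any(del)) {
        m[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

#' Prune a skeleton to its longest geodesic path
#'
#' Treats the skeleton pixels as an 8-connected graph weighted by Euclidean
#' step length and keeps the vertices of the longest shortest path (the graph
#' diameter). On branched skeletons this removes side spurs so that the
#' subsequent line fit follows the main axis.
#'
#' @param points `n x 2` matrix of skeleton `(row, col)` coordinates.
#' @return Subset of `points` forming the longest path, ordered end to end.
#' @export
prune_skeleton <- function(points) {
  n <- nrow(points)
  if (n <= 2L) return(points)
  dr <- outer(points[, 1], points[, 1], `-`)
  dc <- outer(points[, 2], points[, 2], `-`)
  adj <- abs(dr) <= 1L & abs(dc) <= 1L
  diag(adj) <- FALSE
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  if (!nrow(idx)) return(points)
  w <- sqrt((points[idx[, 1], 1] - points[idx[, 2], 1])^2 +
            (points[idx[, 1], 2] - points[idx[, 2], 2])^2)
  g <- igraph::graph_from_edgelist(idx, directed = FALSE)
  g <- igraph::set_edge_attr(g, "weight", value = w)
  path <- igraph::get_diameter(g, weights = igraph::E(g)$weight)
  points[as.integer(path), , drop = FALSE]
}

#' Total-least-squares (orthogonal) line fit
#'
#' Fits the line minimizing the summed squared orthogonal distances: the line
#' through the centroid along the principal eigenvector of the coordinate
#' covariance. Unlike ordinary regression this is well defined for vertical
#' point clouds, which matters because the interventricular septum is often
#' near-parallel to the image columns.
#'
#' @param points `n x 2` matrix of `(row, col)` coordinates, at least two
#'   distinct points.
#' @return A [line2d()] through the centroid.
#' @export
fit_line_tls <- function(points) {
  points <- as.matrix(points)
  if (nrow(unique(points)) < 2L) stop("need at least 2 distinct points for a line fit")
  ctr <- colMeans(points)
  X <- sweep(points, 2, ctr)
  sv <- svd(X, nu = 0)
  if (sv$d[1] < 1e-12 || (sv$d[2] / sv$d[1]) > 1 - 1e-12) {
    stop("degenerate line fit: point cloud is isotropic (no principal direction)")
  }
  d <- sv$v[, 1]
  # canonical sign: positive row component, or positive col if horizontal
  if (d[1] < 0 || (d[1] == 0 && d[2] < 0)) d <- -d
  line2d(ctr, d)
}

#' Center of mass of a binary mask
#'
#' @param mask Non-empty logical matrix.
#' @return `(row, col)` arithmetic mean of foreground pixel coordinates.
#' @export
mass_center <- function(mask) {
  if (!any(mask)) stop("cannot take the mass center of an empty mask")
  rc <- which(mask, arr.ind = TRUE)
  c(row = mean(rc[, 1]), col = mean(rc[, 2]))
}

#' Thoracic anteroposterior axis from thorax and spine masks
#'
#' The AP axis is the line through the centers of mass of the thorax and spine
#' masks, oriented from the spine centroid toward the thorax centroid
#' (posterior to anterior). With anisotropic pixel spacing the centroids are
#' mapped to physical coordinates first, since angles are not preserved under
#' anisotropic scaling.
#'
#' @param thorax,spine Non-empty logical matrices (same shape).
#' @param spacing `(row_mm, col_mm)` pixel size; defaults to the masks'
#'   `spacing` attribute or 1 mm isotropic.
#' @return A [line2d()] in physical coordinates.
#' @export
thoracic_ap_axis <- function(thorax, spine, spacing = NULL) {
  if (is.null(spacing)) spacing <- mask_spacing(thorax)
  ct <- mass_center(thorax) * spacing
  cs <- mass_center(spine) * spacing
  d <- ct - cs
  if (sqrt(sum((d / spacing)^2)) < 1) {
    stop("thorax and spine centroids coincide; AP axis undefined")
  }
  line2d(cs, d)
}

#' Acute angle between two lines, in degrees
#'
#' Lines are unoriented, so the angle is folded to `[0, 90]`:
#' `acos(|a . b|)` for unit directions.
#'
#' @param a,b [line2d()] objects.
#' @return Angle in degrees in `[0, 90]`.
#' @export
angle_between <- function(a, b) {
  stopifnot(inherits(a, "line2d"), inherits(b, "line2d"))
  d <- abs(sum(a$direction * b$direction))
  acos(min(1, d)) * 180 / pi
}

#' Measure the fetal cardiac axis from a label map
#'
#' Implements the mask-based cardiac-axis measurement: the interventricular
#' septum mask is reduced to its largest component, thinned to a skeleton,
#' pruned to the longest geodesic path, and fit with a total-least-squares
#' line (the septal long axis). The thoracic anteroposterior axis is the line
#' through the thorax and spine mask centroids. The cardiac axis is the acute
#' angle between the two lines.
#'
#' The thorax mask is the Thorax Area label when present (area layer or main
#' grid); otherwise the union of all non-background structural labels is used
#' as a fallback.
#'
#' @param map A [label_map()] containing non-empty Interventricular Septum and
#'   Spine labels (and a thorax, per the fallback above).
#' @return A `cax_result`: `angle_deg` in `[0, 90]`, `signed_angle_deg`
#'   (positive when the apex points to the image left of the AP axis),
#'   `septal_line`, `ap_line` (physical coordinates), `n_skeleton_points`,
#'   `warnings`.
#' @export
measure_cax <- function(map) {
  stopifnot(inherits(map, "label_map"))
  warnings <- character()
  ivs <- extract_mask(map, "Interventricular Septum")
  if (!any(ivs)) stop("label 'Interventricular Septum' is empty; cannot measure CAx")
  spine <- extract_mask(map, "Spine")
  if (!any(spine)) stop("label 'Spine' is empty; cannot measure CAx")
  thorax <- thorax_mask(map)
  if (!any(thorax)) stop("label 'Thorax Area' is empty; cannot measure CAx")

  sp <- map$spacing
  if (abs(sp[1] - sp[2]) > 1e-9) {
    warnings <- c(warnings, sprintf("anisotropic spacing (%g, %g) mm; fits done in physical coordinates", sp[1], sp[2]))
  }
  skel <- skeletonize(ivs)
  skel <- prune_skeleton(skel)
  if (nrow(skel) < 10L) {
    warnings <- c(warnings, sprintf("septal skeleton has only %d points; angle may be unstable", nrow(skel)))
  }
  septal <- fit_line_tls(sweep(skel, 2, sp, `*`))
  ap <- thoracic_ap_axis(thorax, spine, spacing = sp)
  angle <- angle_between(septal, ap)

  # signed variant: orient the septal direction toward the anterior half-plane,
  # then take the rotation sign from the 2-D cross product AP x septal
  sd <- septal$direction
  if (sum(sd * ap$direction) < 0) sd <- -sd
  cross <- ap$direction[1] * sd[2] - ap$direction[2] * sd[1]
  signed <- atan2(cross, sum(sd * ap$direction)) * 180 / pi

  structure(list(angle_deg = angle, signed_angle_deg = signed,
                 septal_line = septal, ap_line = ap,
                 n_skeleton_points = nrow(skel), warnings = warnings),
            class = "cax_result")
}

thorax_mask <- function(map) {
  ta <- extract_mask(map, "Thorax Area")
  if (any(ta)) return(ta)
  structure(map$grid != 0L, spacing = map$spacing)
}

heart_mask <- function(map) {
  ha <- extract_mask(map, "Heart Area")
  if (any(ha)) return(ha)
  ids <- vapply(c("Left Atrium", "Left Ventricle", "Right Atrium", "Right Ventricle",
                  "Interventricular Septum", "Interatrial Septum",
                  "Left Ventricular Wall", "Right Ventricular Wall"),
                function(nm) scheme_id(map$scheme, nm), integer(1))
  structure(matrix(map$grid %in% ids, nrow(map$grid), ncol(map$grid)),
            spacing = map$spacing)
}

#' @export
print.cax_result <- function(x, ...) {
  cat(sprintf("<cax_result> CAx = %.2f deg (signed %.2f), %d skeleton points\n",
              x$angle_deg, x$signed_angle_deg, x$n_skeleton_points))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Ordered outer contour of a binary mask
#'
#' Traces the outer boundary of the largest 8-connected component. Every
#' contour point is a foreground pixel that touches background (or the image
#' edge) in its 4-neighborhood.
#'
#' @param mask Non-empty logical matrix.
#' @return Ordered `n x 2` integer matrix of `(row, col)` boundary coordinates.
#' @export
extract_contour <- function(mask) {
  if (!any(mask)) stop("cannot extract the contour of an empty mask")
  m <- largest_component(mask, connectivity = 8)
  oc <- EBImage::ocontour(matrix(as.integer(m), nrow(m), ncol(m)))[[1]]
  cbind(row = oc[, 1] + 1L, col = oc[, 2] + 1L)  # ocontour is 0-based
}

#' Direct least-squares ellipse fit
#'
#' Fits the conic `A x^2 + B xy + C y^2 + D x + E y + F = 0` to the points by
#' the numerically stable direct least-squares method with the elliptical
#' constraint `4AC - B^2 = 1`, after centering and scaling the points for
#' conditioning. On points lying exactly on an ellipse the five geometric
#' parameters are recovered to machine precision.
#'
#' @param points `n x 2` matrix of `(row, col)` coordinates, `n >= 5`,
#'   not collinear.
#' @return An [ellipse()].
#' @export
fit_ellipse <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 5L) stop("need at least 5 points to fit an ellipse, got ", nrow(points))
  x <- points[, 2]; y <- points[, 1]  # x = col, y = row
  mx <- mean(x); my <- mean(y)
  s <- sqrt(mean((x - mx)^2 + (y - my)^2))
  if (s < 1e-12) stop("degenerate ellipse fit: all points coincide")
  xs <- (x - mx) / s; ys <- (y - my) / s

  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  if (abs(det(S3)) < 1e-12 * nrow(points)^3) {
    stop("degenerate ellipse fit: points are collinear or otherwise rank-deficient")
  }
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  V <- Re(ev$vectors)
  cond <- 4 * V[1, ] * V[3, ] - V[2, ]^2
  ok <- which(cond > 0)
  if (!length(ok)) stop("fit degenerated to a non-elliptical conic")
  a1 <- V[, ok[1]]
  coef <- c(a1, as.vector(Tm %*% a1))  # A B C D E F in scaled frame

  # undo the normalization x -> (X - mx)/s, y -> (Y - my)/s
  A <- coef[1] / s^2
  B <- coef[2] / s^2
  C <- coef[3] / s^2
  D <- coef[4] / s - (2 * coef[1] * mx + coef[2] * my) / s^2
  E <- coef[5] / s - (coef[2] * mx + 2 * coef[3] * my) / s^2
  F <- (coef[1] * mx^2 + coef[2] * mx * my + coef[3] * my^2) / s^2 -
       (coef[4] * mx + coef[5] * my) / s + coef[6]

  conic_to_ellipse(c(A, B, C, D, E, F))
}

conic_to_ellipse <- function(k) {
  A <- k[1]; B <- k[2]; C <- k[3]; D <- k[4]; E <- k[5]; F <- k[6]
  disc <- B^2 - 4 * A * C
  if (disc >= 0) stop("fit degenerated to a non-elliptical conic (discriminant >= 0)")
  x0 <- (2 * C * D - B * E) / disc
  y0 <- (2 * A * E - B * D) / disc
  Mq <- matrix(c(A, B / 2, B / 2, C), 2)
  M0 <- matrix(c(F, D / 2, E / 2,
                 D / 2, A, B / 2,
                 E / 2, B / 2, C), 3, byrow = TRUE)
  lam <- eigen(Mq, symmetric = TRUE)
  ratio <- -det(M0) / (det(Mq) * lam$values)
  if (any(ratio <= 0)) stop("fit degenerated to a non-elliptical conic")
  semi <- sqrt(ratio)                    # per eigenvalue; smaller lambda -> larger axis
  i_major <- which.max(semi)
  vmaj <- lam$vectors[, i_major]         # (x, y) direction of the major axis
  rot <- atan2(vmaj[2], vmaj[1]) * 180 / pi
  ellipse(center = c(y0, x0), major = 2 * max(semi), minor = 2 * min(semi),
          rotation_deg = rot)
}

#' Measure the cardiothoracic ratio from a label map
#'
#' For each of the heart and thorax masks: keep the largest component, extract
#' the ordered outer contour, and fit an ellipse by direct least squares. The
#' cardiothoracic ratio is the ratio of the two fitted-ellipse areas
#' (heart / thorax).
#'
#' The Heart Area / Thorax Area labels are used when present; otherwise the
#' heart falls back to the union of the four chambers, the two septa and the
#' two ventricular walls, and the thorax to the union of all non-background
#' labels.
#'
#' @param map A [label_map()].
#' @return A `ctr_result`: `ratio`, `heart_ellipse`, `thorax_ellipse`.
#' @export
measure_ctr <- function(map) {
  stopifnot(inherits(map, "label_map"))
  hm <- heart_mask(map)
  if (!any(hm)) stop("label 'Heart Area' is empty (and no chamber fallback); cannot measure CTR")
  tm <- thorax_mask(map)
  if (!any(tm)) stop("label 'Thorax Area' is empty; cannot measure CTR")
  eh <- fit_ellipse(extract_contour(hm))
  et <- fit_ellipse(extract_contour(tm))
  structure(list(ratio = ellipse_area(eh) / ellipse_area(et),
                 heart_ellipse = eh, thorax_ellipse = et),
            class = "ctr_result")
}

#' @export
print.ctr_result <- function(x, ...) {
  cat(sprintf("<ctr_result> CTR = %.4f (heart %.1f x %.1f px, thorax %.1f x %.1f px)\n",
              x$ratio, x$heart_ellipse$major, x$heart_ellipse$minor,
              x$thorax_ellipse$major, x$thorax_ellipse$minor))
  invisible(x)
}
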