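#' Specification of a synthetic fetal-thorax phantom
#'
#' The phantom emulates the anatomy visible in a four-chamber-view annotation:
#' an elliptical thorax with a posterior spine disc on the midline, an
#' elliptical heart whose major axis makes a known angle (the true cardiac
#' axis) with the anteroposterior axis, a septal band along the heart's major
#' axis, four chamber quadrants, thin ventricular walls, lungs filling the
#' remaining thoracic space, a descending aorta and rib arcs. Anterior is
#' "up" (decreasing row); the spine sits at the posterior pole, so the
#' anteroposterior axis is the image-vertical midline of the thorax.
#'
#' The true cardiothoracic ratio follows from the axis lengths:
#' `true_ctr = (heart_major * heart_minor) / (thorax_major * thorax_minor)`.
#' When `heart_axes` is `NULL` they are derived from `true_ctr` and
#' `heart_aspect`.
#'
#' @param image_size `(H, W)` in pixels (default 512 x 512).
#' @param thorax_axes Full `(major, minor)` thorax axis lengths in pixels;
#'   major runs left-right (columns), minor anteroposterior (rows).
#' @param heart_axes Full `(major, minor)` heart axis lengths, or `NULL` to
#'   derive them from `true_ctr`.
#' @param true_cax_deg True cardiac axis in degrees, in `[0, 90]`.
#' @param true_ctr Target cardiothoracic ratio (used when `heart_axes` is `NULL`).
#' @param heart_aspect Heart major/minor aspect ratio used when deriving axes.
#' @param heart_center_offset `(row, col)` offset of the heart center from the
#'   thorax center, pixels; the default shifts the heart slightly anterior so
#'   it clears the spine at large cardiothoracic ratios.
#' @param septum_thickness Full thickness of the septal band, pixels; defaults
#'   to ~1.8% of the image side (9 px at 512).
#' @param spine_radius Radius of the spine disc, pixels; defaults to ~2.3% of
#'   the image side (12 px at 512).
#' @param rib_arcs Number of rib arcs on the thorax boundary (>= 0).
#' @param boundary_jitter_px SD of the seeded radial boundary noise applied to
#'   the thorax and heart outlines (0 = exact ellipses).
#' @param seed Integer seed making generation deterministic.
#' @param spacing Pixel spacing `(row_mm, col_mm)`.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(image_size = c(512, 512),
                         thorax_axes = NULL,
                         heart_axes = NULL,
                         true_cax_deg = 30,
                         true_ctr = 0.30,
                         heart_aspect = 1.35,
                         heart_center_offset = c(-6, 0),
                         septum_thickness = NULL,
                         spine_radius = NULL,
                         rib_arcs = 4,
                         boundary_jitter_px = 0,
                         seed = 1L,
                         spacing = c(1, 1)) {
  image_size <- rep_len(as.integer(image_size), 2L)
  if (is.null(thorax_axes)) {
    # thorax spans ~72% / 62% of the field of view, as in a well-framed view
    thorax_axes <- c(round(0.72 * image_size[2]), round(0.62 * image_size[1]))
  }
  # structure sizes scale with the field of view unless given explicitly
  if (is.null(spine_radius)) spine_radius <- max(3, round(0.023 * min(image_size)))
  if (is.null(septum_thickness)) septum_thickness <- max(5, round(0.018 * min(image_size)))
  if (is.null(heart_axes)) {
    prod_h <- true_ctr * thorax_axes[1] * thorax_axes[2]
    heart_axes <- c(sqrt(prod_h * heart_aspect), sqrt(prod_h / heart_aspect))
  }
  if (heart_axes[1] < heart_axes[2]) stop("heart major axis must be >= minor axis")
  if (septum_thickness >= heart_axes[2]) {
    stop("septum thickness (", septum_thickness, ") must be smaller than the heart minor axis")
  }
  if (true_cax_deg < 0 || true_cax_deg > 90) stop("true_cax_deg must be in [0, 90]")
  spec <- structure(list(
    image_size = image_size, thorax_axes = as.numeric(thorax_axes),
    heart_axes = as.numeric(heart_axes), true_cax_deg = as.numeric(true_cax_deg),
    heart_center_offset = as.numeric(rep_len(heart_center_offset, 2L)),
    septum_thickness = as.numeric(septum_thickness),
    spine_radius = as.numeric(spine_radius), rib_arcs = as.integer(rib_arcs),
    boundary_jitter_px = as.numeric(boundary_jitter_px), seed = as.integer(seed),
    spacing = as.numeric(rep_len(spacing, 2L))), class = "phantom_spec")
  spec$true_ctr <- (spec$heart_axes[1] * spec$heart_axes[2]) /
    (spec$thorax_axes[1] * spec$thorax_axes[2])
  if (spec$true_ctr <= 0 || spec$true_ctr >= 1) stop("true CTR must lie in (0, 1)")
  spec
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %dx%d, true CAx %.1f deg, true CTR %.3f, jitter %.1f px, seed %d\n",
              x$image_size[1], x$image_size[2], x$true_cax_deg, x$true_ctr,
              x$boundary_jitter_px, x$seed))
  invisible(x)
}

# Evaluate expr with a local, restored RNG state seeded by `seed`.
with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Smooth periodic radial-noise function of the polar angle, in pixels.
radial_noise_fn <- function(sd, n_knots = 48L) {
  if (sd <= 0) return(function(phi) rep(0, length(phi)))
  knots <- seq(-pi, pi, length.out = n_knots + 1L)
  vals <- stats::rnorm(n_knots, sd = sd)
  vals <- c(vals, vals[1L])
  function(phi) stats::approx(knots, vals, xout = phi, rule = 2)$y
}

#' Generate a synthetic fetal-thorax label map with known ground truth
#'
#' Deterministic given the spec's seed. The structural labels go in the main
#' grid; the overlapping Heart Area / Thorax Area annotations go in the area
#' layer (heart id over the overlap, see [extract_mask()]). All regions are
#' pairwise disjoint within each layer and lie inside the thorax ellipse.
#'
#' @param spec A [phantom_spec()].
#' @param scheme A [label_scheme()].
#' @return A `phantom` object: `label_map` ([label_map()] with area layer),
#'   `true_cax_deg`, `true_ctr`, `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec(), scheme = label_scheme()) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_local_seed(spec$seed, generate_phantom_impl(spec, scheme))
}

generate_phantom_impl <- function(spec, scheme) {
  H <- spec$image_size[1]; W <- spec$image_size[2]
  r0 <- (H + 1) / 2; c0 <- (W + 1) / 2
  ta <- spec$thorax_axes[1] / 2   # col semi-axis
  tb <- spec$thorax_axes[2] / 2   # row semi-axis
  hA <- spec$heart_axes[1] / 2; hB <- spec$heart_axes[2] / 2
  th <- spec$true_cax_deg * pi / 180
  hc <- c(r0, c0) + spec$heart_center_offset
  # heart major-axis direction: anterior with apex toward the image left
  u <- c(-cos(th), -sin(th))
  v <- c(-u[2], u[1])             # heart's left-hand side

  rr <- matrix(seq_len(H), H, W) - 0
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  dr <- rr - r0; dc <- cc - c0

  noise_t <- radial_noise_fn(spec$boundary_jitter_px)
  noise_h <- radial_noise_fn(spec$boundary_jitter_px)

  # thorax: radial inside-test so jitter keeps the region star-convex
  Rt <- sqrt(dr^2 + dc^2)
  phit <- atan2(dc, dr)
  Rt_b <- 1 / sqrt((cos(phit) / tb)^2 + (sin(phit) / ta)^2)
  in_thorax <- Rt <= Rt_b + noise_t(phit)
  rho_t <- Rt / Rt_b              # normalized thorax radius (jitter-free)

  # heart frame coordinates
  pr <- rr - hc[1]; pc <- cc - hc[2]
  s <- pr * u[1] + pc * u[2]
  t <- pr * v[1] + pc * v[2]
  Rh <- sqrt(s^2 + t^2)
  phih <- atan2(t, s)
  Rh_b <- 1 / sqrt((cos(phih) / hA)^2 + (sin(phih) / hB)^2)
  in_heart <- Rh <= Rh_b + noise_h(phih)
  if (any(in_heart & !in_thorax)) stop("infeasible phantom geometry: heart extends outside the thorax")

  # spine disc at the posterior pole, on the midline
  sr <- spec$spine_radius
  sc_ctr <- c(r0 + tb - sr - 2, c0)
  spine <- (rr - sc_ctr[1])^2 + (cc - sc_ctr[2])^2 <= sr^2
  if (any(spine & in_heart)) stop("infeasible phantom geometry: heart overlaps the spine")

  # descending aorta: small disc anterior-left of the spine
  ar <- max(3, 0.5 * sr)
  ao_ctr <- c(sc_ctr[1] - sr - ar - 4, c0 - sr - ar - 2)
  aorta <- (rr - ao_ctr[1])^2 + (cc - ao_ctr[2])^2 <= ar^2

  id <- function(nm) scheme_id(scheme, nm)
  grid <- matrix(0L, H, W)
  paint <- function(mask, nm) {
    sel <- mask & in_thorax & grid == 0L
    grid[sel] <<- id(nm)
  }

  # heart interior partition along the major axis: atria take the posterior
  # 40%, ventricles the anterior 60%
  s_av <- -0.2 * hA
  band <- abs(t) <= spec$septum_thickness / 2
  ring <- in_heart & (s / hA)^2 + (t / hB)^2 > 0.80

  paint(in_heart & band & s > s_av, "Interventricular Septum")
  paint(in_heart & band & s <= s_av, "Interatrial Septum")
  paint(ring & s > s_av & t >= 0, "Left Ventricular Wall")
  paint(ring & s > s_av & t < 0, "Right Ventricular Wall")
  paint(in_heart & s > s_av & t > 0, "Left Ventricle")
  paint(in_heart & s > s_av & t <= 0, "Right Ventricle")
  paint(in_heart & s <= s_av & t > 0, "Left Atrium")
  paint(in_heart & s <= s_av & t <= 0, "Right Atrium")
  paint(spine, "Spine")
  paint(aorta & !in_heart, "Descending Aorta")

  # rib arcs on the thorax boundary ring, alternating left/right
  if (spec$rib_arcs > 0L) {
    rib_ring <- in_thorax & rho_t > 0.955 & !spine
    ang <- atan2(dc, -dr)  # 0 = anterior, +/- pi = posterior
    base <- c(40, 75, 110, 135, 25, 60, 95, 125) * pi / 180
    for (k in seq_len(spec$rib_arcs)) {
      side <- if (k %% 2L == 1L) 1 else -1
      a0 <- base[((k - 1L) %% length(base)) + 1L]
      arc <- rib_ring & side * ang >= a0 - 0.12 & side * ang <= a0 + 0.12
      paint(arc, "RIB")
    }
  }

  # lungs fill the remaining thoracic space with margins, split at the midline
  hm <- 4
  heart_margin <- (s / (hA + hm))^2 + (t / (hB + hm))^2 <= 1
  lung_space <- in_thorax & rho_t <= 0.93 & !heart_margin
  paint(lung_space & cc > c0, "Left Lung")
  paint(lung_space & cc <= c0, "Right Lung")

  area <- matrix(0L, H, W)
  area[in_thorax] <- id("Thorax Area")
  area[in_heart] <- id("Heart Area")

  lm <- label_map(grid, spacing = spec$spacing, scheme = scheme, area = area)
  structure(list(label_map = lm, true_cax_deg = spec$true_cax_deg,
                 true_ctr = spec$true_ctr, spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> true CAx %.1f deg, true CTR %.3f\n", x$true_cax_deg, x$true_ctr))
  print(x$label_map)
  invisible(x)
}

#' Degrade a label map into an imperfect "prediction"
#'
#' Creates controlled imperfect segmentations for testing the evaluation
#' metrics: each label is morphologically eroded (or dilated into background)
#' by a disc of the given radius, optionally a seeded fraction of each label's
#' pixels is dropped, and whole labels can be removed. Erosion by a growing
#' radius degrades Dice monotonically.
#'
#' @param map A [label_map()].
#' @param morph_px Disc radius in pixels (0 = no morphology).
#' @param mode `"erode"` (default) or `"dilate"`; dilation only claims
#'   background pixels, so the grid stays single-valued.
#' @param dropout_labels Character vector of label names to remove entirely.
#' @param noise_frac Fraction of each label's pixels to drop at random.
#' @param seed Seed for the random dropout.
#' @return A degraded [label_map()].
#' @export
degrade_prediction <- function(map, morph_px = 1L, mode = c("erode", "dilate"),
                               dropout_labels = character(), noise_frac = 0,
                               seed = 1L) {
  stopifnot(inherits(map, "label_map"))
  mode <- match.arg(mode)
  if (morph_px < 0) stop("morph_px must be >= 0")
  drop_ids <- vapply(dropout_labels, function(nm) scheme_id(map$scheme, nm), integer(1))
  with_local_seed(seed, {
    grid <- degrade_grid(map$grid, morph_px, mode, drop_ids, noise_frac)
    area <- if (is.null(map$area)) NULL else {
      degrade_grid(map$area, morph_px, mode, drop_ids, noise_frac)
    }
    label_map(grid, spacing = map$spacing, scheme = map$scheme, area = area)
  })
}

degrade_grid <- function(grid, morph_px, mode, drop_ids, noise_frac) {
  for (dd in drop_ids) grid[grid == dd] <- 0L
  ids <- setdiff(sort(unique(as.vector(grid))), 0L)
  if (morph_px > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(morph_px) + 1L, shape = "disc")
    for (lid in ids) {
      mask <- grid == lid
      morphed <- EBImage::erode(matrix(as.numeric(mask), nrow(grid), ncol(grid)), brush) > 0.5
      if (mode == "erode") {
        grid[mask & !morphed] <- 0L
      } else {
        dil <- EBImage::dilate(matrix(as.numeric(mask), nrow(grid), ncol(grid)), brush) > 0.5
        grid[dil & grid == 0L] <- lid
      }
    }
  }
  if (noise_frac > 0) {
    for (lid in ids) {
      idx <- which(grid == lid)
      ndrop <- floor(noise_frac * length(idx))
      if (ndrop > 0) grid[sample(idx, ndrop)] <- 0L
    }
  }
  grid
}
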