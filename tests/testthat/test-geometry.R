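test_that("skeletonize reduces masks to an interior medial line", {
  one <- matrix(FALSE, 9, 9); one[5, 5] <- TRUE
  expect_equal(dim(skeletonize(one)), c(1L, 2L))
  expect_identical(as.integer(skeletonize(one)), c(5L, 5L))

  bar <- matrix(FALSE, 9, 60); bar[4:6, 5:54] <- TRUE
  sk <- skeletonize(bar)
  expect_true(all(sk[, 1] == 5))                 # confined to the middle row
  expect_true(min(sk[, 2]) > 5 && max(sk[, 2]) < 54)
  expect_true(all(bar[sk]))                      # inside the input mask

  expect_error(skeletonize(matrix(FALSE, 8, 8)), "empty")
})

test_that("skeleton of a tilted rectangle follows its principal axis", {
  # rasterize a 90x14 rectangle at 30 degrees
  h <- 128; w <- 128
  rr <- matrix(seq_len(h), h, w); cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  th <- 30 * pi / 180
  u <- c(-cos(th), sin(th)); v <- c(sin(th), cos(th))
  s <- (rr - 64) * u[1] + (cc - 64) * u[2]
  t <- (rr - 64) * v[1] + (cc - 64) * v[2]
  rect <- abs(s) <= 45 & abs(t) <= 7

  # oracle: principal axis of the full rectangle pixel cloud
  pts <- which(rect, arr.ind = TRUE)
  sv <- svd(scale(pts, scale = FALSE))
  oracle_dir <- sv$v[, 1]

  fit <- fit_line_tls(prune_skeleton(skeletonize(rect)))
  ang <- acos(min(1, abs(sum(fit$direction * oracle_dir)))) * 180 / pi
  expect_lt(ang, 2)
})

test_that("total-least-squares line fit handles diagonal, vertical and noisy data", {
  d <- fit_line_tls(rbind(c(0, 0), c(1, 1), c(2, 2)))
  expect_equal(d$point, c(1, 1))
  expect_equal(abs(sum(d$direction * c(1, 1) / sqrt(2))), 1, tolerance = 1e-12)

  vert <- fit_line_tls(rbind(c(0, 5), c(1, 5), c(2, 5)))
  expect_equal(vert$direction, c(1, 0))

  withr::with_seed(42, {
    t <- seq(-10, 10, length.out = 200)
    true_dir <- c(sin(0.4), cos(0.4))
    pts <- cbind(3 + t * true_dir[1] + rnorm(200, sd = 0.5),
                 7 + t * true_dir[2] + rnorm(200, sd = 0.5))
  })
  fit <- fit_line_tls(pts)
  ang <- acos(min(1, abs(sum(fit$direction * true_dir)))) * 180 / pi
  expect_lt(ang, 1)

  expect_error(fit_line_tls(rbind(c(1, 1), c(1, 1))), "distinct")
  square <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  expect_error(fit_line_tls(square), "degenerate|isotropic")
})

test_that("TLS minimizes orthogonal residuals against random candidate lines", {
  withr::with_seed(7, {
    pts <- cbind(rnorm(60, sd = 3), rnorm(60, sd = 1))
    fit <- fit_line_tls(pts)
    ctr <- colMeans(pts)
    X <- sweep(pts, 2, ctr)
    ssq <- function(d) sum((X %*% c(-d[2], d[1]))^2)  # orthogonal distances
    best <- ssq(fit$direction)
    angles <- runif(1000, 0, pi)
    for (a in angles) expect_lte(best, ssq(c(cos(a), sin(a))) + 1e-9)
  })
})

test_that("mass_center equals the analytic / brute-force centroid", {
  disc <- matrix(FALSE, 11, 11)
  rr <- matrix(seq_len(11), 11, 11); cc <- t(rr)
  disc[(rr - 6)^2 + (cc - 6)^2 <= 16] <- TRUE
  expect_equal(unname(mass_center(disc)), c(6, 6))

  rect <- matrix(FALSE, 10, 10); rect[3:6, 1:10] <- TRUE
  expect_equal(unname(mass_center(rect)), c(4.5, 5.5))

  m <- random_mask(25, 30, seed = 9)
  idx <- which(m, arr.ind = TRUE)
  expect_equal(unname(mass_center(m)),
               c(sum(idx[, 1]) / nrow(idx), sum(idx[, 2]) / nrow(idx)),
               tolerance = 1e-12)

  expect_error(mass_center(matrix(FALSE, 5, 5)), "empty")
})

test_that("the thoracic AP axis runs from the spine toward the thorax centroid", {
  th <- matrix(FALSE, 80, 60); th[25:35, 25:35] <- TRUE   # centroid (30, 30)
  sp <- matrix(FALSE, 80, 60); sp[48:52, 28:32] <- TRUE   # centroid (50, 30)
  ax <- thoracic_ap_axis(th, sp)
  expect_equal(ax$direction, c(-1, 0))

  flipped <- thoracic_ap_axis(sp, th)
  expect_equal(flipped$direction, c(1, 0))
  expect_equal(angle_between(ax, flipped), 0)

  expect_error(thoracic_ap_axis(th, th), "coincide")
})

test_that("angle_between returns the acute angle in [0, 90]", {
  a <- line2d(c(0, 0), c(1, 0))
  expect_equal(angle_between(a, a), 0)
  expect_equal(angle_between(a, line2d(c(0, 0), c(0, 1))), 90)

  deg <- function(x) line2d(c(0, 0), c(sin(x * pi / 180), cos(x * pi / 180)))
  expect_equal(angle_between(deg(30), deg(170)), 40, tolerance = 1e-9)
  expect_equal(angle_between(deg(30), deg(170)), angle_between(deg(170), deg(30)))
})

test_that("ellipse fitting recovers exact parameters and rejects degeneracies", {
  e0 <- ellipse(center = c(60, 80), major = 90, minor = 40, rotation_deg = 25)
  fit <- fit_ellipse(ellipse_points(e0, 360))
  expect_equal(fit$center, e0$center, tolerance = 1e-6)
  expect_equal(fit$major, e0$major, tolerance = 1e-6)
  expect_equal(fit$minor, e0$minor, tolerance = 1e-6)
  expect_equal(fit$rotation_deg, e0$rotation_deg, tolerance = 1e-6)

  circ <- fit_ellipse(ellipse_points(ellipse(c(0, 0), 20, 20, 0), 120))
  expect_equal(circ$major, 20, tolerance = 1e-6)
  expect_equal(circ$minor, 20, tolerance = 1e-6)

  expect_error(fit_ellipse(cbind(1:4, c(2, 3, 5, 7))), "5 points")
  expect_error(fit_ellipse(cbind(1:20, 2 * (1:20) + 1)), "degenerate|collinear")
})

test_that("ellipse_area is analytic and matches rasterized pixel counts", {
  expect_equal(ellipse_area(ellipse(c(0, 0), 20, 10, 0)), 50 * pi)
  expect_equal(ellipse_area(ellipse(c(0, 0), 10, 10, 0)), 25 * pi)

  e <- ellipse(c(100, 100), 120, 64, 40)
  rr <- matrix(seq_len(200), 200, 200); cc <- t(rr)
  th <- e$rotation_deg * pi / 180
  x <- cc - 100; y <- rr - 100
  xr <- x * cos(th) + y * sin(th); yr <- -x * sin(th) + y * cos(th)
  inside <- (xr / (e$major / 2))^2 + (yr / (e$minor / 2))^2 <= 1
  expect_equal(sum(inside) / ellipse_area(e), 1, tolerance = 0.02)
})

test_that("measure_cax recovers aligned and oblique phantom axes", {
  aligned <- small_phantom(cax = 0, seed = 21)
  expect_lte(measure_cax(aligned$label_map)$angle_deg, 1)

  ph <- generate_phantom(phantom_spec(true_cax_deg = 45, seed = 22))
  res <- measure_cax(ph$label_map)
  expect_equal(res$angle_deg, 45, tolerance = 2)
  expect_gte(res$n_skeleton_points, 10)
  expect_s3_class(res$septal_line, "line2d")

  nospine <- ph$label_map
  nospine$grid[nospine$grid == nospine$scheme[["Spine"]]] <- 0L
  expect_error(measure_cax(nospine), "Spine")
})

test_that("the signed cardiac axis flips with the septal tilt side but the acute angle does not", {
  ph <- small_phantom(cax = 35, seed = 23)
  res <- measure_cax(ph$label_map)
  expect_equal(res$signed_angle_deg, 35, tolerance = 2)
  mirrored <- ph$label_map
  mirrored$grid <- mirrored$grid[, ncol(mirrored$grid):1]
  mirrored$area <- mirrored$area[, ncol(mirrored$area):1]
  mres <- measure_cax(mirrored)
  expect_equal(mres$angle_deg, res$angle_deg, tolerance = 0.5)
  expect_equal(mres$signed_angle_deg, -res$signed_angle_deg, tolerance = 0.5)
})

test_that("measure_ctr matches the analytic area ratio", {
  # heart mask identical to thorax mask -> ratio 1
  sch <- label_scheme()
  rr <- matrix(seq_len(64), 64, 64); cc <- t(rr)
  disc <- (rr - 32)^2 + (cc - 32)^2 <= 20^2
  area <- matrix(0L, 64, 64)
  area[disc] <- sch[["Heart Area"]]  # heart covers the whole "thorax"
  m <- label_map(matrix(0L, 64, 64), area = area)
  expect_equal(measure_ctr(m)$ratio, 1, tolerance = 1e-6)

  ph <- generate_phantom(phantom_spec(image_size = c(256, 256),
                                      thorax_axes = c(160, 120),
                                      heart_axes = c(60, 40),
                                      true_cax_deg = 30, spine_radius = 8,
                                      septum_thickness = 5, seed = 24))
  res <- measure_ctr(ph$label_map)
  expect_lt(abs(res$ratio / ((60 * 40) / (160 * 120)) - 1), 0.03)
})
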