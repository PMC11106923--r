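#' Construct a label map
#'
#' A label map is the universal input of the measurement pipeline: an `H x W`
#' integer grid whose values are 0 (background) or ids of a [label_scheme()].
#' Because the heart-area and thorax-area annotations overlap the structural
#' labels anatomically but a grid is single-valued, a label map may carry an
#' optional second aligned layer (`area`) holding only the Heart Area /
#' Thorax Area ids; [extract_mask()] consults it transparently.
#'
#' Coordinates are 1-based `(row, col)` with pixel centers at integer
#' coordinates; row 1 is the top (anterior, by the phantom's convention).
#'
#' @param grid Integer matrix of label ids (structural layer).
#' @param spacing Physical pixel size `(row_mm, col_mm)`; default 1 mm isotropic.
#' @param scheme A [label_scheme()]; defaults to the standard 15-label scheme.
#' @param area Optional aligned integer matrix holding the Heart Area /
#'   Thorax Area layer (all other values must be 0).
#' @return A `label_map` object.
#' @export
label_map <- function(grid, spacing = c(1, 1), scheme = label_scheme(), area = NULL) {
  if (!is.matrix(grid)) stop("grid must be a matrix")
  storage.mode(grid) <- "integer"
  if (nrow(grid) < 8L || ncol(grid) < 8L) {
    stop("label map must be at least 8x8, got ", nrow(grid), "x", ncol(grid))
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 2L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be two positive numbers (row_mm, col_mm)")
  }
  scheme <- validate_scheme(scheme)
  check_grid_values(grid, scheme)
  if (!is.null(area)) {
    storage.mode(area) <- "integer"
    if (!identical(dim(area), dim(grid))) stop("area layer must match grid shape")
    check_grid_values(area, scheme)
  }
  structure(list(grid = grid, spacing = spacing, scheme = scheme, area = area),
            class = "label_map")
}

check_grid_values <- function(grid, scheme) {
  vals <- sort(unique(as.vector(grid)))
  bad <- setdiff(vals, c(0L, as.integer(scheme)))
  if (length(bad)) {
    stop("grid contains values outside the label scheme: ",
         paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> %d x %d, spacing (%g, %g) mm%s\n",
              nrow(x$grid), ncol(x$grid), x$spacing[1], x$spacing[2],
              if (is.null(x$area)) "" else ", with area layer"))
  present <- names(x$scheme)[x$scheme %in% unique(as.vector(x$grid))]
  if (!is.null(x$area)) {
    present <- union(present, names(x$scheme)[x$scheme %in% unique(as.vector(x$area))])
  }
  cat("  labels present:", if (length(present)) paste(present, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Read a label map from an indexed PNG or a NIfTI file
#'
#' PNG files must be single-channel (grayscale) 8- or 16-bit; pixel values are
#' interpreted directly as label ids. NIfTI images must be 2-D or 3-D with a
#' singleton third dimension; pixel spacing is taken from the header
#' (`pixdim`), or for PNG from the pHYs resolution chunk when present.
#'
#' If a sibling file with an `_area` suffix exists (e.g. `case_area.png` next
#' to `case.png`), it is read as the aligned Heart Area / Thorax Area layer.
#'
#' @param path Path to a `.png`, `.nii` or `.nii.gz` file.
#' @param scheme A [label_scheme()].
#' @param read_area Look for and attach the `_area` sibling layer (default TRUE).
#' @return A [label_map()].
#' @export
read_label_map <- function(path, scheme = label_scheme(), read_area = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  parsed <- read_label_grid(path)
  area <- NULL
  ap <- area_sibling_path(path)
  if (read_area && !is.na(ap) && file.exists(ap)) {
    area <- read_label_grid(ap)$grid
  }
  label_map(parsed$grid, spacing = parsed$spacing, scheme = scheme, area = area)
}

read_label_grid <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path, info = TRUE)
    info <- attr(img, "info")
    if (length(dim(img)) != 2L) {
      stop("label PNG must be single-channel, got ", dim(img)[3], " channels: ", path)
    }
    depth <- info$bit.depth
    grid <- matrix(as.integer(round(img * (2^depth - 1))), nrow(img), ncol(img))
    spacing <- c(1, 1)
    if (!is.null(info$dpi) && all(is.finite(info$dpi)) && all(info$dpi > 0)) {
      dpi <- rep_len(info$dpi, 2L)
      spacing <- 25.4 / c(dpi[2L], dpi[1L])  # dpi stored (col, row)
    }
    list(grid = grid, spacing = spacing)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) == 3L && d[3L] == 1L) {
      img <- img[, , 1L]
      d <- dim(img)
    }
    if (length(d) != 2L) {
      stop("NIfTI label map must be 2-D (or have a singleton third dimension): ", path)
    }
    pd <- RNifti::pixdim(img)
    spacing <- if (length(pd) >= 2L && all(pd[1:2] > 0)) as.numeric(pd[1:2]) else c(1, 1)
    list(grid = matrix(as.integer(round(img)), d[1L], d[2L]), spacing = spacing)
  } else {
    stop("unsupported label-map format (need .png, .nii or .nii.gz): ", path)
  }
}

area_sibling_path <- function(path) {
  m <- regmatches(path, regexec("^(.*?)(\\.png|\\.nii\\.gz|\\.nii)$", path, ignore.case = TRUE))[[1]]
  if (!length(m)) return(NA_character_)
  paste0(m[2], "_area", m[3])
}

#' Write a label map to an indexed PNG or a NIfTI file
#'
#' The written file round-trips losslessly through [read_label_map()] on both
#' grid values and spacing (PNG spacing is carried in the pHYs chunk; NIfTI in
#' `pixdim`). When the map has an area layer, a sibling `*_area.*` file is
#' written next to `path`.
#'
#' @param map A [label_map()].
#' @param path Output path ending in `.png`, `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(map, path) {
  stopifnot(inherits(map, "label_map"))
  if (!dir.exists(dirname(path))) stop("parent directory does not exist: ", dirname(path))
  write_label_grid(map$grid, map$spacing, path)
  if (!is.null(map$area)) {
    write_label_grid(map$area, map$spacing, area_sibling_path(path))
  }
  invisible(path)
}

write_label_grid <- function(grid, spacing, path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    maxv <- max(grid)
    depth <- if (maxv > 255L) 16L else 8L
    if (maxv > 65535L) stop("label ids exceed 16-bit PNG range")
    dpi <- 25.4 / c(spacing[2L], spacing[1L])  # (col, row) order
    png::writePNG(grid / (2^depth - 1), path, dpi = dpi)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::asNifti(grid)
    RNifti::pixdim(img) <- spacing
    RNifti::writeNifti(img, path, datatype = "int16")
  } else {
    stop("unsupported label-map format (need .png, .nii or .nii.gz): ", path)
  }
  invisible(path)
}

#' Extract the binary mask of one label
#'
#' Returns a logical matrix that is `TRUE` exactly where the grid equals the
#' label's id. The Heart Area / Thorax Area labels are taken from the map's
#' area layer when one is attached; the thorax-area mask then also includes
#' heart-area pixels (the heart lies inside the thorax, and the single-valued
#' layer stores the heart id on the overlap).
#'
#' @param map A [label_map()].
#' @param label_name Label name from the scheme (case-insensitive).
#' @return Logical matrix with a `spacing` attribute.
#' @export
extract_mask <- function(map, label_name) {
  stopifnot(inherits(map, "label_map"))
  id <- scheme_id(map$scheme, label_name)
  is_area <- tolower(label_name) %in% c("heart area", "thorax area")
  if (is_area && !is.null(map$area)) {
    if (tolower(label_name) == "thorax area") {
      ha <- scheme_id(map$scheme, "Heart Area")
      mask <- map$area == id | map$area == ha
    } else {
      mask <- map$area == id
    }
  } else {
    mask <- map$grid == id
  }
  structure(mask, spacing = map$spacing)
}

mask_spacing <- function(mask) {
  sp <- attr(mask, "spacing")
  if (is.null(sp)) c(1, 1) else sp
}

#' Label connected components of a binary mask
#'
#' 4-connectivity labelling is delegated to `EBImage::bwlabel`; 8-connectivity
#' additionally merges components that touch diagonally.
#'
#' @param mask Logical matrix.
#' @param connectivity 4 or 8.
#' @return Integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 8) {
  connectivity <- match.arg(as.character(connectivity), c("4", "8"))
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  if (connectivity == "4" || max(lab) <= 1L) return(lab)
  # merge 4-connected components that touch along a diagonal
  h <- nrow(lab); w <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-h, -w]), as.vector(lab[-1, -1])),  # down-right
    cbind(as.vector(lab[-h, -1]), as.vector(lab[-1, -w]))   # down-left
  )
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L & pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs)) {
    g <- igraph::graph_from_edgelist(matrix(as.character(pairs), ncol = 2), directed = FALSE)
    g <- igraph::simplify(g)
    memb <- igraph::components(g)$membership
    remap <- seq_len(max(lab))
    remap[as.integer(names(memb))] <- max(lab) + memb  # temporary ids, then compact
    fg <- lab > 0L
    lab[fg] <- remap[lab[fg]]
    lab[fg] <- match(lab[fg], sort(unique(lab[fg])))
  }
  lab
}

#' Keep only the largest connected component of a mask
#'
#' Ties on component area are broken deterministically by the smallest
#' top-left foreground coordinate (row-major order). An empty mask is
#' returned unchanged.
#'
#' @param mask Logical matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return Logical matrix of the same shape.
#' @export
largest_component <- function(mask, connectivity = 8) {
  sp <- mask_spacing(mask)
  if (!any(mask)) return(structure(mask & FALSE, spacing = sp))
  lab <- label_components(mask, connectivity)
  sizes <- tabulate(lab[lab > 0L])
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # first foreground pixel in column-major scan per candidate; pick the one
    # whose earliest pixel comes first in row-major order
    firsts <- vapply(best, function(id) {
      idx <- which(lab == id)
      rc <- arrayInd(idx, dim(lab))
      idx_rowmajor <- (rc[, 1] - 1L) * ncol(lab) + rc[, 2]
      min(idx_rowmajor)
    }, integer(1))
    best <- best[which.min(firsts)]
  }
  structure(lab == best, spacing = sp)
}
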