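#' Tissue classes of the layered optical head model
#'
#' The six optical tissue classes used throughout the package, in canonical
#' top-down order for a scalp-incised preparation: air above the skull, then
#' (optionally) superficial soft tissue, skull, cerebrospinal fluid, gray
#' matter and white matter. Label volumes store the integer code
#' `match(class, tissue_classes()) - 1L` per voxel (air = 0).
#'
#' @return Character vector of the six class names.
#' @export
tissue_classes <- function() {
  c("air", "soft_tissue", "skull", "csf", "gray", "white")
}

label_code <- function(class) {
  m <- match(class, tissue_classes())
  if (anyNA(m)) {
    abort(paste0("unknown tissue class: ",
                 paste(class[is.na(m)], collapse = ", ")))
  }
  m - 1L
}

#' Construct a voxelized optical head model
#'
#' Low-level constructor: bundles an integer label grid with its voxel size,
#' per-wavelength optical property table and named landmarks. Most users will
#' call [build_layered_phantom()] or [macaque_phantom()] instead.
#'
#' @param labels 3-D integer array of tissue-class codes (see
#'   [tissue_classes()]; air = 0).
#' @param voxel_size Isotropic voxel edge length in mm.
#' @param origin Physical mm coordinate of the corner of voxel `[1,1,1]`.
#'   Voxel centers are at `origin + (index - 0.5) * voxel_size`.
#' @param wavelengths Wavelengths (nm) the model will be solved at.
#' @param landmarks Named list of interior points (mm, length-3 numeric).
#' @param optics Tissue optical property table, see [default_tissue_optics()].
#' @param geometry Surface geometry descriptor: `list(type = "slab")` (outward
#'   normal is -z) or `list(type = "sphere", center =, radius =)`.
#'
#' @return An object of class `voxel_model`.
#' @export
voxel_model <- function(labels, voxel_size, origin = c(0, 0, 0),
                        wavelengths = c(780, 805, 830),
                        landmarks = list(),
                        optics = default_tissue_optics(),
                        geometry = list(type = "slab")) {
  stopifnot(is.array(labels), length(dim(labels)) == 3)
  if (!is.numeric(voxel_size) || length(voxel_size) != 1 || voxel_size <= 0) {
    abort("voxel_size must be a single positive number (mm)")
  }
  storage.mode(labels) <- "integer"
  if (any(labels < 0L | labels > 5L)) {
    abort("labels must be integer codes 0..5 (see tissue_classes())")
  }
  if (!any(labels == label_code("gray"))) {
    abort("model contains no gray-matter voxels")
  }
  m <- structure(
    list(labels = labels, voxel_size = voxel_size, origin = as.numeric(origin),
         wavelengths = as.numeric(wavelengths), landmarks = landmarks,
         optics = optics, geometry = geometry),
    class = "voxel_model")
  for (nm in names(landmarks)) {
    if (is.null(voxel_index(m, landmarks[[nm]]))) {
      abort(paste0("landmark '", nm, "' lies outside the grid"))
    }
  }
  validate_optics(optics, wavelengths)
  m
}

validate_optics <- function(optics, wavelengths) {
  need <- setdiff(tissue_classes(), "air")
  for (w in wavelengths) {
    have <- optics$class[abs(optics$wavelength_nm - w) < 1e-9]
    miss <- setdiff(need, have)
    if (length(miss) > 0) {
      abort(paste0("optics table lacks entries at ", w, " nm for: ",
                   paste(miss, collapse = ", ")))
    }
  }
  bad <- optics$class != "air" &
    (optics$mu_a < 0 | optics$mu_s_prime <= 0 | optics$n < 1)
  if (any(bad)) abort("invalid optical properties (need mu_a >= 0, mu_s_prime > 0, n >= 1)")
  invisible(optics)
}

#' @export
print.voxel_model <- function(x, ...) {
  d <- dim(x$labels)
  cat("<voxel_model> ", paste(d, collapse = " x "), " voxels @ ",
      x$voxel_size, " mm (", x$geometry$type, ")\n", sep = "")
  tab <- table(factor(tissue_classes()[x$labels + 1L],
                      levels = tissue_classes()))
  cat("  labels:", paste0(names(tab), "=", as.integer(tab), collapse = " "), "\n")
  if (length(x$landmarks)) {
    cat("  landmarks:", paste(names(x$landmarks), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @method tidy voxel_model
#' @export
tidy.voxel_model <- function(x, ...) {
  tab <- table(factor(tissue_classes()[x$labels + 1L],
                      levels = tissue_classes()))
  tibble(class = names(tab), n_voxels = as.integer(tab),
         volume_mm3 = as.integer(tab) * x$voxel_size^3)
}

## index helpers ------------------------------------------------------------

# voxel index (integer triplet) containing a physical point, or NULL if outside
voxel_index <- function(model, point) {
  d <- dim(model$labels)
  ijk <- floor((as.numeric(point) - model$origin) / model$voxel_size) + 1L
  ijk <- as.integer(pmin(pmax(ijk, 1L), d))  # clamp points on the far faces
  raw <- (as.numeric(point) - model$origin) / model$voxel_size
  if (any(raw < -1e-9 | raw > d + 1e-9)) return(NULL)
  ijk
}

voxel_center <- function(model, ijk) {
  model$origin + (as.numeric(ijk) - 0.5) * model$voxel_size
}

#' Tissue class label at a physical point
#'
#' Points outside the grid are reported as `"air"` (the model is embedded in
#' air).
#'
#' @param model A [voxel_model()].
#' @param point Physical mm coordinate (length 3).
#' @return Tissue class name.
#' @export
label_at <- function(model, point) {
  ijk <- voxel_index(model, point)
  if (is.null(ijk)) return("air")
  tissue_classes()[model$labels[ijk[1], ijk[2], ijk[3]] + 1L]
}

## phantom construction -----------------------------------------------------

#' Build a layered slab (or spherical-cap) phantom
#'
#' Stacks tissue layers top-down in the canonical order air / soft tissue /
#' skull / CSF / gray / white, with white matter filling the remaining depth.
#' The `hand_knob` landmark is placed at the gray-layer midplane under the
#' grid center. The flat slab is the canonical test geometry; passing a
#' `curvature` radius bends the layer stack over a spherical cap (dome) whose
#' apex is at the grid center.
#'
#' @param layer_thicknesses Named numeric vector/list of layer thicknesses in
#'   mm, e.g. `c(skull = 2, csf = 1, gray = 2)`. Classes not listed get zero
#'   thickness; white matter always fills the rest and need not be listed.
#' @param grid_shape Integer voxel counts `c(nx, ny, nz)`; z is depth.
#' @param voxel_size Voxel edge length, mm.
#' @param curvature Optional sphere radius (mm) for a curved phantom.
#' @param wavelengths,optics Passed to [voxel_model()].
#'
#' @return A [voxel_model()].
#' @export
#' @examples
#' ph <- build_layered_phantom(c(skull = 2, csf = 1, gray = 2),
#'                             grid_shape = c(20, 20, 12), voxel_size = 1)
#' label_at(ph, c(10, 10, 3.5))  # "gray"
build_layered_phantom <- function(layer_thicknesses, grid_shape, voxel_size,
                                  curvature = NULL,
                                  wavelengths = c(780, 805, 830),
                                  optics = default_tissue_optics()) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1), voxel_size > 0)
  thick <- setNames(numeric(6), tissue_classes())
  lt <- unlist(layer_thicknesses)
  unknown <- setdiff(names(lt), tissue_classes())
  if (length(unknown)) {
    abort(paste0("unknown layer class: ", paste(unknown, collapse = ", ")))
  }
  if (any(lt < 0)) abort("layer thicknesses must be >= 0")
  thick[names(lt)] <- lt
  thick["white"] <- 0  # white always fills the remainder
  depth_grid <- grid_shape[3] * voxel_size
  stack_depth <- sum(thick)
  if (stack_depth + voxel_size > depth_grid) {
    over <- names(which.max(thick))
    abort(paste0("grid too shallow for the requested layers (need > ",
                 stack_depth + voxel_size, " mm, have ", depth_grid,
                 " mm); thickest layer: ", over))
  }
  # cumulative depth of the bottom of each layer, top-down order
  bottoms <- cumsum(thick[tissue_classes()[1:5]])
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  zc <- (seq_len(nz) - 0.5) * voxel_size
  if (is.null(curvature)) {
    depth <- array(rep(zc, each = nx * ny), dim = grid_shape)
  } else {
    R <- curvature
    if (R <= max(nx, ny) * voxel_size / 2) {
      abort("curvature radius too small for the lateral grid extent")
    }
    cx <- nx * voxel_size / 2; cy <- ny * voxel_size / 2
    xc <- (seq_len(nx) - 0.5) * voxel_size
    yc <- (seq_len(ny) - 0.5) * voxel_size
    dx2 <- outer((xc - cx)^2, (yc - cy)^2, "+")
    depth <- array(0, dim = grid_shape)
    for (k in seq_len(nz)) {
      # radial depth below the spherical surface (center at (cx, cy, R))
      depth[, , k] <- R - sqrt(dx2 + (zc[k] - R)^2)
    }
  }
  lab <- array(5L, dim = grid_shape)  # white fill
  lab[depth < bottoms[5]] <- 4L       # gray
  lab[depth < bottoms[4]] <- 3L       # csf
  lab[depth < bottoms[3]] <- 2L       # skull
  lab[depth < bottoms[2]] <- 1L       # soft tissue
  lab[depth < bottoms[1]] <- 0L       # air cap
  lab[depth < 0] <- 0L                # above the curved surface
  gray_mid <- unname(bottoms[4] + thick["gray"] / 2)
  center_xy <- c(nx, ny) * voxel_size / 2
  if (is.null(curvature)) {
    knob <- c(center_xy, gray_mid)
  } else {
    knob <- c(center_xy, gray_mid)  # apex column: radial depth == z depth
  }
  geometry <- if (is.null(curvature)) list(type = "slab") else
    list(type = "sphere",
         center = c(center_xy, curvature), radius = curvature)
  voxel_model(lab, voxel_size, wavelengths = wavelengths,
              landmarks = list(hand_knob = knob), optics = optics,
              geometry = geometry)
}

#' The packaged macaque-like layered phantom
#'
#' A scalp-incised parietal configuration: air above skull (2 mm), CSF (1 mm),
#' gray matter (2 mm) and white-matter fill, with the hand-knob landmark at
#' the gray-layer midplane under the grid center. This synthetic phantom
#' stands in for MRI-derived individual head models and reproduces their
#' layer ordering beneath the optode patch.
#'
#' @param grid_shape,voxel_size Grid dimensions; the default spans 70 x 70 mm
#'   laterally and 30 mm of depth at 1 mm, wide enough for source-detector
#'   separations up to 25 mm around the projected hand knob.
#' @inheritParams build_layered_phantom
#' @return A [voxel_model()].
#' @export
macaque_phantom <- function(grid_shape = c(70, 70, 30), voxel_size = 1,
                            curvature = NULL,
                            optics = default_tissue_optics()) {
  build_layered_phantom(c(skull = 2, csf = 1, gray = 2),
                        grid_shape = grid_shape, voxel_size = voxel_size,
                        curvature = curvature, optics = optics)
}

#' Replace superficial soft tissue with air over a surface patch
#'
#' Emulates a scalp-incised preparation: soft-tissue voxels whose (x, y)
#' position falls inside the patch become air. All other labels are left
#' untouched, so the voxel count is conserved.
#'
#' @param model A [voxel_model()].
#' @param region Either `"all"` or a list with `x_range` and `y_range`
#'   (mm, length-2 each) delimiting the patch.
#' @return The modified [voxel_model()].
#' @export
replace_superficial_with_air <- function(model, region = "all") {
  d <- dim(model$labels)
  h <- model$voxel_size
  xc <- model$origin[1] + (seq_len(d[1]) - 0.5) * h
  yc <- model$origin[2] + (seq_len(d[2]) - 0.5) * h
  if (identical(region, "all")) {
    inx <- rep(TRUE, d[1]); iny <- rep(TRUE, d[2])
  } else {
    inx <- xc >= region$x_range[1] & xc <= region$x_range[2]
    iny <- yc >= region$y_range[1] & yc <= region$y_range[2]
  }
  mask <- array(outer(inx, iny, "&"), dim = d)
  sel <- mask & model$labels == label_code("soft_tissue")
  if (!any(sel)) {
    warn("region contains no soft-tissue voxels; model returned unchanged")
    return(model)
  }
  model$labels[sel] <- label_code("air")
  model
}

#' Project an interior point to the tissue-air surface
#'
#' Walks from the interior point along the outward surface normal (straight
#' up for slab phantoms, radially for spherical ones) and returns the point
#' on the tissue-air interface.
#'
#' @param model A [voxel_model()].
#' @param interior_point Physical mm coordinate inside tissue.
#' @return Surface point (mm, length 3).
#' @export
project_to_surface <- function(model, interior_point) {
  if (label_at(model, interior_point) == "air") {
    abort("point is in air; nothing to project")
  }
  h <- model$voxel_size
  p <- as.numeric(interior_point)
  if (model$geometry$type == "slab") {
    nrm <- c(0, 0, -1)
  } else {
    v <- p - model$geometry$center
    nrm <- v / sqrt(sum(v^2))  # radially outward (toward smaller depth)
  }
  step <- h / 4
  q <- p
  repeat {
    q2 <- q + step * nrm
    if (label_at(model, q2) == "air") {
      # bisect the interface between q (tissue) and q2 (air)
      for (i in 1:25) {
        mid <- (q + q2) / 2
        if (label_at(model, mid) == "air") q2 <- mid else q <- mid
      }
      return((q + q2) / 2)
    }
    q <- q2
    if (sum((q - p)^2) > sum(dim(model$labels) * h)^2) {
      abort("no tissue-air interface found along the surface normal")
    }
  }
}

## optical property lookup --------------------------------------------------

# per-class properties at one wavelength, as a list of numeric vectors
# indexed by label code + 1
optics_at <- function(model, wavelength) {
  if (!any(abs(model$wavelengths - wavelength) < 1e-9)) {
    abort(paste0("model not configured for wavelength ", wavelength, " nm"))
  }
  o <- model$optics[abs(model$optics$wavelength_nm - wavelength) < 1e-9, ]
  mu_a <- mu_sp <- nref <- numeric(6)
  idx <- label_code(o$class) + 1L
  mu_a[idx] <- o$mu_a; mu_sp[idx] <- o$mu_s_prime; nref[idx] <- o$n
  list(mu_a = mu_a, mu_s_prime = mu_sp, n = nref)
}
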