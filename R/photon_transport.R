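## Continuous-wave diffusion-approximation forward solver on voxel grids.
##
## Discretization: 7-point finite-volume scheme over tissue voxels only
## (air is excluded from the domain; the tissue-air interface carries Robin
## partial-current boundary conditions). The flux-balance form is assembled,
## so matrix entries are conductances (mm^2), the unknown fluence is W/mm^2
## for a unit (1 W) source, and the absorption term is mu_a * h^3.

# internal-reflection boundary factor A = (1+r_d)/(1-r_d), Fresnel-derived
# polynomial fit in the refractive index
boundary_afactor <- function(n) {
  rd <- -1.440 / n^2 + 0.710 / n + 0.668 + 0.0636 * n
  (1 + rd) / (1 - rd)
}

#' Assemble (and factorize) the diffusion operator for a model
#'
#' Builds the sparse symmetric positive-definite finite-volume system for
#' one wavelength and computes its sparse Cholesky factorization once, so
#' that many sources/detectors can be solved against the same operator
#' (as in channel sweeps). Deterministic; direct solve, no iteration.
#'
#' @param model A [voxel_model()].
#' @param wavelength Wavelength in nm (must be in `model$wavelengths`).
#' @return An object of class `diffusion_operator`.
#' @export
diffusion_operator <- function(model, wavelength) {
  d <- dim(model$labels)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  h <- model$voxel_size
  N <- prod(d)
  lab <- as.integer(model$labels)
  tissue <- lab != 0L
  n_sys <- sum(tissue)
  if (n_sys == 0) abort("model contains no tissue voxels")
  sys_of <- integer(N)
  sys_of[tissue] <- seq_len(n_sys)

  opt <- optics_at(model, wavelength)
  Dclass <- 1 / (3 * (opt$mu_a + opt$mu_s_prime))
  Aclass <- boundary_afactor(opt$n)
  Dv <- Dclass[lab + 1L]        # per grid voxel
  mua_v <- opt$mu_a[lab + 1L]

  lin <- seq_len(N)
  ix <- ((lin - 1L) %% nx) + 1L
  iy <- (((lin - 1L) %/% nx) %% ny) + 1L
  iz <- ((lin - 1L) %/% (nx * ny)) + 1L

  offs <- c(1L, nx, as.integer(nx * ny))
  edge <- list(ix < nx, iy < ny, iz < nz)

  ii <- jj <- integer(0); xx <- numeric(0)
  nb_bnd <- integer(N)          # count of boundary faces per tissue voxel
  diag_v <- mua_v * h^3
  for (a in 1:3) {
    has <- edge[[a]]
    from <- lin[has]; to <- from + offs[a]
    tt <- tissue[from] & tissue[to]
    # interior faces: series conductance through the two half-voxels
    f <- from[tt]; t2 <- to[tt]
    g <- 2 * h * Dv[f] * Dv[t2] / (Dv[f] + Dv[t2])
    sf <- sys_of[f]; st <- sys_of[t2]
    ii <- c(ii, sf, st); jj <- c(jj, st, sf); xx <- c(xx, -g, -g)
    diag_v[f] <- diag_v[f] + g
    diag_v[t2] <- diag_v[t2] + g
    # tissue voxel facing air inside the grid (either orientation)
    ta <- from[tissue[from] & !tissue[to]]
    nb_bnd[ta] <- nb_bnd[ta] + 1L
    at <- to[!tissue[from] & tissue[to]]
    nb_bnd[at] <- nb_bnd[at] + 1L
    # tissue voxel on the grid edge (exterior counts as air)
    lo <- lin[!has]               # far face in +a direction
    nb_bnd[lo[tissue[lo]]] <- nb_bnd[lo[tissue[lo]]] + 1L
    near0 <- switch(a, ix == 1L, iy == 1L, iz == 1L)
    n0 <- lin[near0 & tissue]
    nb_bnd[n0] <- nb_bnd[n0] + 1L
  }
  g_bnd_v <- h^2 / ((h / 2) / Dv + 2 * Aclass[lab + 1L])
  diag_v <- diag_v + nb_bnd * g_bnd_v
  ti <- lin[tissue]
  A <- sparseMatrix(i = c(ii, sys_of[ti]), j = c(jj, sys_of[ti]),
                    x = c(xx, diag_v[ti]), dims = c(n_sys, n_sys))
  factor <- Matrix::Cholesky(forceSymmetric(A), LDL = FALSE, super = TRUE)

  structure(list(
    A = A, factor = factor, sys_of = sys_of, tissue_lin = ti,
    dims = d, h = h, wavelength = wavelength,
    D_voxel = Dv[ti], mua_voxel = mua_v[ti], g_bnd = g_bnd_v[ti],
    n_bnd_faces = nb_bnd[ti],
    model = model), class = "diffusion_operator")
}

#' @export
print.diffusion_operator <- function(x, ...) {
  cat("<diffusion_operator> ", nrow(x$A), " tissue voxels @ ", x$h,
      " mm, ", x$wavelength, " nm\n", sep = "")
  invisible(x)
}

op_solve <- function(op, rhs) {
  as.numeric(Matrix::solve(op$factor, rhs, system = "A"))
}

# physical voxel-center coordinates of system voxels (n_sys x 3)
sys_centers <- function(op) {
  d <- op$dims; nx <- d[1]; ny <- d[2]
  lin <- op$tissue_lin - 1L
  ix <- (lin %% nx) + 1L
  iy <- ((lin %/% nx) %% ny) + 1L
  iz <- (lin %/% (nx * ny)) + 1L
  m <- op$model
  cbind(m$origin[1] + (ix - 0.5) * op$h,
        m$origin[2] + (iy - 0.5) * op$h,
        m$origin[3] + (iz - 0.5) * op$h)
}

# inward surface normal at a surface point
inward_normal <- function(model, surface_point) {
  if (model$geometry$type == "slab") return(c(0, 0, 1))
  v <- model$geometry$center - as.numeric(surface_point)
  v / sqrt(sum(v^2))
}

# Isotropic point source one transport mean free path below the interface,
# spread with trilinear weights over the surrounding tissue voxels.
# Returns list(vec = system RHS summing to 1, position = mm point).
source_vector <- function(op, surface_point) {
  model <- op$model
  h <- op$h
  nrm <- inward_normal(model, surface_point)
  p <- as.numeric(surface_point)
  # locate the entry tissue voxel to read mu_s' (precondition: the point is
  # within about one voxel of the tissue-air interface)
  entry <- NULL
  for (s in seq(0.25, 2, by = 0.25) * h) {
    if (label_at(model, p + s * nrm) != "air") { entry <- p + s * nrm; break }
  }
  if (is.null(entry)) abort("source/detector point is in air, away from any tissue surface")
  opt <- optics_at(model, op$wavelength)
  musp <- opt$mu_s_prime[label_code(label_at(model, entry)) + 1L]
  z0 <- 1 / musp
  pos <- p + z0 * nrm
  # tie-break: if the nominal depth lands outside tissue, take the deepest
  # tissue position along the normal within two transport mean free paths
  if (label_at(model, pos) == "air") {
    for (s in seq(2 * z0, 0.25 * h, by = -0.25 * h)) {
      if (label_at(model, p + s * nrm) != "air") { pos <- p + s * nrm; break }
    }
  }
  w <- trilinear_weights(op, pos)
  if (length(w$sys) == 0) {
    abort("no tissue voxels near the requested source depth")
  }
  vec <- numeric(nrow(op$A))
  vec[w$sys] <- w$w
  list(vec = vec, position = pos, z0 = z0, normal = nrm, musp = musp)
}

# trilinear interpolation weights over tissue voxels around a physical point
trilinear_weights <- function(op, point) {
  m <- op$model; h <- op$h; d <- op$dims
  f <- (as.numeric(point) - m$origin) / h - 0.5
  base <- floor(f); frac <- f - base
  sys <- integer(0); w <- numeric(0)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ijk <- as.integer(base + c(dx, dy, dz) + 1L)
    wt <- prod(ifelse(c(dx, dy, dz) == 1, frac, 1 - frac))
    if (wt <= 0) next
    if (any(ijk < 1L | ijk > d)) next
    lin <- (ijk[3] - 1L) * d[1] * d[2] + (ijk[2] - 1L) * d[1] + ijk[1]
    s <- op$sys_of[lin]
    if (s == 0L) next
    sys <- c(sys, s); w <- c(w, wt)
  }
  if (length(w)) w <- w / sum(w)
  list(sys = sys, w = w)
}

#' Solve the CW diffusion equation for one source
#'
#' Solves `-div(D grad phi) + mu_a phi = S` over the tissue domain with
#' Robin (partial-current) boundary conditions at every tissue-air face,
#' for an isotropic unit point source one transport mean free path
#' (`1/mu_s'`) below the surface at `source`.
#'
#' Two methods are available. `"hybrid"` (default) is a singularity-subtracted
#' scheme: the analytic extrapolated-boundary point-source solution for the
#' source-layer optical properties is used as the primary field and the
#' discrete operator solves only for the (smooth) correction that accounts
#' for domain truncation, boundary shape and tissue heterogeneity away from
#' the source. This removes the large near-source error of a pure 7-point
#' stencil. `"discrete"` is the plain finite-volume solve; it is the
#' building block of the adjoint sensitivity machinery, where its exact
#' linear-algebraic reciprocity matters more than near-field accuracy.
#'
#' @param model A [voxel_model()].
#' @param source Surface point (mm) on the tissue-air interface.
#' @param wavelength Wavelength, nm.
#' @param method `"hybrid"` or `"discrete"`.
#' @param strength Source power (arbitrary units; fluence scales linearly).
#' @param op Optional precomputed [diffusion_operator()] to reuse.
#' @return A `fluence_field` object; `$values` is a full-grid 3-D array
#'   (air voxels 0), non-negative everywhere.
#' @export
solve_fluence <- function(model, source, wavelength,
                          method = c("hybrid", "discrete"),
                          strength = 1, op = NULL) {
  method <- match.arg(method)
  if (is.null(op)) op <- diffusion_operator(model, wavelength)
  sv <- source_vector(op, source)
  if (strength == 0) {
    vals <- array(0, dim = op$dims)
  } else if (method == "discrete") {
    phi <- op_solve(op, sv$vec * strength)
    vals <- field_to_grid(op, pmax(phi, 0))
  } else {
    ph <- hybrid_field(op, sv, strength)
    vals <- field_to_grid(op, pmax(ph, 0))
  }
  structure(list(values = vals, source = as.numeric(source),
                 wavelength = wavelength, method = method,
                 strength = strength, op = op, model = model),
            class = "fluence_field")
}

field_to_grid <- function(op, sysvec) {
  g <- numeric(prod(op$dims))
  g[op$tissue_lin] <- sysvec
  array(g, dim = op$dims)
}

# singularity-subtracted solve: extrapolated-boundary dipole primary +
# discrete correction (residual zeroed in a small ball around the source,
# where the primary is exact up to the boundary-model approximation)
hybrid_field <- function(op, sv, strength = 1, r_cut = 2.5 * op$h) {
  m <- op$model
  opt <- optics_at(m, op$wavelength)
  cls <- label_code(label_at(m, sv$position)) + 1L
  D0 <- 1 / (3 * (opt$mu_a[cls] + opt$mu_s_prime[cls]))
  mueff <- sqrt(opt$mu_a[cls] / D0)
  zb <- 2 * boundary_afactor(opt$n[cls]) * D0
  ctr <- sys_centers(op)
  sp <- sv$position - sv$z0 * sv$normal       # surface point
  rel <- sweep(ctr, 2, sp)
  zloc <- rel %*% sv$normal
  rho2 <- pmax(rowSums(rel^2) - zloc^2, 0)
  r1 <- sqrt(rho2 + (zloc - sv$z0)^2)
  r2 <- sqrt(rho2 + (zloc + sv$z0 + 2 * zb)^2)
  prim <- (exp(-mueff * pmax(r1, 1e-9)) / pmax(r1, 1e-9) -
           exp(-mueff * r2) / r2) / (4 * pi * D0)
  res <- -as.numeric(op$A %*% prim)
  res[r1 <= r_cut] <- 0
  psi <- op_solve(op, res)
  strength * (prim + psi)
}

#' Detected intensity at a surface detector
#'
#' Two detector models are provided. `"partial_current"` returns the Robin
#' boundary flux per unit area at the surface voxel under the detector --
#' the physical reflectance estimate, directly comparable to closed-form
#' semi-infinite reflectance formulas. `"pairing"` evaluates the fluence at
#' the detector optode's own injection point (one transport mean free path
#' deep): because source and detection then use identical vectors against a
#' symmetric operator, source-detector exchange is reciprocal to machine
#' precision, which is the convention the sensitivity machinery uses.
#'
#' @param field A `fluence_field` from [solve_fluence()].
#' @param detector Surface point (mm) on the tissue-air interface.
#' @param method `"partial_current"` or `"pairing"`.
#' @return Detected intensity (arbitrary units), strictly positive for a
#'   nonzero source.
#' @export
detected_intensity <- function(field, detector,
                               method = c("partial_current", "pairing")) {
  method <- match.arg(method)
  op <- field$op
  m <- field$model
  if (method == "pairing") {
    dv <- source_vector(op, detector)  # aborts if detector is off-surface
    phi_sys <- as.numeric(field$values)[op$tissue_lin]
    I <- sum(dv$vec * phi_sys)
  } else {
    nrm <- inward_normal(m, detector)
    # surface voxel under the detector
    q <- as.numeric(detector) + 0.5 * op$h * nrm
    if (label_at(m, q) == "air") q <- as.numeric(detector) + op$h * nrm
    ijk <- voxel_index(m, q)
    if (is.null(ijk) || label_at(m, q) == "air") {
      abort("detector must lie on the tissue-air interface")
    }
    lin <- (ijk[3] - 1L) * op$dims[1] * op$dims[2] +
      (ijk[2] - 1L) * op$dims[1] + ijk[1]
    s <- op$sys_of[lin]
    if (s == 0L) abort("detector must lie on the tissue-air interface")
    if (op$n_bnd_faces[s] == 0L) {
      abort("detector voxel has no tissue-air boundary face (interior point?)")
    }
    I <- op$g_bnd[s] * as.numeric(field$values)[op$tissue_lin][s] / op$h^2
  }
  if (I < 0) I <- 0
  I
}

#' @export
print.fluence_field <- function(x, ...) {
  cat("<fluence_field> ", x$wavelength, " nm, method=", x$method,
      ", source=(", paste(signif(x$source, 4), collapse = ", "), ") mm\n",
      sep = "")
  invisible(x)
}
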