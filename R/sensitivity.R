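## Adjoint (reciprocity) sensitivity machinery: photon measurement density
## function, spatial sensitivity profile, partial path lengths, and the
## source-detector distance sweep.

#' Photon measurement density function of a source-detector pair
#'
#' Computes the per-voxel transit density via the reciprocity principle:
#' `PMDF(v) = V * phi_s(v) * phi_d(v) / I`, where `phi_s` and `phi_d` are
#' the (discrete) fluence fields for unit sources injected at the source
#' and detector optodes and `I = <s_d, phi_s>` is the reciprocal
#' source-detector coupling. With this pairing the identity
#' `sum(PMDF) = -d ln I / d mu_a` holds exactly for the discrete operator
#' (with diffusion coefficient held fixed), and the PMDF and `I` are
#' invariant under source-detector exchange to machine precision.
#'
#' @param model A [voxel_model()].
#' @param source,detector Surface points (mm); must be distinct.
#' @param wavelength Wavelength, nm.
#' @param op Optional precomputed [diffusion_operator()] to reuse.
#' @return An object of class `pmdf`: per-voxel density (mm of path per
#'   voxel; sums to the mean optical path length), detected intensity,
#'   and metadata.
#' @export
compute_pmdf <- function(model, source, detector, wavelength, op = NULL) {
  if (sqrt(sum((as.numeric(source) - as.numeric(detector))^2)) <
      model$voxel_size / 2) {
    abort("source and detector must be distinct surface points")
  }
  if (is.null(op)) op <- diffusion_operator(model, wavelength)
  sv <- source_vector(op, source)
  dv <- source_vector(op, detector)
  phi_s <- op_solve(op, sv$vec)
  phi_d <- op_solve(op, dv$vec)
  I <- sum(dv$vec * phi_s)
  if (!is.finite(I) || I <= 0) {
    abort("degenerate geometry: detected intensity is not positive")
  }
  vals <- op$h^3 * phi_s * phi_d / I
  structure(list(values = field_to_grid(op, vals), intensity = I,
                 source = as.numeric(source), detector = as.numeric(detector),
                 wavelength = wavelength, model = model, op = op),
            class = "pmdf")
}

#' @export
print.pmdf <- function(x, ...) {
  cat("<pmdf> ", x$wavelength, " nm, d_SD = ",
      signif(sqrt(sum((x$source - x$detector)^2)), 4),
      " mm, sum = ", signif(sum(x$values), 5), " mm\n", sep = "")
  invisible(x)
}

#' Spatial sensitivity profile and partial optical path lengths
#'
#' Converts a PMDF into the channel's calibration product. The SSP is the
#' PMDF on the mm scale at which the sum over all voxels equals the mean
#' optical path length (the adjoint identity delivers the PMDF directly on
#' that scale, so the layer-wise sums are the partial optical path lengths
#' in each tissue layer, e.g. `L_gray` for gray matter). The regional
#' `L_gray` sums the gray-matter voxels whose centers fall inside an
#' axis-aligned cube centered at a named landmark.
#'
#' @param pmdf A [compute_pmdf()] result.
#' @param model The model the PMDF was computed on (defaults to the one
#'   stored in the PMDF).
#' @param landmark Name of the landmark for the regional cube.
#' @param cube_edge Cube edge length, mm.
#' @param alignment Optional label (`"parallel"`/`"orthogonal"`) recorded in
#'   the output.
#' @return An object of class `channel_sensitivity` with fields `ssp`
#'   (3-D array), `intensity`, `l_mean`, `partial_path` (named per class),
#'   `regional_l_gray`, `d_sd` and `alignment`.
#' @export
compute_ssp <- function(pmdf, model = pmdf$model, landmark = "hand_knob",
                        cube_edge = 5.4, alignment = NA_character_) {
  if (!landmark %in% names(model$landmarks)) {
    abort(paste0("landmark '", landmark, "' not found in the model"))
  }
  vals <- pmdf$values
  l_mean <- sum(vals)
  lab <- model$labels
  partial <- vapply(tissue_classes(), function(cl) {
    sum(vals[lab == label_code(cl)])
  }, numeric(1))
  lm_pt <- as.numeric(model$landmarks[[landmark]])
  d <- dim(lab); h <- model$voxel_size
  ctr <- list(model$origin[1] + (seq_len(d[1]) - 0.5) * h,
              model$origin[2] + (seq_len(d[2]) - 0.5) * h,
              model$origin[3] + (seq_len(d[3]) - 0.5) * h)
  half <- cube_edge / 2
  inx <- abs(ctr[[1]] - lm_pt[1]) <= half
  iny <- abs(ctr[[2]] - lm_pt[2]) <= half
  inz <- abs(ctr[[3]] - lm_pt[3]) <= half
  cube <- array(FALSE, dim = d)
  cube[inx, iny, inz] <- TRUE
  regional <- sum(vals[cube & lab == label_code("gray")])
  structure(list(ssp = vals, intensity = pmdf$intensity, l_mean = l_mean,
                 partial_path = partial, regional_l_gray = regional,
                 d_sd = sqrt(sum((pmdf$source - pmdf$detector)^2)),
                 alignment = alignment, source = pmdf$source,
                 detector = pmdf$detector, wavelength = pmdf$wavelength,
                 model = model),
            class = "channel_sensitivity")
}

#' @export
print.channel_sensitivity <- function(x, ...) {
  cat("<channel_sensitivity> d_SD = ", signif(x$d_sd, 4), " mm, ",
      x$wavelength, " nm\n  I = ", signif(x$intensity, 4),
      ", L_mean = ", signif(x$l_mean, 5), " mm, L_gray = ",
      signif(x$partial_path[["gray"]], 5), " mm, regional L_gray = ",
      signif(x$regional_l_gray, 5), " mm\n", sep = "")
  invisible(x)
}

#' @method tidy channel_sensitivity
#' @export
tidy.channel_sensitivity <- function(x, ...) {
  pp <- setNames(as.list(x$partial_path),
                 paste0("l_", names(x$partial_path)))
  dplyr::bind_cols(
    tibble(d_sd = x$d_sd, alignment = x$alignment,
           wavelength_nm = x$wavelength, intensity = x$intensity,
           l_mean = x$l_mean),
    as_tibble(pp),
    tibble(regional_l_gray = x$regional_l_gray))
}

#' Source-detector distance optimization sweep
#'
#' Places source-detector pairs symmetrically about the scalp projection of
#' a landmark (the hand knob), along two orthogonal surface axes, and
#' records detected intensity, gray-matter partial path length and regional
#' `L_gray` for each separation -- the inputs to choosing the optimal
#' optode distance. On a flat slab the two alignments are the x and y
#' surface axes (a flat phantom has no sulcus to align with).
#'
#' @param model A [voxel_model()].
#' @param landmark Landmark name to project and center on.
#' @param distances Source-detector separations, mm (strictly increasing).
#' @param alignments Subset of `c("parallel", "orthogonal")`.
#' @param wavelength Wavelength, nm.
#' @param cube_edge Regional cube edge, mm.
#' @return A tibble of class `sensitivity_sweep`, rows ordered by alignment
#'   then distance.
#' @export
sweep_sd_distance <- function(model, landmark = "hand_knob",
                              distances = c(5, 10, 15, 20, 25),
                              alignments = c("parallel", "orthogonal"),
                              wavelength = 805, cube_edge = 5.4) {
  stopifnot(all(distances > 0))
  if (is.unsorted(distances, strictly = TRUE)) {
    abort("distances must be strictly increasing")
  }
  if (!landmark %in% names(model$landmarks)) {
    abort(paste0("landmark '", landmark, "' not found in the model"))
  }
  proj <- project_to_surface(model, model$landmarks[[landmark]])
  axes <- list(parallel = c(1, 0, 0), orthogonal = c(0, 1, 0))
  op <- diffusion_operator(model, wavelength)
  d <- dim(model$labels); h <- model$voxel_size
  lo <- model$origin; hi <- model$origin + d * h
  place <- function(offset, axis) {
    q <- proj + offset * axis
    if (model$geometry$type == "sphere") {
      v <- q - model$geometry$center
      q <- model$geometry$center + model$geometry$radius * v / sqrt(sum(v^2))
    }
    q
  }
  rows <- list()
  for (al in alignments) {
    ax <- axes[[al]]
    for (dd in distances) {
      s <- place(-dd / 2, ax); t <- place(dd / 2, ax)
      inside <- function(q) all(q >= lo - 1e-6) && all(q <= hi + 1e-6)
      if (!inside(s) || !inside(t)) {
        abort(paste0("optode placement falls outside the grid at d_SD = ",
                     dd, " mm (", al, ")"))
      }
      sens <- compute_ssp(compute_pmdf(model, s, t, wavelength, op = op),
                          model, landmark = landmark, cube_edge = cube_edge,
                          alignment = al)
      rows[[length(rows) + 1]] <- tidy(sens)
    }
  }
  out <- bind_rows(rows)
  out <- out[order(match(out$alignment, alignments), out$d_sd), ]
  class(out) <- c("sensitivity_sweep", class(out))
  out
}

#' Voxel-wise maximum sensitivity over channels
#'
#' The per-voxel maximum of the SSPs of a set of channels: a coverage map
#' demarcating regions of higher and lower sensitivity under the array.
#'
#' @param sensitivities Non-empty list of `channel_sensitivity` objects
#'   sharing one model, or of plain SSP arrays of one shape.
#' @return A 3-D array, `>=` each input field everywhere.
#' @export
max_sensitivity_map <- function(sensitivities) {
  if (length(sensitivities) == 0) {
    abort("need at least one channel sensitivity")
  }
  arrs <- purrr::map(sensitivities, function(s) {
    if (inherits(s, "channel_sensitivity")) s$ssp else s
  })
  dims <- purrr::map(arrs, dim)
  if (length(unique(purrr::map_chr(dims, paste, collapse = "x"))) != 1) {
    abort("all sensitivity fields must share one model grid")
  }
  Reduce(pmax, arrs)
}

#' Per-channel sensitivity summary for an optode array
#'
#' Runs the PMDF/SSP machinery for every channel of a layout placed on a
#' model surface and returns the per-channel calibration table (the partial
#' optical path lengths used to calibrate measured absorbance).
#'
#' @param model A [voxel_model()].
#' @param channels Channel map tibble from [enumerate_channels()] (columns
#'   `channel`, `x`, `y`, plus the optode endpoint coordinates
#'   `ax`, `ay`, `bx`, `by`).
#' @param wavelengths Wavelengths to compute, nm.
#' @param landmark,cube_edge Passed to [compute_ssp()].
#' @param keep_fields Keep the full SSP arrays (memory-heavy) in the result?
#' @return A list with `summary` (tibble: channel, wavelength_nm, d_sd,
#'   intensity, l_mean, per-layer paths, regional_l_gray) and, when
#'   requested, `fields` (list of SSP arrays keyed `channel@wavelength`).
#' @export
channel_sensitivities <- function(model, channels,
                                  wavelengths = model$wavelengths,
                                  landmark = "hand_knob", cube_edge = 5.4,
                                  keep_fields = FALSE) {
  rows <- list(); fields <- list()
  surface_z <- function(x, y) {
    # drop the lattice onto the model surface
    if (model$geometry$type == "slab") model$origin[3] else {
      ctr <- model$geometry$center; R <- model$geometry$radius
      ctr[3] - sqrt(R^2 - (x - ctr[1])^2 - (y - ctr[2])^2)
    }
  }
  for (w in wavelengths) {
    op <- diffusion_operator(model, w)
    for (i in seq_len(nrow(channels))) {
      chn <- channels[i, ]
      s <- c(chn$ax, chn$ay, surface_z(chn$ax, chn$ay))
      t2 <- c(chn$bx, chn$by, surface_z(chn$bx, chn$by))
      sens <- compute_ssp(compute_pmdf(model, s, t2, w, op = op), model,
                          landmark = landmark, cube_edge = cube_edge)
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble(channel = chn$channel), tidy(sens))
      if (keep_fields) {
        fields[[paste0(chn$channel, "@", w)]] <- sens$ssp
      }
    }
  }
  out <- list(summary = bind_rows(rows))
  if (keep_fields) out$fields <- fields
  out
}
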