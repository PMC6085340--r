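## Triangular bidirectional optode lattice: layout, channels at edge
## midpoints, switching schedule, and anatomical region assignment.

#' Build a triangular optode lattice
#'
#' Optodes sit at regular-triangle lattice points: successive rows are
#' offset by `edge_length * sqrt(3)/2` vertically and `edge_length / 2`
#' horizontally, so every adjacent pair is separated by exactly
#' `edge_length`. Each optode serves as both source and detector through
#' temporal switching, and one measurement channel lives at each lattice
#' edge midpoint.
#'
#' @param row_spec Integer vector of per-row optode counts (>= 1 each).
#' @param edge_length Lattice edge (= source-detector distance), mm.
#' @return An object of class `optode_layout`: `$optodes` (tibble: optode,
#'   x, y, z in mm), `$adjacency` (tibble: a, b), `$edge_length`.
#' @export
build_triangular_layout <- function(row_spec, edge_length = 15) {
  row_spec <- as.integer(row_spec)
  stopifnot(length(row_spec) >= 1, all(row_spec >= 1), edge_length > 0)
  if (sum(row_spec) < 2) {
    abort("degenerate layout: at least two optodes are required")
  }
  rows <- purrr::imap(row_spec, function(n, r) {
    tibble(x = ((r - 1) %% 2) * edge_length / 2 +
             (seq_len(n) - 1) * edge_length,
           y = -(r - 1) * edge_length * sqrt(3) / 2, z = 0)
  })
  opt <- bind_rows(rows)
  opt <- tibble(optode = seq_len(nrow(opt)), x = opt$x, y = opt$y, z = opt$z)
  dm <- as.matrix(stats::dist(opt[, c("x", "y", "z")]))
  pairs <- which(upper.tri(dm) & abs(dm - edge_length) <= 0.01 * edge_length,
                 arr.ind = TRUE)
  if (nrow(pairs) == 0) {
    abort("degenerate layout: no adjacent optode pairs (no channels possible)")
  }
  adjacency <- tibble(a = opt$optode[pairs[, 1]], b = opt$optode[pairs[, 2]])
  swap <- adjacency$a > adjacency$b
  adjacency[swap, c("a", "b")] <- adjacency[swap, c("b", "a")]
  adjacency <- arrange(adjacency, .data$a, .data$b)
  structure(list(optodes = opt, adjacency = adjacency,
                 edge_length = edge_length),
            class = "optode_layout")
}

#' @export
print.optode_layout <- function(x, ...) {
  cat("<optode_layout> ", nrow(x$optodes), " optodes, ",
      nrow(x$adjacency), " edges, edge = ", x$edge_length, " mm\n", sep = "")
  invisible(x)
}

#' Enumerate measurement channels of a layout
#'
#' One channel per lattice edge, located at the edge midpoint (hence
#' channel spacing `edge_length / 2` between channels sharing an optode).
#' Channel ids are deterministic: sorted by midpoint position (top row
#' first, then left to right), then by optode ids.
#'
#' @param layout An [build_triangular_layout()] result.
#' @return A tibble of class `channel_map`: channel, optode_a, optode_b,
#'   x, y, z (midpoint, mm), endpoint coordinates ax, ay, bx, by,
#'   hemisphere (by sign of x relative to the layout midline), region
#'   (`"unassigned"` until [assign_regions()]), side.
#' @export
enumerate_channels <- function(layout) {
  opt <- layout$optodes
  adj <- layout$adjacency
  pa <- opt[match(adj$a, opt$optode), ]
  pb <- opt[match(adj$b, opt$optode), ]
  mid <- tibble(optode_a = adj$a, optode_b = adj$b,
                x = (pa$x + pb$x) / 2, y = (pa$y + pb$y) / 2,
                z = (pa$z + pb$z) / 2,
                ax = pa$x, ay = pa$y, bx = pb$x, by = pb$y)
  mid <- mid[order(-round(mid$y, 9), round(mid$x, 9),
                   mid$optode_a, mid$optode_b), ]
  midline <- mean(range(opt$x))
  out <- dplyr::bind_cols(tibble(channel = seq_len(nrow(mid))), mid)
  out$hemisphere <- ifelse(out$x < midline, "left", "right")
  out$region <- "unassigned"
  out$side <- NA_character_
  class(out) <- c("channel_map", class(out))
  out
}

#' Build the time-multiplexed switching schedule
#'
#' Every optode serves as the source in exactly one slot per cycle; while
#' it illuminates, all its lattice neighbors detect, so two channels are
#' collected simultaneously per ternary optode group and every channel is
#' measured exactly twice per cycle (once in each direction). One full
#' cycle takes `cycle_ms` (130 ms in the reference configuration), which is
#' the sampling interval after duplicate averaging.
#'
#' @param layout An [build_triangular_layout()] result.
#' @param cycle_ms Full-cycle duration, ms.
#' @return A tibble of class `switching_schedule`: slot, source_optode,
#'   detector_optode, channel; attribute `cycle_ms`.
#' @export
build_schedule <- function(layout, cycle_ms = 130) {
  chans <- enumerate_channels(layout)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  chan_of <- setNames(chans$channel, key(chans$optode_a, chans$optode_b))
  adj2 <- bind_rows(layout$adjacency,
                    tibble(a = layout$adjacency$b, b = layout$adjacency$a))
  out <- tibble(slot = match(adj2$a, sort(unique(layout$optodes$optode))),
                source_optode = adj2$a, detector_optode = adj2$b,
                channel = unname(chan_of[key(adj2$a, adj2$b)]))
  out <- arrange(out, .data$slot, .data$detector_optode)
  attr(out, "cycle_ms") <- cycle_ms
  class(out) <- c("switching_schedule", class(out))
  out
}

#' Attach anatomical region labels to channels
#'
#' @param channel_map From [enumerate_channels()].
#' @param assignment Tibble with columns `channel`, `region` and optionally
#'   `side` (anatomical hemisphere of the region). Each channel may appear
#'   at most once; unknown channel ids are an error. Channels not listed
#'   stay `"unassigned"`.
#' @return The channel map with `region`/`side` filled in.
#' @export
assign_regions <- function(channel_map, assignment) {
  if (nrow(assignment) == 0) return(channel_map)
  if (anyDuplicated(assignment$channel)) {
    dup <- unique(assignment$channel[duplicated(assignment$channel)])
    abort(paste0("channel assigned to more than one region: ",
                 paste(dup, collapse = ", ")))
  }
  unknown <- setdiff(assignment$channel, channel_map$channel)
  if (length(unknown)) {
    abort(paste0("assignment references unknown channels: ",
                 paste(unknown, collapse = ", ")))
  }
  i <- match(channel_map$channel, assignment$channel)
  hit <- !is.na(i)
  channel_map$region[hit] <- assignment$region[i[hit]]
  if ("side" %in% names(assignment)) {
    channel_map$side[hit] <- assignment$side[i[hit]]
  }
  channel_map
}

#' The packaged 15-optode parietal array
#'
#' A two-row staggered triangular lattice of 15 optodes at 15 mm edge
#' length with exactly 27 edges, i.e. 27 measurement channels at 7.5 mm
#' spacing. This synthetic fixture reproduces the published array's
#' topology (optode count, channel count, lattice spacing); absolute
#' stereotaxic coordinates of the original are not tabulated anywhere, so
#' positions here are lattice coordinates with the array midline at x = 0
#' of the subject's head only by convention. Loaded from the packaged
#' CSV + JSON data files so alternative digitizations can be swapped in.
#'
#' @return An `optode_layout`.
#' @export
paper_layout <- function() {
  csv <- system.file("extdata", "optode_layout_15.csv", package = "nirsim")
  adj <- system.file("extdata", "optode_adjacency_15.json", package = "nirsim")
  if (nzchar(csv) && nzchar(adj)) {
    return(read_optode_layout(csv, adj, edge_length = 15))
  }
  build_triangular_layout(c(8, 7), 15)
}

#' Region-to-channel correspondence table
#'
#' The published correspondence between motor-cortical areas and channel
#' numbers: premotor area (PMA) channels 8-10 (left) and 11-13 (right),
#' supplementary motor area (SMA) channels 17/18, hand primary motor
#' cortex (hand M1) channels 16, 21, 22, 26 (left) and 19, 23, 24, 27
#' (right), and mouth M1 channels 1, 6, 20 (left) and 5, 15, 25 (right).
#'
#' @return Tibble with columns channel, region, side.
#' @export
paper_region_table <- function() {
  path <- system.file("extdata", "region_table.csv", package = "nirsim")
  if (nzchar(path)) {
    return(readr::read_csv(path, show_col_types = FALSE,
                           col_types = "icc"))
  }
  region_table_builtin()
}

region_table_builtin <- function() {
  bind_rows(
    tibble(channel = c(8L, 9L, 10L), region = "PMA", side = "left"),
    tibble(channel = c(11L, 12L, 13L), region = "PMA", side = "right"),
    tibble(channel = 17L, region = "SMA", side = "left"),
    tibble(channel = 18L, region = "SMA", side = "right"),
    tibble(channel = c(16L, 21L, 22L, 26L), region = "hand_M1", side = "left"),
    tibble(channel = c(19L, 23L, 24L, 27L), region = "hand_M1", side = "right"),
    tibble(channel = c(1L, 6L, 20L), region = "mouth_M1", side = "left"),
    tibble(channel = c(5L, 15L, 25L), region = "mouth_M1", side = "right"))
}

#' Read / write optode layouts as CSV + JSON adjacency
#'
#' @param csv_path CSV with columns optode, x_mm, y_mm, z_mm.
#' @param adjacency_path JSON array of `[a, b]` optode id pairs.
#' @param edge_length Lattice edge length, mm.
#' @return An `optode_layout` (read); `csv_path`, invisibly (write).
#' @export
read_optode_layout <- function(csv_path, adjacency_path, edge_length) {
  df <- readr::read_csv(csv_path, show_col_types = FALSE,
                        col_types = "idddd")
  opt <- tibble(optode = as.integer(df$optode), x = df$x_mm, y = df$y_mm,
                z = df$z_mm)
  pairs <- jsonlite::read_json(adjacency_path, simplifyVector = TRUE)
  adjacency <- tibble(a = as.integer(pairs[, 1]), b = as.integer(pairs[, 2]))
  structure(list(optodes = opt, adjacency = arrange(adjacency, .data$a, .data$b),
                 edge_length = edge_length),
            class = "optode_layout")
}

#' @param layout Layout to write.
#' @rdname read_optode_layout
#' @export
write_optode_layout <- function(layout, csv_path, adjacency_path) {
  readr::write_csv(
    tibble(optode = layout$optodes$optode, x_mm = layout$optodes$x,
           y_mm = layout$optodes$y, z_mm = layout$optodes$z), csv_path)
  jsonlite::write_json(as.matrix(layout$adjacency), adjacency_path,
                       digits = NA)
  invisible(csv_path)
}
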