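# Snapshot I/O: single-channel TIFF images plus CSV tables.
#
# Label images are written as 16-bit TIFF with the cell index scaled by
# 1/65535 (the `tiff` package stores intensities in [0, 1]); float fields are
# written normalized to [0, 1] with the scale recorded in a sidecar CSV, so
# snapshots round-trip exactly to the stated precision.

#' Write a label image as 16-bit TIFF
#'
#' @param grid integer matrix of cell indices (< 65536).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_label_tiff <- function(grid, path) {
  if (max(grid) > 65535) stop("cell index exceeds 16-bit range")
  tiff::writeTIFF(grid / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Read a label image written by [write_label_tiff()]
#'
#' @param path TIFF path.
#' @return integer matrix of cell indices.
#' @export
read_label_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  storage.mode(m) <- "double"
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Write a float field as normalized TIFF plus scale sidecar
#'
#' @param field numeric matrix.
#' @param path output TIFF path; the scale (min/max) is written to
#'   `paste0(path, ".scale.csv")`.
#' @return `path`, invisibly.
#' @export
write_field_tiff <- function(field, path) {
  lo <- min(field); hi <- max(field)
  scl <- if (hi > lo) (field - lo) / (hi - lo) else field * 0
  tiff::writeTIFF(scl, path, bits.per.sample = 16L, compression = "none")
  write.csv(data.frame(min = lo, max = hi),
            paste0(path, ".scale.csv"), row.names = FALSE)
  invisible(path)
}

#' Read a field written by [write_field_tiff()]
#'
#' @param path TIFF path.
#' @return numeric matrix restored to physical units.
#' @export
read_field_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  sc <- read.csv(paste0(path, ".scale.csv"))
  m * (sc$max - sc$min) + sc$min
}

#' Write a trajectory to disk
#'
#' Per snapshot: the label image (`cells_t<MCS>.tif`), the density,
#' bound-VEGF, soluble-VEGF, thickness and displacement-magnitude fields
#' (`<name>_t<MCS>.tif` + scale sidecars), and a cell table
#' (`cells_t<MCS>.csv` with id, phi, area, perimeter, length, centroid).
#' Also writes `metrics.csv` (field summaries), `ledger.csv` (conservation
#' and solver diagnostics) and `config.txt`.
#'
#' @param traj a `vasc_trajectory`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_trajectory <- function(traj, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dx <- traj$config$dx
  summaries <- NULL
  for (sn in traj$snapshots) {
    tag <- sprintf("t%04d", sn$time_mcs)
    write_label_tiff(sn$grid, file.path(dir, sprintf("cells_%s.tif", tag)))
    fields <- list(rho = sn$rho, bound_vegf = sn$b, soluble_vegf = sn$c,
                   thickness = sn$h, displacement = sqrt(sn$u$x^2 + sn$u$y^2))
    for (nm in names(fields)) {
      write_field_tiff(fields[[nm]], file.path(dir, sprintf("%s_%s.tif", nm, tag)))
      summaries <- rbind(summaries, data.frame(
        time_mcs = sn$time_mcs, field = nm, min = min(fields[[nm]]),
        max = max(fields[[nm]]), mean = mean(fields[[nm]])))
    }
    lat <- lattice_state(sn$grid, dx)
    geo <- cell_geometry(lat)
    geo$phi <- sn$phi
    write.csv(geo[, c("id", "phi", "area", "perimeter", "length", "cx", "cy")],
              file.path(dir, sprintf("cells_%s.csv", tag)), row.names = FALSE)
  }
  write.csv(summaries, file.path(dir, "metrics.csv"), row.names = FALSE)
  write.csv(traj$ledger, file.path(dir, "ledger.csv"), row.names = FALSE)
  write_config(traj$config, file.path(dir, "config.txt"))
  # per-MCS centroid record (long format)
  nc <- dim(traj$centroids)[1]
  nt <- dim(traj$centroids)[3]
  cent <- data.frame(
    mcs = rep(seq_len(nt) - 1, each = nc),
    id = rep(seq_len(nc), nt),
    cx = as.vector(traj$centroids[, 1, ]),
    cy = as.vector(traj$centroids[, 2, ]))
  write.csv(cent, file.path(dir, "centroids.csv"), row.names = FALSE)
  invisible(dir)
}
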