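#' Read a 3D image stack from a (OME-)TIFF file
#'
#' Reads a multi-page TIFF into a [voxel_grid()]. Voxel size is resolved, in
#' order of precedence, from (1) `voxel_size_override`, (2) a JSON sidecar
#' `<path>.json` as written by [write_stack()], (3) TIFF metadata: an
#' ImageJ-style description tag (`spacing=`, `unit=micron`) for z combined
#' with the x/y resolution tags. If none yields a full `(dz, dy, dx)` triple
#' the call fails: counting in physical units without a calibrated voxel
#' size is meaningless.
#'
#' Integer TIFF samples are read at their native integer values (so an 8-bit
#' stack spans 0..255) and the dtype full-scale is recorded for
#' [check_saturation()]; float TIFFs are read as-is together with any sidecar
#' `scale` used at write time.
#'
#' @param path TIFF file path.
#' @param voxel_size_override optional `(dz, dy, dx)` in µm, overriding
#'   metadata.
#' @return A `VoxelGrid`.
#' @export
read_stack <- function(path, voxel_size_override = NULL) {
  if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
  # readTIFF normalizes integer samples to [0, 1] and returns float
  # samples as stored
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2L)
    stop("non-3D data: ", path, " has fewer than 2 slices", call. = FALSE)
  if (length(dim(pages[[1]])) != 2L)
    stop("only single-channel grayscale stacks are supported", call. = FALSE)
  info <- attributes(pages[[1]])
  bits <- info$bits.per.sample
  is_int <- !is.null(bits) && bits %in% c(8L, 12L, 16L)  # 32-bit = float
  ny <- dim(pages[[1]])[1]; nx <- dim(pages[[1]])[2]; nz <- length(pages)

  # assemble as (z, y, x)
  data <- array(0, c(nz, ny, nx))
  for (i in seq_len(nz)) data[i, , ] <- pages[[i]]

  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar, simplifyVector = TRUE) else NULL

  full_scale <- NULL
  if (is_int) {
    # undo readTIFF's [0, 1] normalization back to native integer values
    data <- round(data * (2^bits - 1))
    full_scale <- 2^bits - 1
  } else if (!is.null(meta$scale)) {
    data <- data * meta$scale
  }

  vs <- NULL
  if (!is.null(voxel_size_override)) {
    vs <- voxel_size_override
  } else if (!is.null(meta$voxel_size)) {
    vs <- as.numeric(meta$voxel_size)
  } else {
    vs <- voxel_size_from_tags(info)
  }
  if (is.null(vs))
    stop("no voxel-size information for ", path,
         "; supply voxel_size_override", call. = FALSE)
  voxel_grid(data, vs, full_scale = full_scale)
}

# Parse (dz, dy, dx) from TIFF tags: ImageJ description 'spacing=' for z,
# resolution tags (pixels per unit) for y/x. Returns NULL if incomplete.
voxel_size_from_tags <- function(info) {
  dz <- dy <- dx <- NA_real_
  desc <- info$description
  if (!is.null(desc) && grepl("spacing=", desc)) {
    dz <- as.numeric(sub(".*spacing=([0-9.eE+-]+).*", "\\1", desc))
  }
  unit_scale <- 1
  if (!is.null(info$resolution.unit) && info$resolution.unit == "cm")
    unit_scale <- 1e4  # pixels/cm -> um/pixel = 1e4 / res
  if (!is.null(info$resolution.unit) && info$resolution.unit == "inch")
    unit_scale <- 25400
  if (!is.null(info$x.resolution) && info$x.resolution > 0)
    dx <- unit_scale / info$x.resolution
  if (!is.null(info$y.resolution) && info$y.resolution > 0)
    dy <- unit_scale / info$y.resolution
  vs <- c(dz, dy, dx)
  if (any(!is.finite(vs)) || any(vs <= 0)) return(NULL)
  vs
}

#' Write a 3D image stack to TIFF with a JSON metadata sidecar
#'
#' Intensities are stored as 32-bit float samples. Because baseline TIFF
#' float samples are defined on `[0, 1]`, values are divided by a scale
#' (the smallest power of two at or above the data maximum) that is recorded,
#' together with the voxel size, in a sidecar `<path>.json`; [read_stack()]
#' undoes the scaling. Powers of two keep the round trip exact at float32
#' precision.
#'
#' @param grid a `VoxelGrid`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(grid, path) {
  stopifnot(inherits(grid, "VoxelGrid"))
  mx <- max(grid$data)
  scale <- if (mx <= 1) 1 else 2^ceiling(log2(mx))
  nz <- dim(grid$data)[1]
  pages <- lapply(seq_len(nz), function(i) grid$data[i, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "deflate",
                  reduce = FALSE)
  jsonlite::write_json(
    list(voxel_size = grid$voxel_size, scale = scale, float = TRUE,
         axis_order = "zyx", unit = "micron"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Check an image stack for intensity saturation
#'
#' Multi-threshold segmentation presumes the intensity histogram is not
#' clipped at the detector maximum: thresholds are percentages of the image
#' maximum, and a saturated maximum both flattens bright boutons into
#' plateaus and distorts every threshold below it. This check reports the
#' fraction of voxels at full scale and fails when it exceeds
#' `max_fraction` (default 0: any saturated voxel fails).
#'
#' @param grid a `VoxelGrid`.
#' @param max_fraction maximum tolerated fraction of saturated voxels.
#' @param full_scale detector full-scale value; defaults to the grid's
#'   recorded value. Required for floating-point data.
#' @return A list of class `saturation_report`: `fraction`, `pass`,
#'   `full_scale`, `n_saturated`.
#' @export
check_saturation <- function(grid, max_fraction = 0, full_scale = NULL) {
  stopifnot(inherits(grid, "VoxelGrid"))
  fs <- if (!is.null(full_scale)) full_scale else grid$full_scale
  if (is.null(fs))
    stop("full-scale value unknown: floating-point data need 'full_scale'",
         call. = FALSE)
  n_sat <- sum(grid$data >= fs)
  frac <- n_sat / length(grid$data)
  structure(list(fraction = frac, pass = frac <= max_fraction,
                 full_scale = fs, n_saturated = n_sat),
            class = "saturation_report")
}

#' @export
print.saturation_report <- function(x, ...) {
  cat(sprintf("saturation: %d voxels at full scale %g (fraction %.3g) -> %s\n",
              x$n_saturated, x$full_scale, x$fraction,
              if (x$pass) "pass" else "FAIL"))
  invisible(x)
}

#' Write / read bouton center tables
#'
#' Centers are exchanged as plain CSV with columns `x, y, z` (µm) and
#' `n_thresholds`, the number of threshold levels whose segmented objects
#' contributed to the merged center. Values round-trip at 6 decimals.
#'
#' @param bouton_set a `BoutonSet` (see [merge_centers()]) or a matrix of
#'   `(z, y, x)` centers.
#' @param path CSV path.
#' @return `write_centers()`: `path` invisibly. `read_centers()`: a
#'   data.frame with columns `x, y, z, n_thresholds`.
#' @export
write_centers <- function(bouton_set, path) {
  if (inherits(bouton_set, "BoutonSet")) {
    centers <- bouton_set$centers
    nthr <- vapply(bouton_set$members, function(m)
      length(unique(m$threshold)), integer(1))
  } else {
    centers <- matrix(bouton_set, ncol = 3L)
    nthr <- rep(NA_integer_, nrow(centers))
  }
  if (nrow(centers) > 0 && any(!is.finite(centers)))
    stop("centers must be finite", call. = FALSE)
  df <- data.frame(x = round(centers[, 3], 6), y = round(centers[, 2], 6),
                   z = round(centers[, 1], 6), n_thresholds = nthr)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_centers
#' @export
read_centers <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
  utils::read.csv(path)
}

# centers matrix (z,y,x) from a centers data.frame
centers_zyx <- function(df) {
  cbind(z = df$z, y = df$y, x = df$x)
}
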