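#' Voxel spacing in nanometres
#'
#' Physical size of one voxel along each axis. The default matches a typical
#' FIB/SEM acquisition: 5 nm/pixel in the imaging plane and 20 nm milled per
#' section in z.
#'
#' @param dx,dy,dz Spacing in nm along x, y (in-plane) and z (across
#'   sections). All must be strictly positive.
#' @return A named numeric vector of class `voxel_spacing`.
#' @export
#' @examples
#' voxel_spacing()          # acquisition spacing (5, 5, 20)
#' voxel_spacing(20, 20, 20) # isotropic analysis spacing
voxel_spacing <- function(dx = 5, dy = 5, dz = 20) {
  s <- c(dx = as.numeric(dx), dy = as.numeric(dy), dz = as.numeric(dz))
  if (any(!is.finite(s)) || any(s <= 0)) {
    stop("voxel spacing must be strictly positive and finite", call. = FALSE)
  }
  structure(s, class = "voxel_spacing")
}

as_voxel_spacing <- function(x) {
  if (inherits(x, "voxel_spacing")) return(x)
  x <- as.numeric(x)
  if (length(x) == 1) x <- rep(x, 3)
  if (length(x) != 3) stop("spacing must have length 1 or 3", call. = FALSE)
  voxel_spacing(x[1], x[2], x[3])
}

#' Label volume: a 3D integer compartment map with physical spacing
#'
#' Wraps a 3D integer array of compartment labels (0 = background). The array
#' is stored with dimensions `(ny, nx, nz)` so that `labels[j, i, k]` is the
#' voxel in image row `j` (y), column `i` (x) of section `k` (z), matching how
#' multi-page TIFF stacks are read. The physical center of voxel `(i, j, k)`
#' (1-based) is `((i - 0.5) dx, (j - 0.5) dy, (k - 0.5) dz)` nm, i.e. the
#' volume's physical origin is the outer corner of the first voxel.
#'
#' @param labels 3D integer array, non-negative, dims `(ny, nx, nz)`.
#' @param spacing A [voxel_spacing()] (or numeric length 3, nm).
#' @return An object of class `label_volume` with elements `labels` and
#'   `spacing`.
#' @export
label_volume <- function(labels, spacing = voxel_spacing()) {
  spacing <- as_voxel_spacing(spacing)
  if (length(dim(labels)) != 3) stop("labels must be a 3D array", call. = FALSE)
  if (dim(labels)[3] < 1) stop("volume must contain at least one section", call. = FALSE)
  if (is.double(labels)) {
    if (any(labels != round(labels))) {
      stop("labels must be integers", call. = FALSE)
    }
    storage.mode(labels) <- "integer"
  }
  if (!is.integer(labels)) stop("labels must be an integer array", call. = FALSE)
  if (any(labels < 0)) stop("labels must be non-negative", call. = FALSE)
  structure(list(labels = labels, spacing = spacing), class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf(
    "<label_volume> %d x %d x %d voxels (ny, nx, nz), spacing %g x %g x %g nm\n",
    d[1], d[2], d[3], x$spacing["dx"], x$spacing["dy"], x$spacing["dz"]
  ))
  labs <- label_ids(x)
  cat("  compartment labels:", if (length(labs)) paste(labs, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Shape of a label volume as (nz, ny, nx)
#' @param vol A `label_volume`.
#' @return Named integer vector `c(nz, ny, nx)`.
#' @export
volume_shape <- function(vol) {
  d <- dim(vol$labels)
  c(nz = d[3], ny = d[1], nx = d[2])
}

#' Non-background label ids present in a volume
#' @param vol A `label_volume`.
#' @return Sorted integer vector of labels > 0.
#' @export
label_ids <- function(vol) {
  u <- sort(unique(as.vector(vol$labels)))
  u[u > 0L]
}

#' Physical bounds of a volume in nm
#' @param vol A `label_volume`.
#' @return Named numeric vector `c(x, y, z)`: the upper physical extent.
#' @export
volume_extent <- function(vol) {
  d <- dim(vol$labels)
  s <- vol$spacing
  c(x = d[2] * s[["dx"]], y = d[1] * s[["dy"]], z = d[3] * s[["dz"]])
}

#' Physical centers of voxels (nm)
#'
#' @param vol A `label_volume`.
#' @param ix,iy,iz 1-based voxel indices (x column, y row, z section).
#' @return A tibble with columns `x`, `y`, `z` in nm.
#' @export
voxel_centers <- function(vol, ix, iy, iz) {
  s <- vol$spacing
  tibble::tibble(
    x = (ix - 0.5) * s[["dx"]],
    y = (iy - 0.5) * s[["dy"]],
    z = (iz - 0.5) * s[["dz"]]
  )
}

#' Read a segmented label volume from a multi-page TIFF
#'
#' Page `k` of the stack maps to section index `k`; pixel (row, col) maps to
#' (y, x). Pixels must be of an integer type (uint8/uint16).
#'
#' @param path Path to a multi-page TIFF file.
#' @param spacing Physical voxel spacing ([voxel_spacing()] or numeric, nm).
#' @return A [label_volume()].
#' @export
read_label_volume <- function(path, spacing = voxel_spacing()) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0) stop("empty TIFF stack: ", path, call. = FALSE)
  ok <- vapply(pages, function(p) is.matrix(p) && is.integer(p), logical(1))
  if (!all(ok)) {
    stop("label TIFF must contain single-channel integer pages: ", path, call. = FALSE)
  }
  d1 <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) identical(dim(p), d1), logical(1)))) {
    stop("all TIFF pages must share the same dimensions", call. = FALSE)
  }
  arr <- array(0L, dim = c(d1[1], d1[2], length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
  label_volume(arr, spacing)
}

#' Write a label volume to a multi-page TIFF
#'
#' Written as uint8 when the maximum label fits, uint16 otherwise. Round-trips
#' exactly through [read_label_volume()].
#'
#' @param vol A `label_volume`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(vol, path) {
  mx <- max(vol$labels)
  bits <- if (mx < 256) 8L else 16L
  if (mx > 65535) stop("labels exceed uint16 range", call. = FALSE)
  denom <- 2^bits - 1
  nz <- dim(vol$labels)[3]
  pages <- lapply(seq_len(nz), function(k) vol$labels[, , k] / denom)
  tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none",
                  reduce = FALSE)
  invisible(path)
}

particle_required_cols <- c("particle_id", "x_nm", "y_nm", "z_nm")

#' Read an immunogold particle table (CSV, nm units)
#'
#' Required columns: `particle_id, x_nm, y_nm, z_nm` (coordinates in nm in the
#' volume frame). Optional: `compartment_id`, `localization` (`PM` or
#' `intracellular`). Row order is preserved.
#'
#' @param path CSV path.
#' @return A tibble, one row per particle.
#' @export
read_particle_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(particle_required_cols, names(df))
  if (length(missing_cols)) {
    stop("particle table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("x_nm", "y_nm", "z_nm")) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      if (anyNA(conv) && !anyNA(v)) {
        stop("non-numeric values in column ", col, call. = FALSE)
      }
      df[[col]] <- conv
    }
    if (anyNA(df[[col]])) stop("missing/non-numeric values in column ", col, call. = FALSE)
  }
  if (anyDuplicated(df$particle_id)) {
    stop("duplicate particle_id values in ", path, call. = FALSE)
  }
  if ("localization" %in% names(df)) {
    bad <- !df$localization %in% c("PM", "intracellular", NA, "")
    if (any(bad)) stop("localization must be 'PM' or 'intracellular'", call. = FALSE)
    df$localization[df$localization == ""] <- NA_character_
  }
  tibble::as_tibble(df)
}

#' Write a particle table to CSV (nm units)
#' @param particles Tibble with at least `particle_id, x_nm, y_nm, z_nm`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_particle_table <- function(particles, path) {
  readr::write_csv(particles, path)
  invisible(path)
}

#' Read synapse patch metadata (CSV)
#'
#' Columns: `patch_id` (integer label in the synapse patch volume), `type`
#' (`asymmetric` or `symmetric`), `compartment_id` (the compartment whose
#' surface the patch sits on).
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_synapse_meta <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patch_id", "type", "compartment_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("synapse metadata missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!all(df$type %in% c("asymmetric", "symmetric"))) {
    stop("synapse type must be 'asymmetric' or 'symmetric'", call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Read compartment metadata (CSV)
#'
#' Columns: `label_id`, `kind` (one of `pyramidal_shaft`, `spine`,
#' `interneuron_shaft`), optional `parent_id` (a spine's parent shaft).
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_compartment_meta <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label_id", "kind")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("compartment metadata missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  kinds <- c("pyramidal_shaft", "spine", "interneuron_shaft")
  if (!all(df$kind %in% kinds)) {
    stop("kind must be one of: ", paste(kinds, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$label_id)) stop("label_id values must be unique", call. = FALSE)
  if (!"parent_id" %in% names(df)) df$parent_id <- NA_integer_
  spine_no_parent <- df$kind == "spine" & is.na(df$parent_id)
  if (any(spine_no_parent)) stop("spine compartments require a parent_id", call. = FALSE)
  tibble::as_tibble(df)
}

#' Write result tables plus a reproducibility manifest
#'
#' Each element of `tables` is written as `<name>.csv` with a fixed column
#' order; a `manifest.json` records the package version, seed, parameters and
#' per-table row counts. Re-running with identical inputs and seed reproduces
#' byte-identical CSVs; manifests differ only in the `created` timestamp.
#'
#' @param tables Named list of data frames.
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed used for the run (recorded, not consumed).
#' @param params Named list of run parameters to record.
#' @return Character vector of file paths written, invisibly.
#' @export
write_results <- function(tables, out_dir, seed = NULL, params = list()) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  stopifnot(is.list(tables))
  if (length(tables) && is.null(names(tables))) stop("tables must be named", call. = FALSE)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    readr::write_csv(as.data.frame(tables[[nm]]), p)
    paths <- c(paths, p)
  }
  manifest <- list(
    package = "skmap",
    version = as.character(utils::packageVersion("skmap")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    parameters = params,
    tables = lapply(tables, function(t) list(rows = nrow(as.data.frame(t))))
  )
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(paths, mp))
}
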