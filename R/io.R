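#' Write a volume in MetaImage (MHD + RAW) format
#'
#' @param values 3D array.
#' @param path Output path ending in `.mhd`; the raw block is written
#'   next to it.
#' @param spacing Numeric length-3 element spacing (mm).
#' @param origin Numeric length-3 position of the first element (mm).
#' @param element_type `"float"`, `"double"`, `"int"`, or `"uchar"`.
#' @return `path`, invisibly.
#' @export
write_mhd <- function(values, path, spacing, origin = c(0, 0, 0),
                      element_type = c("float", "double", "int", "uchar")) {
  element_type <- match.arg(element_type)
  if (length(dim(values)) != 3L) stop("values must be a 3D array")
  raw_name <- sub("\\.mhd$", ".raw", basename(path))
  met <- c(float = "MET_FLOAT", double = "MET_DOUBLE", int = "MET_INT",
           uchar = "MET_UCHAR")[[element_type]]
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    sprintf("Offset = %s", paste(format(origin, trim = TRUE), collapse = " ")),
    "CenterOfRotation = 0 0 0",
    "AnatomicalOrientation = RAI",
    sprintf("ElementSpacing = %s",
            paste(format(spacing, trim = TRUE), collapse = " ")),
    sprintf("DimSize = %d %d %d", dim(values)[1], dim(values)[2],
            dim(values)[3]),
    sprintf("ElementType = %s", met),
    sprintf("ElementDataFile = %s", raw_name)
  )
  writeLines(hdr, path)
  con <- file(file.path(dirname(path), raw_name), "wb")
  on.exit(close(con))
  v <- as.vector(values)
  switch(element_type,
         float = writeBin(as.numeric(v), con, size = 4, endian = "little"),
         double = writeBin(as.numeric(v), con, size = 8, endian = "little"),
         int = writeBin(as.integer(v), con, size = 4, endian = "little"),
         uchar = writeBin(as.raw(v), con))
  invisible(path)
}

#' Read a MetaImage (MHD + RAW) volume
#'
#' @param path Path to the `.mhd` header.
#' @return List with `values` (3D array), `spacing`, `origin`.
#' @export
read_mhd <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = " "), character(1))
  get <- function(k) vals[match(k, keys)]
  dims <- as.integer(strsplit(get("DimSize"), "\\s+")[[1]])
  spacing <- as.numeric(strsplit(get("ElementSpacing"), "\\s+")[[1]])
  origin <- as.numeric(strsplit(get("Offset"), "\\s+")[[1]])
  et <- get("ElementType")
  raw_path <- file.path(dirname(path), get("ElementDataFile"))
  n <- prod(dims)
  con <- file(raw_path, "rb")
  on.exit(close(con))
  v <- switch(et,
              MET_FLOAT = readBin(con, numeric(), n, size = 4, endian = "little"),
              MET_DOUBLE = readBin(con, numeric(), n, size = 8, endian = "little"),
              MET_INT = readBin(con, integer(), n, size = 4, endian = "little"),
              MET_UCHAR = as.integer(readBin(con, raw(), n)),
              stop("unsupported ElementType: ", et))
  list(values = array(v, dim = dims), spacing = spacing, origin = origin)
}

grid_is_uniform <- function(grid) {
  ok <- function(d) length(d) == 0 || max(d) - min(d) <= 1e-9 * max(d)
  ok(grid$dx) && ok(grid$dy) && ok(grid$dz)
}

#' Export a cell volume on a model grid to MetaImage
#'
#' Uniform grids are written directly; non-uniform grids are resampled
#' to a uniform spacing (default: the finest step) with the original
#' axis coordinates recorded in a JSON sidecar (`<path>.json`).
#'
#' @param values Per-cell 3D array.
#' @param grid The [rectilinear_grid()].
#' @param path Output `.mhd` path.
#' @param spacing Optional uniform export spacing (mm).
#' @param element_type Passed to [write_mhd()].
#' @param sidecar Extra metadata stored in the JSON sidecar.
#' @return `path`, invisibly.
#' @export
export_volume <- function(values, grid, path, spacing = NULL,
                          element_type = "float", sidecar = list()) {
  meta <- list(units = sidecar$units, coordinates = "cell centers (mm)")
  meta <- c(meta, sidecar[setdiff(names(sidecar), "units")])
  if (is.null(spacing) && grid_is_uniform(grid)) {
    write_mhd(values, path, spacing = c(grid$dx[1], grid$dy[1], grid$dz[1]),
              origin = c(grid$cx[1], grid$cy[1], grid$cz[1]),
              element_type = element_type)
  } else {
    if (is.null(spacing)) spacing <- min(grid$dx, grid$dy, grid$dz)
    qx <- uniform_centers(min(grid$x), max(grid$x), spacing)
    qy <- uniform_centers(min(grid$y), max(grid$y), spacing)
    qz <- uniform_centers(min(grid$z), max(grid$z), spacing)
    res <- resample_volume(sar_volume(values, grid = grid), qx, qy, qz)
    write_mhd(res$values, path, spacing = rep(spacing, 3),
              origin = c(qx[1], qy[1], qz[1]), element_type = element_type)
    meta$resampled_from <- list(x = grid$cx, y = grid$cy, z = grid$cz)
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Export a voxel model as a label volume with JSON sidecar
#'
#' @param model A [voxel_model()].
#' @param path Output `.mhd` path.
#' @param spacing Optional uniform export spacing (mm).
#' @return `path`, invisibly.
#' @export
export_model <- function(model, path, spacing = NULL) {
  mats <- lapply(model$materials, function(m) m[c("sigma", "eps_r", "rho",
                                                  "c", "k", "perfusion")])
  export_volume(model$material + 0, model$grid, path, spacing = spacing,
                element_type = "float",
                sidecar = list(units = "material label",
                               materials = mats,
                               electrode_count = n_electrodes(model),
                               voi = model$voi[c("lo", "hi")]))
  invisible(path)
}

#' Save / load a field basis
#'
#' Bases are stored as single-file R serializations so plan re-evaluation
#' can run without any solver work.
#'
#' @param basis A [compute_basis()] result.
#' @param path File path.
#' @return `path` (save) or the restored basis (load).
#' @export
save_basis <- function(basis, path) {
  saveRDS(basis, path)
  invisible(path)
}

#' @rdname save_basis
#' @export
load_basis <- function(path) {
  b <- readRDS(path)
  if (!inherits(b, "field_basis")) stop("file does not contain a field basis")
  b
}
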