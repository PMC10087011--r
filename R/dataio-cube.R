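#' Cache a cube to HDF5 and read it back
#'
#' \code{writeCube()} stores an \linkS4class{MSICube} or \linkS4class{HFCube}
#' in a single HDF5 container (grid geometry, channel axis, data matrix,
#' foreground mask, provenance as a JSON string); \code{readCube()} inverts it
#' exactly. The cube is validated before anything is written.
#'
#' @param cube an \linkS4class{MSICube} or \linkS4class{HFCube}
#' @param path path of the HDF5 file to create (overwritten if present)
#' @return \code{writeCube()}: invisibly, \code{path}; \code{readCube()}: the
#'   reconstructed cube.
#' @examples
#' cube <- MSICube(matrix(1:8, 2), mz = c(100, 200), grid_shape = c(2, 2),
#'                 pixel_size_um = 100)
#' f <- file.path(tempdir(), "cube.h5")
#' writeCube(cube, f)
#' identical(mzAxis(readCube(f)), mzAxis(cube))
#' @export
writeCube <- function(cube, path) {
  if (!seLike(cube)) stop("cube must be an MSICube or HFCube", call. = FALSE)
  validObject(cube)  # rejects NaN/negative values before any write
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll())
  md <- metadata(cube)
  rhdf5::h5write(class(cube), path, "class")
  rhdf5::h5write(as.integer(md$grid_shape), path, "grid_shape")
  rhdf5::h5write(assay(cube), path, "data")
  rhdf5::h5write(as.integer(colData(cube)$foreground), path, "foreground")
  if (is(cube, "MSICube")) {
    rhdf5::h5write(mzAxis(cube), path, "mz")
    rhdf5::h5write(as.numeric(md$pixel_size_um), path, "pixel_size_um")
    rhdf5::h5write(as.character(jsonlite::toJSON(md$meta, auto_unbox = TRUE)),
                   path, "meta_json")
  } else {
    rhdf5::h5write(as.integer(md$tile_size_px), path, "tile_size_px")
    rhdf5::h5write(as.character(jsonlite::toJSON(md$provenance,
                                                 auto_unbox = TRUE)),
                   path, "provenance_json")
  }
  invisible(path)
}

#' @rdname writeCube
#' @export
readCube <- function(path) {
  if (!file.exists(path)) stop("no such cube file: ", path, call. = FALSE)
  on.exit(rhdf5::h5closeAll())
  cls <- as.character(rhdf5::h5read(path, "class"))
  gs <- as.integer(rhdf5::h5read(path, "grid_shape"))
  dat <- rhdf5::h5read(path, "data")
  fg <- as.logical(rhdf5::h5read(path, "foreground"))
  if (cls == "MSICube") {
    MSICube(dat, mz = as.numeric(rhdf5::h5read(path, "mz")),
            grid_shape = gs,
            pixel_size_um = as.numeric(rhdf5::h5read(path, "pixel_size_um")),
            foreground = fg,
            meta = jsonlite::fromJSON(as.character(
              rhdf5::h5read(path, "meta_json"))))
  } else {
    HFCube(dat, grid_shape = gs,
           tile_size_px = as.integer(rhdf5::h5read(path, "tile_size_px")),
           foreground = fg,
           provenance = jsonlite::fromJSON(as.character(
             rhdf5::h5read(path, "provenance_json"))))
  }
}
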