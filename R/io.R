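#' @include AllClasses.R
NULL

#' Read a patch network table
#'
#' Reads a patch table (CSV with header columns \code{patch_id}, \code{x_km},
#' \code{y_km}, \code{length_km}) and optionally an explicit square distance
#' matrix (CSV whose first column and header are patch ids). When no
#' distance matrix is supplied, pairwise Euclidean distances are computed
#' from the coordinates. Patch order is preserved from the file.
#'
#' @param path patch table CSV path.
#' @param distancePath optional CSV path of a square distance matrix (km)
#'   keyed by patch id.
#' @return a [PatchNetwork-class].
#' @seealso [writePatchTable()]
#' @export
readPatchTable <- function(path, distancePath = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patch_id", "x_km", "y_km", "length_km")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("patch table is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$patch_id))
    stop("duplicate patch ids in ", path)
  if (any(!is.finite(tab$length_km)) || any(tab$length_km <= 0))
    stop("patch lengths must be finite and strictly positive")
  dist <- NULL
  if (!is.null(distancePath)) {
    dm <- utils::read.csv(distancePath, row.names = 1L, check.names = FALSE)
    dm <- as.matrix(dm)
    if (nrow(dm) != ncol(dm))
      stop("distance matrix must be square")
    ids <- as.character(tab$patch_id)
    if (!setequal(rownames(dm), ids) || !setequal(colnames(dm), ids))
      stop("distance matrix ids do not match the patch table")
    dm <- dm[ids, ids]
    if (max(abs(dm - t(dm))) > 1e-9)
      stop("distance matrix must be symmetric")
    dist <- dm
  }
  PatchNetwork(tab$patch_id, tab$x_km, tab$y_km, tab$length_km, dist = dist)
}

#' Write a patch network table
#'
#' Writes the module's standard patch CSV (\code{patch_id,x_km,y_km,length_km});
#' optionally the distance matrix as a square CSV keyed by patch id.
#'
#' @param network a [PatchNetwork-class].
#' @param path output CSV path.
#' @param distancePath optional path for the distance matrix CSV.
#' @return invisibly, \code{path}.
#' @export
writePatchTable <- function(network, path, distancePath = NULL) {
  tab <- data.frame(
    patch_id = patchIds(network),
    x_km = network@coords[, "x"],
    y_km = network@coords[, "y"],
    length_km = network@length
  )
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  if (!is.null(distancePath)) {
    dm <- as.data.frame(network@dist)
    utils::write.csv(cbind(patch_id = patchIds(network), dm), distancePath,
                     row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a long-format detection history
#'
#' Reads a long-format CSV with columns \code{patch_id}, \code{year},
#' \code{visit}, \code{detected} (0/1/NA) into the dense patch x year x
#' visit array. Cells with no record are missing (the visit did not take
#' place); years are sorted ascending and must form a gap-free unit-step
#' sequence, because the occupancy process is modelled on a unit time step.
#'
#' @param path detections CSV path.
#' @param network the [PatchNetwork-class] the records refer to; every
#'   \code{patch_id} must exist in it. Patches without records are retained
#'   as fully unsurveyed.
#' @return a [DetectionHistory-class].
#' @seealso [writeDetectionHistory()]
#' @export
readDetectionHistory <- function(path, network) {
  stopifnot(is(network, "PatchNetwork"))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patch_id", "year", "visit", "detected")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("detection table is missing column(s): ", paste(miss, collapse = ", "))
  tab$patch_id <- as.character(tab$patch_id)
  unknown <- setdiff(tab$patch_id, patchIds(network))
  if (length(unknown))
    stop("unknown patch id(s): ", paste(utils::head(unknown, 5L), collapse = ", "))
  bad <- !is.na(tab$detected) & !(tab$detected %in% c(0L, 1L))
  if (any(bad))
    stop("detected must be 0, 1 or NA")
  if (anyDuplicated(tab[c("patch_id", "year", "visit")]))
    stop("duplicate (patch, year, visit) rows")
  tab <- tab[!is.na(tab$detected), , drop = FALSE]
  years <- sort(unique(as.integer(tab$year)))
  if (length(years) > 1L && any(diff(years) != 1L))
    stop("year sequence has gaps; the model assumes a unit time step")
  vmax <- max(1L, as.integer(tab$visit))
  ids <- patchIds(network)
  y <- array(NA_integer_, dim = c(length(ids), length(years), vmax))
  if (nrow(tab)) {
    idx <- cbind(match(tab$patch_id, ids),
                 match(as.integer(tab$year), years),
                 as.integer(tab$visit))
    y[idx] <- as.integer(tab$detected)
  }
  DetectionHistory(y, years, ids)
}

#' Write a detection history in long format
#'
#' One row per realised (non-missing) visit, columns
#' \code{patch_id,year,visit,detected}; round-trips losslessly through
#' [readDetectionHistory()].
#'
#' @param history a [DetectionHistory-class].
#' @param path output CSV path.
#' @return invisibly, \code{path}.
#' @export
writeDetectionHistory <- function(history, path) {
  y <- detectionArray(history)
  idx <- which(!is.na(y), arr.ind = TRUE)
  tab <- data.frame(
    patch_id = patchIds(history)[idx[, 1L]],
    year = yearLabels(history)[idx[, 2L]],
    visit = idx[, 3L],
    detected = y[idx]
  )
  tab <- tab[order(tab$patch_id, tab$year, tab$visit), , drop = FALSE]
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a matrix as an ESRI ASCII grid
#'
#' Plain-text raster format: a six-line header (\code{ncols}, \code{nrows},
#' \code{xllcorner}, \code{yllcorner}, \code{cellsize}, \code{NODATA_value})
#' followed by rows of values, top row first (northernmost). \code{NA}
#' entries are written as the NODATA value.
#'
#' @param grid numeric matrix; row 1 is the top (maximum y) row.
#' @param origin numeric (x, y) of the lower-left corner, km.
#' @param cellsize cell edge length, km (> 0).
#' @param path output file path.
#' @param nodata value used for missing cells (default -9999).
#' @return invisibly, \code{path}.
#' @seealso [readRasterAscii()]
#' @export
writeRasterAscii <- function(grid, origin, cellsize, path, nodata = -9999) {
  grid <- as.matrix(grid)
  if (length(grid) == 0L) stop("empty raster")
  if (cellsize <= 0) stop("cellsize must be > 0")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(grid)),
    paste("nrows", nrow(grid)),
    paste("xllcorner", format(origin[1L], digits = 15)),
    paste("yllcorner", format(origin[2L], digits = 15)),
    paste("cellsize", format(cellsize, digits = 15)),
    paste("NODATA_value", nodata)
  ), con)
  g <- grid
  g[is.na(g)] <- nodata
  utils::write.table(format(g, digits = 15, trim = TRUE, scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path ASCII grid path written by [writeRasterAscii()] or any
#'   conforming writer.
#' @return list with \code{grid} (matrix, top row first), \code{origin}
#'   (xll, yll), \code{cellsize}, \code{nodata}.
#' @export
readRasterAscii <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- strsplit(trimws(hdr), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(vapply(kv, `[`, "", 2L))
  names(vals) <- keys
  g <- as.matrix(utils::read.table(path, skip = 6L))
  dimnames(g) <- NULL
  if (nrow(g) != vals[["nrows"]] || ncol(g) != vals[["ncols"]])
    stop("grid body does not match header dimensions")
  g[g == vals[["nodata_value"]]] <- NA_real_
  list(grid = g,
       origin = c(vals[["xllcorner"]], vals[["yllcorner"]]),
       cellsize = vals[["cellsize"]],
       nodata = vals[["nodata_value"]])
}

#' Write posterior draws to CSV
#'
#' One row per saved iteration with a leading \code{chain} column; latent
#' occupancy draws, when saved, go to a separate long-format CSV
#' (\code{draw,patch,year,z}).
#'
#' @param samples a [PosteriorSamples-class].
#' @param path output CSV for scalar draws.
#' @param zPath optional output CSV for latent-state draws.
#' @return invisibly, \code{path}.
#' @export
writePosterior <- function(samples, path, zPath = NULL) {
  tab <- data.frame(chain = samples@chain, samples@draws,
                    check.names = FALSE)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  if (!is.null(zPath)) {
    z <- latentStateDraws(samples)
    idx <- which(!is.na(z), arr.ind = TRUE)
    tab <- data.frame(draw = idx[, 1L], patch = idx[, 2L],
                      year = idx[, 3L], z = z[idx])
    utils::write.csv(tab, zPath, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read posterior draws written by [writePosterior()]
#'
#' @param path CSV of scalar draws.
#' @return a matrix of draws with a \code{chain} attribute.
#' @export
readPosterior <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  chain <- as.integer(tab$chain)
  m <- as.matrix(tab[setdiff(names(tab), "chain")])
  attr(m, "chain") <- chain
  m
}
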