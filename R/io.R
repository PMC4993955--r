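#' Write a ShapeModel to a JSON file
#'
#' Numeric arrays are written at full precision so a read/write round trip
#' leaves scores stable to better than 1e-10.
#'
#' @param model A [ShapeModel-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeShapeModel <- function(model, path) {
  stopifnot(is(model, "ShapeModel"))
  obj <- list(
    format = "tkrshape.ShapeModel", version = 1L,
    bone = model@bone,
    n_points = nPoints(model),
    n_components = ncol(model@basis),
    variance_fraction = model@varianceFraction,
    n_train_oa = model@nTrainOA,
    n_train_non_oa = model@nTrainNonOA,
    mean_shape = as.vector(t(model@meanShape)),
    basis = as.vector(model@basis),  # column-major
    eigenvalues = model@eigenvalues,
    m_non_oa = model@mNonOA,
    m_oa = model@mOA)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a ShapeModel written by [writeShapeModel()]
#'
#' @param path JSON file path.
#' @return A [ShapeModel-class].
#' @export
readShapeModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "tkrshape.ShapeModel"))
    stop("not a tkrshape ShapeModel file: ", path)
  np <- obj$n_points; M <- obj$n_components
  new("ShapeModel", bone = obj$bone,
      meanShape = unflattenShape(obj$mean_shape),
      basis = matrix(obj$basis, nrow = 3L * np, ncol = M),
      eigenvalues = obj$eigenvalues,
      mNonOA = obj$m_non_oa, mOA = obj$m_oa,
      nTrainOA = as.integer(obj$n_train_oa),
      nTrainNonOA = as.integer(obj$n_train_non_oa),
      varianceFraction = obj$variance_fraction)
}

#' Read/write point clouds as x,y,z CSV
#'
#' Row order encodes point correspondence, so it must be preserved across
#' samples of the same bone.
#'
#' @param path CSV file with columns `x`, `y`, `z`.
#' @return `readXyzCsv`: an `n x 3` matrix.
#' @export
readXyzCsv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("x", "y", "z") %in% names(df)))
  as.matrix(df[, c("x", "y", "z")])
}

#' @rdname readXyzCsv
#' @param points `n x 3` matrix.
#' @export
writeXyzCsv <- function(points, path) {
  stopifnot(is.matrix(points), ncol(points) == 3L)
  utils::write.csv(data.frame(x = points[, 1], y = points[, 2], z = points[, 3]),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a PLY file (ascii or binary little-endian)
#'
#' Supports the common layout produced by mesh tools: a `vertex` element with
#' `float`/`double` properties `x`, `y`, `z` (extra scalar properties are
#' skipped) and an optional `face` element with a
#' `list uchar int vertex_indices` property.
#'
#' @param path PLY file path.
#' @return A list with `vertices` (`n x 3` matrix) and `faces`
#'   (`m x 3` integer matrix of 1-based indices, or `NULL`).
#' @export
readPly <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readHeaderLine <- function() {
    chars <- raw()
    repeat {
      b <- readBin(con, "raw", 1L)
      if (length(b) == 0L) stop("unexpected end of PLY header")
      if (b == as.raw(10L)) break
      chars <- c(chars, b)
    }
    sub("\r$", "", rawToChar(chars))
  }
  if (readHeaderLine() != "ply") stop("not a PLY file: ", path)
  fmt <- NULL; elements <- list(); cur <- NULL
  typeSize <- c(char = 1, uchar = 1, int8 = 1, uint8 = 1, short = 2, ushort = 2,
                int16 = 2, uint16 = 2, int = 4, uint = 4, int32 = 4, uint32 = 4,
                float = 4, float32 = 4, double = 8, float64 = 8)
  repeat {
    ln <- readHeaderLine()
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (!length(tok) || tok[1] == "comment") next
    if (tok[1] == "format") fmt <- tok[2]
    else if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      stopifnot(!is.null(cur))
      if (tok[2] == "list") {
        cur$props[[tok[5]]] <- list(list = TRUE, countType = tok[3], type = tok[4])
      } else {
        cur$props[[tok[3]]] <- list(list = FALSE, type = tok[2])
      }
    } else if (tok[1] == "end_header") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      break
    }
  }
  if (is.null(fmt)) stop("PLY header has no format line")
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop("unsupported PLY format: ", fmt)

  readScalarBin <- function(type, n = 1L) {
    sz <- typeSize[[type]]
    what <- if (type %in% c("float", "float32", "double", "float64")) "double" else "integer"
    signed <- !type %in% c("uchar", "uint8", "ushort", "uint16", "uint", "uint32")
    readBin(con, what, n = n, size = sz, endian = "little", signed = signed)
  }
  vertices <- NULL; faces <- NULL
  if (fmt == "ascii") {
    rest <- readLines(con)
    rest <- rest[nzchar(trimws(rest))]
    pos <- 0L
    for (el in elements) {
      lines <- rest[pos + seq_len(el$count)]
      pos <- pos + el$count
      if (el$name == "vertex") {
        pn <- names(el$props)
        vals <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
        vertices <- vals[, match(c("x", "y", "z"), pn), drop = FALSE]
      } else if (el$name == "face") {
        faces <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), function(v) {
          v <- as.integer(v)
          if (v[1] != 3L) stop("only triangular faces supported")
          v[2:4] + 1L
        }))
      }
    }
  } else {
    for (el in elements) {
      if (el$name == "vertex") {
        simple <- !vapply(el$props, `[[`, logical(1), "list")
        stopifnot(all(simple))
        pn <- names(el$props)
        types <- vapply(el$props, `[[`, character(1), "type")
        vals <- matrix(NA_real_, el$count, length(pn))
        if (length(unique(types)) == 1L) {
          block <- readScalarBin(types[1], el$count * length(pn))
          vals[] <- matrix(block, ncol = length(pn), byrow = TRUE)
        } else {
          for (i in seq_len(el$count))
            for (j in seq_along(pn)) vals[i, j] <- readScalarBin(types[j])
        }
        vertices <- vals[, match(c("x", "y", "z"), pn), drop = FALSE]
      } else if (el$name == "face") {
        p <- el$props[[1]]
        faces <- matrix(NA_integer_, el$count, 3L)
        for (i in seq_len(el$count)) {
          k <- readScalarBin(p$countType)
          if (k != 3L) stop("only triangular faces supported")
          faces[i, ] <- readScalarBin(p$type, 3L) + 1L
        }
      } else {
        stop("unsupported PLY element: ", el$name)
      }
    }
  }
  if (is.null(vertices)) stop("PLY file has no vertex element")
  list(vertices = vertices, faces = faces)
}

#' Write an ascii PLY file
#'
#' @param vertices `n x 3` matrix.
#' @param path Output path.
#' @param faces Optional `m x 3` integer matrix of 1-based triangle indices.
#' @return `path`, invisibly.
#' @export
writePly <- function(vertices, path, faces = NULL) {
  stopifnot(is.matrix(vertices), ncol(vertices) == 3L)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nrow(vertices)),
           "property double x", "property double y", "property double z")
  if (!is.null(faces)) {
    hdr <- c(hdr, sprintf("element face %d", nrow(faces)),
             "property list uchar int vertex_indices")
  }
  hdr <- c(hdr, "end_header")
  writeLines(hdr, con)
  writeLines(sprintf("%.17g %.17g %.17g",
                     vertices[, 1], vertices[, 2], vertices[, 3]), con)
  if (!is.null(faces)) {
    writeLines(sprintf("3 %d %d %d",
                       faces[, 1] - 1L, faces[, 2] - 1L, faces[, 3] - 1L), con)
  }
  invisible(path)
}
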