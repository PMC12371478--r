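# Readers and writers: FreeSurfer binary triangle geometry, GIFTI surfaces
# and functional maps, single-column CSV maps.

FS_TRIANGLE_MAGIC <- as.raw(c(0xff, 0xff, 0xfe))

#' Read a FreeSurfer binary triangle-geometry file
#'
#' Parses the classic FreeSurfer surface format (magic bytes `ff ff fe`,
#' a newline-terminated creation comment, big-endian counts, float32
#' coordinates and int32 0-based triangle indices). Only the triangle dialect
#' is supported; the quad dialect is rejected at the magic number.
#'
#' @param path path to the geometry file (e.g. `lh.sphere`, `lh.pial`).
#' @return a [surface_mesh()] with coordinates in the file's native mm units.
#' @export
read_freesurfer_geometry <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readBin(path, what = "raw", n = file.size(path))
  if (length(raw) < 3L || !identical(raw[1:3], FS_TRIANGLE_MAGIC)) {
    stop("not a FreeSurfer triangle-geometry file: bad magic number at byte offset 0",
         call. = FALSE)
  }
  # creation comment: terminated by "\n\n" (some writers emit a single "\n")
  nl <- which(raw == as.raw(0x0a))
  nl <- nl[nl > 3L]
  if (length(nl) == 0L) {
    stop("truncated FreeSurfer file: unterminated comment at byte offset ",
         length(raw), call. = FALSE)
  }
  pos <- nl[1L]
  if (pos < length(raw) && raw[pos + 1L] == as.raw(0x0a)) pos <- pos + 1L
  con <- rawConnection(raw[(pos + 1L):length(raw)])
  on.exit(close(con))
  counts <- readBin(con, what = "integer", n = 2L, size = 4L, endian = "big")
  if (length(counts) < 2L || any(counts < 0L)) {
    stop("truncated FreeSurfer file: missing counts at byte offset ", pos,
         call. = FALSE)
  }
  nv <- counts[1L]; nf <- counts[2L]
  coords <- readBin(con, what = "numeric", n = 3L * nv, size = 4L, endian = "big")
  if (length(coords) < 3L * nv) {
    stop("truncated FreeSurfer file: expected ", 3L * nv,
         " floats at byte offset ", pos + 8L, call. = FALSE)
  }
  tris <- readBin(con, what = "integer", n = 3L * nf, size = 4L, endian = "big")
  if (length(tris) < 3L * nf) {
    stop("truncated FreeSurfer file: expected ", 3L * nf,
         " triangle indices at byte offset ", pos + 8L + 12L * nv, call. = FALSE)
  }
  surface_mesh(matrix(coords, ncol = 3L, byrow = TRUE),
               matrix(tris, ncol = 3L, byrow = TRUE) + 1L,
               check_connected = FALSE)
}

#' Write a mesh in FreeSurfer binary triangle-geometry format
#'
#' @param mesh a [surface_mesh()].
#' @param path output path.
#' @param comment creation comment embedded in the header.
#' @return `path`, invisibly.
#' @export
write_freesurfer_geometry <- function(mesh, path,
                                      comment = "created by spinbench") {
  stopifnot(inherits(mesh, "surface_mesh"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(FS_TRIANGLE_MAGIC, con)
  writeBin(c(charToRaw(comment), as.raw(c(0x0a, 0x0a))), con)
  writeBin(as.integer(n_vertices(mesh)), con, size = 4L, endian = "big")
  writeBin(as.integer(nrow(mesh$triangles)), con, size = 4L, endian = "big")
  writeBin(as.numeric(t(mesh$coordinates)), con, size = 4L, endian = "big")
  writeBin(as.integer(t(mesh$triangles) - 1L), con, size = 4L, endian = "big")
  invisible(path)
}

# --- GIFTI ------------------------------------------------------------------

gifti_data_arrays <- function(path) {
  doc <- xml2::read_xml(path)
  # local-name() sidesteps the optional GIFTI namespace
  xml2::xml_find_all(doc, "//*[local-name() = 'DataArray']")
}

gifti_node_data <- function(node) {
  # xml_find_first with d1: prefix fails on non-namespaced docs; handle both
  data_node <- xml2::xml_find_first(node, ".//*[local-name() = 'Data']")
  enc <- xml2::xml_attr(node, "Encoding")
  txt <- xml2::xml_text(data_node)
  decode_gifti_values(txt, enc,
                      xml2::xml_attr(node, "DataType"),
                      tolower(xml2::xml_attr(node, "Endian")),
                      as.integer(xml2::xml_attr(node, "Dim0")),
                      as.integer(xml2::xml_attr(node, "Dim1")),
                      xml2::xml_attr(node, "ArrayIndexingOrder"))
}

decode_gifti_values <- function(txt, enc, dtype, endian, dim0, dim1, order) {
  if (is.na(endian) || !nzchar(endian)) endian <- "little"
  endian <- if (startsWith(endian, "big")) "big" else "little"
  what <- switch(dtype,
    "NIFTI_TYPE_FLOAT32" = list(type = "numeric", size = 4L),
    "NIFTI_TYPE_FLOAT64" = list(type = "numeric", size = 8L),
    "NIFTI_TYPE_INT32" = list(type = "integer", size = 4L),
    stop("unsupported GIFTI DataType: ", dtype, call. = FALSE)
  )
  dims <- c(dim0, dim1)
  dims <- dims[!is.na(dims)]
  n <- prod(dims)
  vals <- switch(enc,
    "ASCII" = as.numeric(scan(text = txt, quiet = TRUE)),
    "Base64Binary" = readBin(jsonlite::base64_dec(gsub("\\s", "", txt)),
                             what$type, n = n, size = what$size, endian = endian),
    "GZipBase64Binary" = readBin(
      memDecompress(jsonlite::base64_dec(gsub("\\s", "", txt)), type = "gzip"),
      what$type, n = n, size = what$size, endian = endian),
    stop("unsupported GIFTI Encoding: ", enc, call. = FALSE)
  )
  if (length(vals) != n) {
    stop("GIFTI data array has ", length(vals), " values, expected ", n,
         call. = FALSE)
  }
  if (length(dims) == 2L) {
    if (!is.na(order) && order == "ColumnMajorOrder") {
      matrix(vals, nrow = dims[1L], ncol = dims[2L])
    } else {
      matrix(vals, nrow = dims[1L], ncol = dims[2L], byrow = TRUE)
    }
  } else {
    vals
  }
}

#' Read a GIFTI surface file (`.surf.gii`)
#'
#' Supports ASCII, Base64Binary and GZipBase64Binary encodings.
#'
#' @param path path to the `.surf.gii` file.
#' @return a [surface_mesh()].
#' @export
read_surface_gifti <- function(path) {
  nodes <- gifti_data_arrays(path)
  intents <- vapply(nodes, function(n) xml2::xml_attr(n, "Intent"), character(1))
  ip <- which(intents == "NIFTI_INTENT_POINTSET")
  it <- which(intents == "NIFTI_INTENT_TRIANGLE")
  if (length(ip) == 0L || length(it) == 0L) {
    stop("GIFTI surface needs POINTSET and TRIANGLE data arrays; found intents: ",
         paste(intents, collapse = ", "), call. = FALSE)
  }
  coords <- gifti_node_data(nodes[[ip[1L]]])
  tris <- gifti_node_data(nodes[[it[1L]]])
  surface_mesh(coords, tris + 1L, check_connected = FALSE)
}

#' Write a GIFTI surface file (`.surf.gii`)
#'
#' Emits ASCII-encoded data arrays (POINTSET in float32 semantics, TRIANGLE
#' 0-based int32).
#'
#' @param mesh a [surface_mesh()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_surface_gifti <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  coord_txt <- paste(apply(mesh$coordinates, 1L, paste, collapse = " "),
                     collapse = "\n")
  tri_txt <- paste(apply(mesh$triangles - 1L, 1L, paste, collapse = " "),
                   collapse = "\n")
  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<GIFTI Version="1.0" NumberOfDataArrays="2">\n',
    gifti_array_xml("NIFTI_INTENT_POINTSET", "NIFTI_TYPE_FLOAT32",
                    n_vertices(mesh), 3L, coord_txt),
    gifti_array_xml("NIFTI_INTENT_TRIANGLE", "NIFTI_TYPE_INT32",
                    nrow(mesh$triangles), 3L, tri_txt),
    "</GIFTI>\n"
  )
  writeLines(xml, path, sep = "")
  invisible(path)
}

gifti_array_xml <- function(intent, dtype, dim0, dim1, data_txt) {
  dim_attr <- if (is.na(dim1)) {
    sprintf('Dimensionality="1" Dim0="%d"', dim0)
  } else {
    sprintf('Dimensionality="2" Dim0="%d" Dim1="%d"', dim0, dim1)
  }
  paste0(
    sprintf('<DataArray Intent="%s" DataType="%s" ArrayIndexingOrder="RowMajorOrder" %s Encoding="ASCII" Endian="LittleEndian" ExternalFileName="" ExternalFileOffset="">\n',
            intent, dtype, dim_attr),
    "<Data>", data_txt, "</Data>\n</DataArray>\n"
  )
}

#' Read a per-vertex scalar map from a GIFTI functional file (`.func.gii`)
#'
#' @param path path to the `.func.gii` file.
#' @return a numeric vector (single data array) or a matrix with one column
#'   per data array.
#' @export
read_map_gifti <- function(path) {
  nodes <- gifti_data_arrays(path)
  if (length(nodes) == 0L) stop("no data arrays in GIFTI file", call. = FALSE)
  vals <- lapply(nodes, gifti_node_data)
  if (length(vals) == 1L) drop(vals[[1L]]) else do.call(cbind, lapply(vals, drop))
}

#' Write a per-vertex scalar map as a GIFTI functional file
#'
#' @param values numeric per-vertex vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_map_gifti <- function(values, path) {
  values <- as.numeric(values)
  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<GIFTI Version="1.0" NumberOfDataArrays="1">\n',
    gifti_array_xml("NIFTI_INTENT_NONE", "NIFTI_TYPE_FLOAT64",
                    length(values), NA_integer_,
                    paste(format(values, digits = 17), collapse = " ")),
    "</GIFTI>\n"
  )
  writeLines(xml, path, sep = "")
  invisible(path)
}

#' Read a per-vertex scalar map from a single-column CSV
#'
#' The file must carry the header `value`.
#'
#' @param path path to the CSV file.
#' @return numeric vector of per-vertex values.
#' @export
read_map_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!"value" %in% names(df)) {
    stop("map CSV must have a `value` column; found: ",
         paste(names(df), collapse = ", "), call. = FALSE)
  }
  as.numeric(df$value)
}

#' Write a per-vertex scalar map to a single-column CSV
#'
#' @param values numeric per-vertex vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_map_csv <- function(values, path) {
  utils::write.csv(data.frame(value = as.numeric(values)), path,
                   row.names = FALSE)
  invisible(path)
}
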