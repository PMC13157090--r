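#' Read a colored point cloud from a PLY file
#'
#' Supports the two PLY dialects that multi-view-stereo tools emit: ASCII
#' and binary little-endian. The vertex element must carry `x`, `y`, `z`;
#' color properties (`red`/`green`/`blue` or `r`/`g`/`b`, `uchar` or float)
#' are optional — missing colors are filled with mid-gray (0.5, 0.5, 0.5)
#' and a warning is raised. 8-bit colors are rescaled to `[0, 1]`. Face
#' elements are ignored (the package works on point sets). Rows with
#' non-finite coordinates are dropped with a message.
#'
#' @param path path to a `.ply` file.
#' @return A [colored_point_cloud] with `units = "reconstruction"`, unless
#'   the file carries a `comment units mm` header line, in which case
#'   `units = "mm"`.
#' @seealso [write_ply()]
#' @export
read_ply <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- ply_read_header(con)
  vert <- hdr$elements[["vertex"]]
  if (is.null(vert)) {
    stop("PLY format error in ", path, ": no 'vertex' element", call. = FALSE)
  }
  pnames <- vert$prop_names
  need <- c("x", "y", "z")
  if (!all(need %in% pnames)) {
    stop("PLY format error in ", path, ": vertex element is missing property '",
         setdiff(need, pnames)[1], "'", call. = FALSE)
  }
  cnames <- if (all(c("red", "green", "blue") %in% pnames)) {
    c("red", "green", "blue")
  } else if (all(c("r", "g", "b") %in% pnames)) {
    c("r", "g", "b")
  } else NULL

  first <- names(hdr$elements)[1]
  if (hdr$format == "ascii") {
    tab <- ply_read_ascii_element(con, hdr, "vertex")
  } else {
    if (first != "vertex") {
      ply_skip_binary_until(con, hdr, "vertex")
    }
    tab <- ply_read_binary_element(con, vert)
  }
  pts <- cbind(tab[["x"]], tab[["y"]], tab[["z"]])
  if (is.null(cnames)) {
    warning("PLY file has no color properties; filling colors with mid-gray",
            call. = FALSE)
    cols <- NULL
  } else {
    cols <- cbind(tab[[cnames[1]]], tab[[cnames[2]]], tab[[cnames[3]]])
    ctypes <- vert$prop_types[match(cnames, pnames)]
    # uchar (or any integer-coded) colors arrive as 0..255
    if (any(ctypes %in% c("uchar", "uint8", "char", "int8", "ushort",
                          "uint16", "short", "int16", "int", "int32",
                          "uint", "uint32")) ||
        (nrow(cols) > 0L && max(cols, na.rm = TRUE) > 1 + 1e-9)) {
      cols <- cols / 255
    }
    cols[!is.finite(cols)] <- 0.5
    cols[cols < 0] <- 0
    cols[cols > 1] <- 1
  }
  colored_point_cloud(pts, cols, units = hdr$units)
}

#' Write a colored point cloud to a PLY file
#'
#' @param cloud a [colored_point_cloud].
#' @param path output path.
#' @param binary write binary little-endian (`TRUE`, default) or ASCII.
#' @param precision `"float"` (standard 32-bit coordinates) or `"double"`.
#'   Colors are always written as 8-bit `uchar`.
#' @return `path`, invisibly.
#' @export
write_ply <- function(cloud, path, binary = TRUE,
                      precision = c("float", "double")) {
  stopifnot(inherits(cloud, "colored_point_cloud"))
  precision <- match.arg(precision)
  n <- n_points(cloud)
  ctype <- if (precision == "float") "float" else "double"
  header <- c(
    "ply",
    paste("format", if (binary) "binary_little_endian" else "ascii", "1.0"),
    "comment written by ringcal",
    if (cloud$units == "mm") "comment units mm",
    paste("element vertex", n),
    paste("property", ctype, c("x", "y", "z")),
    paste("property uchar", c("red", "green", "blue")),
    "end_header")
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot write ", path, call. = FALSE))
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  col8 <- round(cloud$colors * 255)
  col8[col8 < 0] <- 0
  col8[col8 > 255] <- 255
  if (n == 0L) return(invisible(path))
  if (binary) {
    csize <- if (precision == "float") 4L else 8L
    coord_raw <- writeBin(as.numeric(t(cloud$points)), raw(),
                          size = csize, endian = "little")
    dim(coord_raw) <- c(3L * csize, n)
    col_raw <- as.raw(t(col8))
    dim(col_raw) <- c(3L, n)
    writeBin(as.vector(rbind(coord_raw, col_raw)), con)
  } else {
    lines <- paste(format(cloud$points[, 1], digits = 17, scientific = TRUE,
                          trim = TRUE),
                   format(cloud$points[, 2], digits = 17, scientific = TRUE,
                          trim = TRUE),
                   format(cloud$points[, 3], digits = 17, scientific = TRUE,
                          trim = TRUE),
                   as.integer(col8[, 1]), as.integer(col8[, 2]),
                   as.integer(col8[, 3]))
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

# ---- internals -------------------------------------------------------------

ply_type_size <- c(char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
                   short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
                   int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

ply_read_header <- function(con) {
  magic <- readLines(con, n = 1L)
  if (!identical(trimws(magic), "ply")) {
    stop("not a PLY file (missing 'ply' magic line)", call. = FALSE)
  }
  format <- NULL
  units <- "reconstruction"
  elements <- list()
  cur <- NULL
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("PLY header truncated", call. = FALSE)
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 0L) next
    switch(tok[1],
      comment = {
        if (length(tok) >= 3L && tok[2] == "units" && tok[3] == "mm") {
          units <- "mm"
        }
      },
      format = {
        format <- switch(tok[2],
          ascii = "ascii",
          binary_little_endian = "binary_little_endian",
          stop("unsupported PLY format: ", tok[2], call. = FALSE))
      },
      element = {
        cur <- tok[2]
        elements[[cur]] <- list(count = as.integer(tok[3]),
                                prop_names = character(),
                                prop_types = character(),
                                has_list = FALSE)
      },
      property = {
        if (is.null(cur)) stop("PLY property before element", call. = FALSE)
        if (tok[2] == "list") {
          elements[[cur]]$has_list <- TRUE
          elements[[cur]]$prop_names <- c(elements[[cur]]$prop_names,
                                          tok[length(tok)])
          elements[[cur]]$prop_types <- c(elements[[cur]]$prop_types, "list")
        } else {
          elements[[cur]]$prop_names <- c(elements[[cur]]$prop_names, tok[3])
          elements[[cur]]$prop_types <- c(elements[[cur]]$prop_types, tok[2])
        }
      },
      end_header = break,
      obj_info = NULL,
      stop("unrecognized PLY header line: ", line, call. = FALSE))
  }
  if (is.null(format)) stop("PLY header has no format line", call. = FALSE)
  list(format = format, elements = elements, units = units)
}

ply_read_ascii_element <- function(con, hdr, name) {
  # skip elements preceding `name`, line-counted (list rows are 1 line each)
  for (el in names(hdr$elements)) {
    if (el == name) break
    readLines(con, n = hdr$elements[[el]]$count)
  }
  el <- hdr$elements[[name]]
  if (el$has_list) {
    stop("list properties on the vertex element are not supported",
         call. = FALSE)
  }
  n <- el$count
  p <- length(el$prop_names)
  vals <- scan(con, what = numeric(), n = n * p, quiet = TRUE)
  if (length(vals) != n * p) {
    stop("PLY format error: expected ", n * p, " vertex values, got ",
         length(vals), call. = FALSE)
  }
  m <- matrix(vals, nrow = n, ncol = p, byrow = TRUE)
  out <- lapply(seq_len(p), function(j) m[, j])
  names(out) <- el$prop_names
  out
}

ply_skip_binary_until <- function(con, hdr, name) {
  for (el in names(hdr$elements)) {
    if (el == name) return(invisible())
    e <- hdr$elements[[el]]
    if (e$has_list) {
      stop("cannot skip a binary element with list properties (element '",
           el, "' precedes 'vertex')", call. = FALSE)
    }
    sz <- sum(ply_type_size[e$prop_types])
    readBin(con, "raw", n = e$count * sz)
  }
}

ply_read_binary_element <- function(con, el) {
  if (el$has_list) {
    stop("list properties on the vertex element are not supported",
         call. = FALSE)
  }
  sizes <- ply_type_size[el$prop_types]
  if (anyNA(sizes)) {
    stop("unknown PLY property type: ",
         el$prop_types[is.na(sizes)][1], call. = FALSE)
  }
  rec <- sum(sizes)
  n <- el$count
  raw_all <- readBin(con, "raw", n = n * rec)
  if (length(raw_all) != n * rec) {
    stop("PLY binary payload truncated", call. = FALSE)
  }
  offs <- c(0L, cumsum(sizes))
  out <- vector("list", length(el$prop_names))
  names(out) <- el$prop_names
  if (n == 0L) {
    for (j in seq_along(out)) out[[j]] <- numeric(0)
    return(out)
  }
  base <- rep((seq_len(n) - 1L) * rec, each = 1L)
  for (j in seq_along(el$prop_names)) {
    ty <- el$prop_types[j]
    sz <- sizes[j]
    idx <- as.vector(outer(seq_len(sz), base + offs[j], "+"))
    bytes <- raw_all[idx]
    out[[j]] <- switch(ty,
      float = , float32 = readBin(bytes, "numeric", n = n, size = 4L,
                                  endian = "little"),
      double = , float64 = readBin(bytes, "numeric", n = n, size = 8L,
                                   endian = "little"),
      uchar = , uint8 = as.numeric(readBin(bytes, "integer", n = n, size = 1L,
                                           signed = FALSE, endian = "little")),
      char = , int8 = as.numeric(readBin(bytes, "integer", n = n, size = 1L,
                                         signed = TRUE, endian = "little")),
      ushort = , uint16 = as.numeric(readBin(bytes, "integer", n = n,
                                             size = 2L, signed = FALSE,
                                             endian = "little")),
      short = , int16 = as.numeric(readBin(bytes, "integer", n = n, size = 2L,
                                           signed = TRUE, endian = "little")),
      int = , int32 = , uint = , uint32 =
        as.numeric(readBin(bytes, "integer", n = n, size = 4L,
                           endian = "little")),
      stop("unknown PLY property type: ", ty, call. = FALSE))
  }
  out
}
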