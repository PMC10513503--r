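#' Read a triangulated surface mesh
#'
#' Reads PLY (ASCII), OFF, or STL (ASCII or binary) files into a
#' validated [tri_mesh()].  STL stores a triangle soup, so identical
#' vertex coordinates are merged on input.  File indices are 0-based as
#' the formats prescribe; in R they become 1-based.
#'
#' @param path file path.
#' @param format `"ply"`, `"off"` or `"stl"`; default inferred from the
#'   file extension.
#' @param name mesh label; defaults to the file name.
#' @return a [tri_mesh()].
#' @export
read_mesh <- function(path, format = NULL, name = NULL) {
  if (!file.exists(path)) stop("unreadable file: ", path)
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("ply", "off", "stl"))
  if (is.null(name)) name <- basename(path)
  out <- switch(format,
                ply = read_ply(path),
                off = read_off(path),
                stl = read_stl(path))
  tri_mesh(out$vertices, out$triangles, name = name)
}

#' Write a triangulated surface mesh
#'
#' @param mesh a [tri_mesh()].
#' @param path output file path.
#' @param format `"ply"`, `"off"` or `"stl"` (ASCII); default inferred
#'   from the extension.
#' @param binary write binary STL instead of ASCII (STL only).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL, binary = FALSE) {
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("ply", "off", "stl"))
  switch(format,
         ply = write_ply(mesh, path),
         off = write_off(mesh, path),
         stl = write_stl(mesh, path, binary = binary))
  invisible(path)
}

read_off <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- trimws(txt)
  txt <- txt[nzchar(txt) & !startsWith(txt, "#")]
  if (!identical(toupper(txt[1L]), "OFF")) stop("unreadable file: not OFF")
  counts <- scan(text = txt[2L], quiet = TRUE)
  nv <- counts[1L]; nf <- counts[2L]
  vals <- scan(text = txt[3:(2 + nv)], quiet = TRUE)
  vertices <- matrix(vals, ncol = 3L, byrow = TRUE)
  fvals <- lapply(txt[(3 + nv):(2 + nv + nf)], function(s)
    scan(text = s, quiet = TRUE))
  if (any(vapply(fvals, `[`, 0, 1L) != 3))
    stop("unreadable file: non-triangular face in OFF")
  triangles <- t(vapply(fvals, function(x) x[2:4], numeric(3L))) + 1L
  list(vertices = vertices, triangles = triangles)
}

write_off <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$triangles)), con)
  writeLines(apply(mesh$vertices, 1L, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = " ")), con)
  writeLines(apply(mesh$triangles - 1L, 1L, function(r)
    paste(c(3L, r), collapse = " ")), con)
}

read_ply <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (!identical(trimws(txt[1L]), "ply")) stop("unreadable file: not PLY")
  endh <- which(trimws(txt) == "end_header")[1L]
  if (is.na(endh)) stop("unreadable file: PLY header not terminated")
  header <- trimws(txt[seq_len(endh)])
  fmt <- grep("^format ", header, value = TRUE)
  if (!length(fmt) || !grepl("ascii", fmt[1L]))
    stop("unreadable file: only ASCII PLY is supported")
  el <- grep("^element ", header)
  get_count <- function(what) {
    ln <- grep(paste0("^element ", what, " "), header, value = TRUE)
    if (!length(ln)) stop("unreadable file: PLY lacks element ", what)
    as.integer(strsplit(ln[1L], "\\s+")[[1L]][3L])
  }
  nv <- get_count("vertex"); nf <- get_count("face")
  body <- trimws(txt[(endh + 1L):length(txt)])
  body <- body[nzchar(body)]
  vvals <- lapply(body[seq_len(nv)], function(s) scan(text = s, quiet = TRUE))
  vertices <- t(vapply(vvals, function(x) x[1:3], numeric(3L)))
  fvals <- lapply(body[nv + seq_len(nf)], function(s) scan(text = s, quiet = TRUE))
  if (any(vapply(fvals, `[`, 0, 1L) != 3))
    stop("unreadable file: non-triangular face in PLY")
  triangles <- t(vapply(fvals, function(x) x[2:4], numeric(3L))) + 1L
  list(vertices = vertices, triangles = triangles)
}

write_ply <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(mesh$triangles)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(apply(mesh$vertices, 1L, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = " ")), con)
  writeLines(apply(mesh$triangles - 1L, 1L, function(r)
    paste(c(3L, r), collapse = " ")), con)
}

read_stl <- function(path) {
  ## binary sniff: ASCII STL starts with "solid" and contains "facet"
  head_raw <- readBin(path, "raw", n = 512L)
  head_txt <- rawToChar(head_raw[head_raw != as.raw(0L)])
  is_ascii <- grepl("^\\s*solid", head_txt, useBytes = TRUE) &&
    grepl("facet", head_txt, useBytes = TRUE)
  tri_soup <- if (is_ascii) read_stl_ascii(path) else read_stl_binary(path)
  weld_triangle_soup(tri_soup)
}

read_stl_ascii <- function(path) {
  txt <- trimws(readLines(path, warn = FALSE))
  vlines <- grep("^vertex\\s", txt, value = TRUE)
  if (!length(vlines)) stop("unreadable file: no vertices in STL")
  vals <- vapply(strsplit(vlines, "\\s+"), function(x)
    as.numeric(x[2:4]), numeric(3L))
  soup <- t(vals)
  if (nrow(soup) %% 3L != 0L) stop("unreadable file: STL vertex count not a multiple of 3")
  soup
}

read_stl_binary <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  invisible(readBin(con, "raw", n = 80L))
  nf <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  soup <- matrix(NA_real_, nf * 3L, 3L)
  for (i in seq_len(nf)) {
    rec <- readBin(con, "numeric", n = 12L, size = 4L, endian = "little")
    soup[(3L * i - 2L):(3L * i), ] <- matrix(rec[4:12], 3L, 3L, byrow = TRUE)
    invisible(readBin(con, "raw", n = 2L))
  }
  soup
}

weld_triangle_soup <- function(soup) {
  key <- apply(soup, 1L, function(r) paste(formatC(r, digits = 12), collapse = "|"))
  uid <- match(key, unique(key))
  vertices <- soup[!duplicated(key), , drop = FALSE]
  triangles <- matrix(uid, ncol = 3L, byrow = TRUE)
  list(vertices = vertices, triangles = triangles)
}

write_stl <- function(mesh, path, binary = FALSE) {
  v <- mesh$vertices; tr <- mesh$triangles
  e1 <- v[tr[, 2L], , drop = FALSE] - v[tr[, 1L], , drop = FALSE]
  e2 <- v[tr[, 3L], , drop = FALSE] - v[tr[, 1L], , drop = FALSE]
  nrm <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
               e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
               e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  nrm <- nrm / sqrt(rowSums(nrm^2))
  if (binary) {
    con <- file(path, "wb"); on.exit(close(con))
    writeBin(as.raw(rep(0L, 80L)), con)
    writeBin(as.integer(nrow(tr)), con, size = 4L, endian = "little")
    for (i in seq_len(nrow(tr))) {
      rec <- c(nrm[i, ], t(v[tr[i, ], ]))
      writeBin(as.numeric(rec), con, size = 4L, endian = "little")
      writeBin(as.raw(c(0L, 0L)), con)
    }
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(sprintf("solid %s", mesh$name), con)
    for (i in seq_len(nrow(tr))) {
      writeLines(sprintf("  facet normal %.9g %.9g %.9g",
                         nrm[i, 1L], nrm[i, 2L], nrm[i, 3L]), con)
      writeLines("    outer loop", con)
      for (j in 1:3)
        writeLines(sprintf("      vertex %.17g %.17g %.17g",
                           v[tr[i, j], 1L], v[tr[i, j], 2L], v[tr[i, j], 3L]), con)
      writeLines(c("    endloop", "  endfacet"), con)
    }
    writeLines(sprintf("endsolid %s", mesh$name), con)
  }
  invisible(path)
}
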