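#' Read a point cloud from disk
#'
#' Supports whitespace XYZ text, PLY (ascii and binary little-endian), PCD
#' (ascii and binary) and LAS 1.x (point record formats 0-3). All coordinates
#' are interpreted as meters. Per-point ring / time / intensity fields are
#' preserved when the format carries them. Records with non-finite
#' coordinates are dropped with a warning.
#'
#' @param path File path.
#' @param format One of `"auto"`, `"xyz"`, `"ply"`, `"pcd"`, `"las"`.
#'   `"auto"` resolves from the file extension.
#' @return A [point_cloud()].
#' @export
read_point_cloud <- function(path, format = c("auto", "xyz", "ply", "pcd", "las")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read point cloud: file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     xyz = "xyz", txt = "xyz", ply = "ply", pcd = "pcd",
                     las = "las",
                     stop("cannot resolve point-cloud format from extension '.", ext, "'"))
  }
  switch(format,
         xyz = read_xyz(path),
         ply = read_ply(path),
         pcd = read_pcd(path),
         las = read_las(path))
}

#' Write a point cloud to disk
#'
#' @param cloud A [point_cloud()].
#' @param path Output file path.
#' @param format One of `"auto"`, `"xyz"`, `"ply"`, `"pcd"`, `"las"`;
#'   `"auto"` resolves from the extension. PLY/PCD are written in ascii; LAS
#'   as version 1.2, point format 0 (or 1 when the cloud has per-point time).
#' @param allow_empty Write a zero-point file instead of erroring on an empty
#'   cloud.
#' @return Invisibly, `path`.
#' @export
write_point_cloud <- function(cloud, path,
                              format = c("auto", "xyz", "ply", "pcd", "las"),
                              allow_empty = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, xyz = "xyz", txt = "xyz", ply = "ply", pcd = "pcd",
                     las = "las",
                     stop("cannot resolve point-cloud format from extension '.", ext, "'"))
  }
  if (nrow(cloud) == 0 && !allow_empty)
    stop("refusing to write an empty point cloud (set allow_empty = TRUE to override)")
  switch(format,
         xyz = write_xyz(cloud, path),
         ply = write_ply(cloud, path),
         pcd = write_pcd(cloud, path),
         las = write_las(cloud, path))
  invisible(path)
}

## ---- XYZ text: whitespace separated, '#' comments, extra columns ignored ----

read_xyz <- function(path) {
  parse_tab <- function(dt) {
    if (ncol(dt) < 3) stop("malformed XYZ file '", path, "': fewer than 3 columns")
    for (j in 1:3) dt[[j]] <- suppressWarnings(as.numeric(dt[[j]]))
    point_cloud(dt[[1]], dt[[2]], dt[[3]])
  }
  # fast path: fread the file directly; fall back to a comment-stripping
  # line parse when '#' comments or ragged records trip it up
  dt <- tryCatch(
    data.table::fread(path, header = FALSE, sep = " ", fill = TRUE,
                      blank.lines.skip = TRUE, data.table = FALSE),
    error = function(e) NULL)
  if (!is.null(dt) && ncol(dt) >= 3 &&
      all(vapply(dt[1:3], is.numeric, logical(1))))
    return(parse_tab(dt))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  if (!length(lines)) stop("malformed XYZ file '", path, "': no data records")
  dt2 <- tryCatch(
    data.table::fread(text = lines, header = FALSE, sep = " ", fill = TRUE,
                      data.table = FALSE),
    error = function(e) stop("malformed XYZ file '", path, "': ",
                             conditionMessage(e)))
  parse_tab(dt2)
}

write_xyz <- function(cloud, path) {
  m <- xyz(cloud)
  data.table::fwrite(data.table::as.data.table(m), path, sep = " ",
                     col.names = FALSE)
}

## ---- PLY ----

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln)) stop("malformed PLY '", path, "': unexpected end of header")
    header <- c(header, ln)
    if (trimws(ln) == "end_header") break
    if (length(header) > 500) stop("malformed PLY '", path, "': header too long")
  }
  if (trimws(header[1]) != "ply") stop("malformed PLY '", path, "': missing magic")
  fmt_line <- grep("^format ", header, value = TRUE)
  if (!length(fmt_line)) stop("malformed PLY '", path, "': missing format line")
  fmt <- strsplit(trimws(fmt_line[1]), "\\s+")[[1]][2]
  # parse vertex element properties
  el_lines <- grep("^element ", header)
  vert_i <- grep("^element vertex", header)
  if (!length(vert_i)) stop("malformed PLY '", path, "': no vertex element")
  n_vert <- as.integer(strsplit(trimws(header[vert_i[1]]), "\\s+")[[1]][3])
  nxt <- el_lines[el_lines > vert_i[1]]
  end_i <- if (length(nxt)) min(nxt) else length(header)
  prop_lines <- header[(vert_i[1] + 1):(end_i - 1)]
  prop_lines <- grep("^property ", trimws(prop_lines), value = TRUE)
  toks <- lapply(strsplit(prop_lines, "\\s+"), identity)
  if (any(vapply(toks, function(tk) tk[2] == "list", logical(1))))
    stop("malformed PLY '", path, "': list properties on vertices unsupported")
  types <- vapply(toks, `[`, "", 2)
  names_ <- vapply(toks, `[`, "", 3)
  if (!all(c("x", "y", "z") %in% names_))
    stop("malformed PLY '", path, "': vertex element lacks x/y/z")
  vals <- NULL
  if (fmt == "ascii") {
    raw <- readLines(con)
    raw <- raw[nzchar(trimws(raw))]
    if (length(raw) < n_vert)
      stop("malformed PLY '", path, "': expected ", n_vert, " vertex records, found ", length(raw))
    rows <- strsplit(trimws(raw[seq_len(n_vert)]), "\\s+")
    nfield <- length(names_)
    bad_len <- which(vapply(rows, length, 0L) < nfield)
    if (length(bad_len))
      stop("malformed PLY '", path, "': vertex record ", bad_len[1], " has too few fields")
    vals <- matrix(suppressWarnings(as.numeric(unlist(rows, use.names = FALSE))),
                   ncol = nfield, byrow = TRUE)
  } else if (fmt == "binary_little_endian") {
    sizes <- ply_type_size[types]
    if (anyNA(sizes)) stop("malformed PLY '", path, "': unknown property type")
    rec <- sum(sizes)
    buf <- readBin(con, "raw", n = rec * n_vert)
    if (length(buf) < rec * n_vert) stop("malformed PLY '", path, "': truncated body")
    vals <- matrix(NA_real_, n_vert, length(types))
    off <- 0L
    for (j in seq_along(types)) {
      idx <- as.vector(outer(seq_len(sizes[j]), (seq_len(n_vert) - 1L) * rec + off, `+`))
      bytes <- buf[idx]
      vals[, j] <- switch(types[j],
        float = , float32 = readBin(bytes, "numeric", n = n_vert, size = 4, endian = "little"),
        double = , float64 = readBin(bytes, "numeric", n = n_vert, size = 8, endian = "little"),
        char = , int8 = readBin(bytes, "integer", n = n_vert, size = 1, signed = TRUE, endian = "little"),
        uchar = , uint8 = readBin(bytes, "integer", n = n_vert, size = 1, signed = FALSE, endian = "little"),
        short = , int16 = readBin(bytes, "integer", n = n_vert, size = 2, signed = TRUE, endian = "little"),
        ushort = , uint16 = readBin(bytes, "integer", n = n_vert, size = 2, signed = FALSE, endian = "little"),
        int = , int32 = readBin(bytes, "integer", n = n_vert, size = 4, endian = "little"),
        uint = , uint32 = readBin(bytes, "integer", n = n_vert, size = 4, endian = "little"))
      off <- off + sizes[j]
    }
  } else {
    stop("malformed PLY '", path, "': unsupported format '", fmt, "'")
  }
  colnames(vals) <- names_
  grab <- function(nm) if (nm %in% names_) vals[, nm] else NULL
  point_cloud(vals[, "x"], vals[, "y"], vals[, "z"],
              ring = grab("ring"),
              t = grab("t") %||% grab("time"),
              intensity = grab("intensity"))
}

write_ply <- function(cloud, path) {
  extras <- intersect(c("ring", "t", "intensity"), names(cloud))
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nrow(cloud)),
           "property double x", "property double y", "property double z",
           vapply(extras, function(e)
             sprintf("property %s %s", if (e == "ring") "int" else "double", e), ""),
           "end_header")
  writeLines(hdr, con)
  if (nrow(cloud) > 0) {
    cols <- c(list(cloud$x, cloud$y, cloud$z), lapply(extras, function(e) cloud[[e]]))
    body <- do.call(paste, c(lapply(cols, format_num), list(sep = " ")))
    writeLines(body, con)
  }
}

format_num <- function(v) {
  if (is.integer(v)) as.character(v) else sprintf("%.8g", v)
}

## ---- PCD ----

read_pcd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln)) stop("malformed PCD '", path, "': unexpected end of header")
    header <- c(header, ln)
    if (grepl("^DATA ", ln)) break
    if (length(header) > 100) stop("malformed PCD '", path, "': header too long")
  }
  gethdr <- function(key) {
    ln <- grep(paste0("^", key, " "), header, value = TRUE)
    if (!length(ln)) return(NULL)
    strsplit(trimws(ln[1]), "\\s+")[[1]][-1]
  }
  fields <- gethdr("FIELDS")
  sizes <- as.integer(gethdr("SIZE"))
  types <- gethdr("TYPE")
  counts <- gethdr("COUNT")
  if (!is.null(counts) && any(as.integer(counts) != 1L))
    stop("malformed PCD '", path, "': COUNT > 1 unsupported")
  n <- as.integer(gethdr("POINTS")[1])
  mode <- gethdr("DATA")[1]
  if (!all(c("x", "y", "z") %in% fields))
    stop("malformed PCD '", path, "': FIELDS lacks x/y/z")
  if (mode == "ascii") {
    raw <- readLines(con)
    raw <- raw[nzchar(trimws(raw))]
    if (length(raw) < n)
      stop("malformed PCD '", path, "': expected ", n, " records, found ", length(raw))
    rows <- strsplit(trimws(raw[seq_len(n)]), "\\s+")
    vals <- matrix(suppressWarnings(as.numeric(unlist(rows, use.names = FALSE))),
                   ncol = length(fields), byrow = TRUE)
  } else if (mode == "binary") {
    rec <- sum(sizes)
    buf <- readBin(con, "raw", n = rec * n)
    if (length(buf) < rec * n) stop("malformed PCD '", path, "': truncated body")
    vals <- matrix(NA_real_, n, length(fields))
    off <- 0L
    for (j in seq_along(fields)) {
      idx <- as.vector(outer(seq_len(sizes[j]), (seq_len(n) - 1L) * rec + off, `+`))
      bytes <- buf[idx]
      vals[, j] <- switch(paste0(types[j], sizes[j]),
        F4 = readBin(bytes, "numeric", n = n, size = 4, endian = "little"),
        F8 = readBin(bytes, "numeric", n = n, size = 8, endian = "little"),
        I1 = readBin(bytes, "integer", n = n, size = 1, signed = TRUE, endian = "little"),
        I2 = readBin(bytes, "integer", n = n, size = 2, signed = TRUE, endian = "little"),
        I4 = readBin(bytes, "integer", n = n, size = 4, endian = "little"),
        U1 = readBin(bytes, "integer", n = n, size = 1, signed = FALSE, endian = "little"),
        U2 = readBin(bytes, "integer", n = n, size = 2, signed = FALSE, endian = "little"),
        U4 = readBin(bytes, "integer", n = n, size = 4, endian = "little"),
        stop("malformed PCD '", path, "': unsupported TYPE/SIZE"))
      off <- off + sizes[j]
    }
  } else {
    stop("malformed PCD '", path, "': unsupported DATA mode '", mode, "'")
  }
  colnames(vals) <- fields
  grab <- function(nm) if (nm %in% fields) vals[, nm] else NULL
  point_cloud(vals[, "x"], vals[, "y"], vals[, "z"],
              ring = grab("ring"), t = grab("t") %||% grab("time"),
              intensity = grab("intensity"))
}

write_pcd <- function(cloud, path) {
  extras <- intersect(c("ring", "t", "intensity"), names(cloud))
  fields <- c("x", "y", "z", extras)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("# .PCD v0.7 - Point Cloud Data file format",
               "VERSION 0.7",
               paste("FIELDS", paste(fields, collapse = " ")),
               paste("SIZE", paste(ifelse(fields == "ring", 4, 8), collapse = " ")),
               paste("TYPE", paste(ifelse(fields == "ring", "I", "F"), collapse = " ")),
               paste("COUNT", paste(rep(1, length(fields)), collapse = " ")),
               sprintf("WIDTH %d", nrow(cloud)),
               "HEIGHT 1",
               "VIEWPOINT 0 0 0 1 0 0 0",
               sprintf("POINTS %d", nrow(cloud)),
               "DATA ascii"), con)
  if (nrow(cloud) > 0) {
    cols <- lapply(fields, function(f) cloud[[f]])
    body <- do.call(paste, c(lapply(cols, format_num), list(sep = " ")))
    writeLines(body, con)
  }
}

## ---- LAS 1.2 (point formats 0-3) ----

read_las <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  sig <- rawToChar(readBin(con, "raw", 4))
  if (sig != "LASF") stop("malformed LAS '", path, "': bad signature")
  seek(con, 24)                                # absolute offsets per LAS 1.2 spec
  ver <- readBin(con, "integer", 2, size = 1, signed = FALSE)
  seek(con, 96)
  offset_to_points <- readBin(con, "integer", 1, size = 4, endian = "little")
  n_vlr <- readBin(con, "integer", 1, size = 4, endian = "little")
  pdrf <- readBin(con, "integer", 1, size = 1, signed = FALSE)
  reclen <- readBin(con, "integer", 1, size = 2, signed = FALSE, endian = "little")
  npts <- readBin(con, "integer", 1, size = 4, endian = "little")
  seek(con, 131)
  scales <- readBin(con, "numeric", 3, size = 8, endian = "little")
  offs <- readBin(con, "numeric", 3, size = 8, endian = "little")
  if (!(pdrf %in% 0:3)) stop("LAS point record format ", pdrf, " unsupported")
  seek(con, offset_to_points)
  buf <- readBin(con, "raw", n = as.numeric(reclen) * npts)
  if (length(buf) < reclen * npts) stop("malformed LAS '", path, "': truncated point data")
  pick <- function(off, size) {
    idx <- as.vector(outer(seq_len(size), (seq_len(npts) - 1L) * reclen + off, `+`))
    buf[idx]
  }
  xi <- readBin(pick(0L, 4L), "integer", n = npts, size = 4, endian = "little")
  yi <- readBin(pick(4L, 4L), "integer", n = npts, size = 4, endian = "little")
  zi <- readBin(pick(8L, 4L), "integer", n = npts, size = 4, endian = "little")
  inten <- readBin(pick(12L, 2L), "integer", n = npts, size = 2, signed = FALSE, endian = "little")
  tt <- NULL
  if (pdrf %in% c(1L, 3L))
    tt <- readBin(pick(20L, 8L), "numeric", n = npts, size = 8, endian = "little")
  point_cloud(xi * scales[1] + offs[1], yi * scales[2] + offs[2],
              zi * scales[3] + offs[3],
              t = tt,
              intensity = if (any(inten != 0)) as.numeric(inten) else NULL)
}

write_las <- function(cloud, path) {
  has_t <- "t" %in% names(cloud)
  pdrf <- if (has_t) 1L else 0L
  reclen <- if (has_t) 28L else 20L
  n <- nrow(cloud)
  scale <- 1e-4
  off <- if (n > 0) floor(apply(xyz(cloud), 2, min)) else c(0, 0, 0)
  hdr_size <- 227L
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("LASF"), con)
  writeBin(rep(0L, 2), con, size = 2, endian = "little")   # source id, encoding
  writeBin(raw(16), con)                                    # guid
  writeBin(c(1L, 2L), con, size = 1)                        # version 1.2
  sysid <- charToRaw(formatC("stemscan", width = 32, flag = "-"))
  writeBin(sysid, con)
  gensw <- charToRaw(formatC("stemscan R", width = 32, flag = "-"))
  writeBin(gensw, con)
  writeBin(c(1L, 2026L), con, size = 2, endian = "little")  # doy, year
  writeBin(hdr_size, con, size = 2, endian = "little")
  writeBin(as.integer(hdr_size), con, size = 4, endian = "little")  # offset to points
  writeBin(0L, con, size = 4, endian = "little")            # n VLRs
  writeBin(pdrf, con, size = 1)
  writeBin(reclen, con, size = 2, endian = "little")
  writeBin(n, con, size = 4, endian = "little")
  writeBin(rep(0L, 5), con, size = 4, endian = "little")    # points by return
  writeBin(rep(scale, 3), con, size = 8, endian = "little")
  writeBin(as.numeric(off), con, size = 8, endian = "little")
  mx <- if (n > 0) apply(xyz(cloud), 2, max) else c(0, 0, 0)
  mn <- if (n > 0) apply(xyz(cloud), 2, min) else c(0, 0, 0)
  writeBin(as.numeric(c(mx[1], mn[1], mx[2], mn[2], mx[3], mn[3])), con,
           size = 8, endian = "little")
  if (n > 0) {
    xi <- as.integer(round((cloud$x - off[1]) / scale))
    yi <- as.integer(round((cloud$y - off[2]) / scale))
    zi <- as.integer(round((cloud$z - off[3]) / scale))
    inten <- if ("intensity" %in% names(cloud))
      as.integer(pmax(0, pmin(65535, round(cloud$intensity)))) else integer(n)
    rec <- matrix(as.raw(0), nrow = reclen, ncol = n)
    pack4 <- function(v) matrix(writeBin(v, raw(), size = 4, endian = "little"), nrow = 4)
    rec[1:4, ] <- pack4(xi)
    rec[5:8, ] <- pack4(yi)
    rec[9:12, ] <- pack4(zi)
    rec[13:14, ] <- matrix(writeBin(inten, raw(), size = 2, endian = "little"),
                           nrow = 2)
    if (has_t)
      rec[21:28, ] <- matrix(writeBin(as.numeric(cloud$t), raw(), size = 8,
                                      endian = "little"), nrow = 8)
    writeBin(as.vector(rec), con)
  }
}
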