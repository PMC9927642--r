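#' Read a point cloud from disk
#'
#' Supported formats: PLY (`ascii` and `binary_little_endian`), PCD (ascii),
#' and whitespace-delimited XYZ text. In XYZ files, `#` starts a comment line
#' and an optional integer 4th column is loaded as instance labels; in
#' PLY/PCD an integer `label` (or `scalar_label`) vertex property is loaded
#' as labels.
#'
#' @param path file to read.
#' @param format one of `"auto"` (by extension), `"ply"`, `"pcd"`, `"xyz"`.
#' @return a [point_cloud()].
#' @seealso [write_cloud()]
#' @export
read_cloud <- function(path, format = c("auto", "ply", "pcd", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read '", path, "': no such file", call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, ply = "ply", pcd = "pcd", "xyz")
  }
  switch(format,
         ply = read_ply(path),
         pcd = read_pcd(path),
         xyz = read_xyz(path))
}

#' Write a point cloud to disk
#'
#' Labels are serialized when present: as a 4th column in XYZ, as an `int32`
#' vertex property named `label` in PLY, and as an extra `label` field in
#' PCD. XYZ coordinates are printed with 17 significant digits so that an
#' XYZ round trip is bit-compatible.
#'
#' @param cloud a [point_cloud()].
#' @param path output file.
#' @param format one of `"ply"`, `"pcd"`, `"xyz"` (default by extension).
#' @return `path`, invisibly.
#' @export
write_cloud <- function(cloud, path, format = c("auto", "ply", "pcd", "xyz")) {
  stopifnot(inherits(cloud, "point_cloud"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, ply = "ply", pcd = "pcd", "xyz")
  }
  ok <- tryCatch({
    switch(format,
           ply = write_ply(cloud, path),
           pcd = write_pcd(cloud, path),
           xyz = write_xyz(cloud, path))
    TRUE
  }, error = function(e) {
    stop("cannot write '", path, "': ", conditionMessage(e), call. = FALSE)
  })
  invisible(path)
}

## ---- xyz ------------------------------------------------------------------

read_xyz <- function(path) {
  df <- tryCatch(
    utils::read.table(path, comment.char = "#", colClasses = "numeric"),
    error = function(e) stop("cannot parse '", path, "' as xyz: ",
                             conditionMessage(e), call. = FALSE))
  if (ncol(df) < 3L) stop("xyz file must have at least 3 columns", call. = FALSE)
  labels <- if (ncol(df) >= 4L) as.integer(df[[4L]]) else NULL
  point_cloud(as.matrix(df[, 1:3]), labels)
}

write_xyz <- function(cloud, path) {
  m <- cloud$points
  lines <- if (is.null(cloud$labels))
    sprintf("%.17g %.17g %.17g", m[, 1], m[, 2], m[, 3])
  else
    sprintf("%.17g %.17g %.17g %d", m[, 1], m[, 2], m[, 3], cloud$labels)
  writeLines(lines, path)
}

## ---- ply ------------------------------------------------------------------

.ply_sizes <- c(char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
                short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
                int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
                float = 4L, float32 = 4L, double = 8L, float64 = 8L)

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) stop("unexpected end of ply header", call. = FALSE)
    header <- c(header, ln)
    if (trimws(ln) == "end_header") break
  }
  if (trimws(header[1L]) != "ply") stop("not a ply file", call. = FALSE)
  fmt <- strsplit(trimws(grep("^format", header, value = TRUE)[1L]), "\\s+")[[1L]][2L]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop("unsupported ply format: ", fmt, call. = FALSE)

  # parse element/property layout; the vertex element must come first
  elems <- list(); cur <- NULL
  for (ln in header) {
    tok <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (tok[1L] == "element") {
      cur <- length(elems) + 1L
      elems[[cur]] <- list(name = tok[2L], n = as.integer(tok[3L]),
                           ptype = character(), pname = character(),
                           list = logical())
    } else if (tok[1L] == "property" && !is.null(cur)) {
      is_list <- tok[2L] == "list"
      elems[[cur]]$list <- c(elems[[cur]]$list, is_list)
      elems[[cur]]$ptype <- c(elems[[cur]]$ptype, if (is_list) NA_character_ else tok[2L])
      elems[[cur]]$pname <- c(elems[[cur]]$pname, tok[length(tok)])
    }
  }
  vi <- which(vapply(elems, function(e) e$name, "") == "vertex")
  if (length(vi) != 1L) stop("ply file has no vertex element", call. = FALSE)
  if (vi != 1L) stop("only ply files with the vertex element first are supported",
                     call. = FALSE)
  v <- elems[[1L]]
  if (any(v$list)) stop("list properties on the vertex element are unsupported",
                        call. = FALSE)

  if (fmt == "ascii") {
    body <- readLines(con, n = v$n)
    dat <- utils::read.table(text = body, col.names = v$pname,
                             colClasses = "numeric")
  } else {
    sizes <- .ply_sizes[v$ptype]
    if (anyNA(sizes)) stop("unknown ply property type", call. = FALSE)
    row_bytes <- sum(sizes)
    raw <- readBin(con, "raw", n = row_bytes * v$n)
    if (length(raw) < row_bytes * v$n) stop("truncated ply payload", call. = FALSE)
    offs <- c(0L, cumsum(sizes))
    dat <- as.data.frame(lapply(seq_along(v$pname), function(p) {
      s <- sizes[p]
      pick <- rep((0:(v$n - 1L)) * row_bytes, each = s) + offs[p] + seq_len(s)
      ty <- v$ptype[p]
      if (ty %in% c("float", "float32", "double", "float64"))
        readBin(raw[pick], "double", n = v$n, size = s, endian = "little")
      else
        readBin(raw[pick], "integer", n = v$n, size = s, endian = "little",
                signed = !(ty %in% c("uchar", "uint8", "ushort", "uint16")))
    }))
    names(dat) <- v$pname
  }
  need <- c("x", "y", "z")
  if (!all(need %in% names(dat)))
    stop("ply vertex element lacks x/y/z properties", call. = FALSE)
  lab_col <- intersect(c("label", "scalar_label"), names(dat))[1L]
  labels <- if (!is.na(lab_col)) as.integer(dat[[lab_col]]) else NULL
  point_cloud(cbind(dat$x, dat$y, dat$z), labels)
}

write_ply <- function(cloud, path) {
  n <- n_points(cloud)
  has_lab <- !is.null(cloud$labels)
  header <- c("ply", "format ascii 1.0",
              paste("element vertex", n),
              "property double x", "property double y", "property double z",
              if (has_lab) "property int label",
              "end_header")
  m <- cloud$points
  body <- if (has_lab)
    sprintf("%.17g %.17g %.17g %d", m[, 1], m[, 2], m[, 3], cloud$labels)
  else
    sprintf("%.17g %.17g %.17g", m[, 1], m[, 2], m[, 3])
  writeLines(c(header, body), path)
}

## ---- pcd ------------------------------------------------------------------

read_pcd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  kv <- function(key) {
    ln <- grep(paste0("^", key, "\\b"), lines, value = TRUE)[1L]
    if (is.na(ln)) return(NULL)
    strsplit(trimws(ln), "\\s+")[[1L]][-1L]
  }
  data_ln <- grep("^DATA\\b", lines)[1L]
  if (is.na(data_ln)) stop("not a pcd file (no DATA line)", call. = FALSE)
  if (kv("DATA")[1L] != "ascii")
    stop("only ascii pcd payloads are supported", call. = FALSE)
  fields <- kv("FIELDS")
  npts <- as.integer(kv("POINTS")[1L])
  body <- lines[(data_ln + 1L):length(lines)]
  body <- body[nzchar(trimws(body))][seq_len(npts)]
  dat <- utils::read.table(text = body, col.names = fields, colClasses = "numeric")
  if (!all(c("x", "y", "z") %in% fields))
    stop("pcd file lacks x/y/z fields", call. = FALSE)
  lab_col <- intersect(c("label", "scalar_label"), fields)[1L]
  labels <- if (!is.na(lab_col)) as.integer(dat[[lab_col]]) else NULL
  point_cloud(cbind(dat$x, dat$y, dat$z), labels)
}

write_pcd <- function(cloud, path) {
  n <- n_points(cloud)
  has_lab <- !is.null(cloud$labels)
  fields <- c("x", "y", "z", if (has_lab) "label")
  header <- c("# .PCD v0.7 - Point Cloud Data file format",
              "VERSION 0.7",
              paste("FIELDS", paste(fields, collapse = " ")),
              paste("SIZE", paste(rep(8L, 3L + has_lab), collapse = " ")),
              paste("TYPE", paste(c("F", "F", "F", if (has_lab) "I"), collapse = " ")),
              paste("COUNT", paste(rep(1L, 3L + has_lab), collapse = " ")),
              paste("WIDTH", n), "HEIGHT 1", "VIEWPOINT 0 0 0 1 0 0 0",
              paste("POINTS", n), "DATA ascii")
  m <- cloud$points
  body <- if (has_lab)
    sprintf("%.17g %.17g %.17g %d", m[, 1], m[, 2], m[, 3], cloud$labels)
  else
    sprintf("%.17g %.17g %.17g", m[, 1], m[, 2], m[, 3])
  writeLines(c(header, body), path)
}
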