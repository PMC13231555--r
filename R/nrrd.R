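# Minimal NRRD0004 reader/writer for 3D scalar volumes.
# Supports the header fields this package emits plus the common type and
# encoding variants (raw, gzip, ascii/text). Detached data files and
# non-3D volumes are rejected.

nrrd_type_map <- list(
  "signed char" = list(what = "integer", size = 1, signed = TRUE),
  "int8"        = list(what = "integer", size = 1, signed = TRUE),
  "uchar"       = list(what = "integer", size = 1, signed = FALSE),
  "uint8"       = list(what = "integer", size = 1, signed = FALSE),
  "unsigned char" = list(what = "integer", size = 1, signed = FALSE),
  "short"       = list(what = "integer", size = 2, signed = TRUE),
  "int16"       = list(what = "integer", size = 2, signed = TRUE),
  "ushort"      = list(what = "integer", size = 2, signed = FALSE),
  "uint16"      = list(what = "integer", size = 2, signed = FALSE),
  "int"         = list(what = "integer", size = 4, signed = TRUE),
  "int32"       = list(what = "integer", size = 4, signed = TRUE),
  "uint"        = list(what = "integer", size = 4, signed = FALSE),
  "uint32"      = list(what = "integer", size = 4, signed = FALSE),
  "float"       = list(what = "double",  size = 4, signed = TRUE),
  "double"      = list(what = "double",  size = 8, signed = TRUE)
)

# Parse "(a,b,c)" -> numeric vector; "none" -> NA.
nrrd_parse_vector <- function(s) {
  s <- trimws(s)
  if (identical(tolower(s), "none")) return(rep(NA_real_, 3))
  as.numeric(strsplit(gsub("[()]", "", s), ",")[[1]])
}

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- readLines(con, n = 1L, warn = FALSE)
  if (!grepl("^NRRD000[1-5]$", magic))
    stop("not an NRRD file (bad magic line): ", path, call. = FALSE)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L)
      stop("truncated NRRD header in ", path, call. = FALSE)
    if (nchar(line) == 0L) break          # blank line ends the header
    if (grepl("^#", line)) next
    m <- regmatches(line, regexec("^([^:]+):=?\\s*(.*)$", line))[[1]]
    if (length(m) != 3L)
      stop("unparseable NRRD header line: ", line, call. = FALSE)
    fields[[tolower(trimws(m[2]))]] <- trimws(m[3])
  }
  if (!is.null(fields[["data file"]]) || !is.null(fields[["datafile"]]))
    stop("detached NRRD data files are not supported", call. = FALSE)
  ndim <- as.integer(fields[["dimension"]])
  if (!identical(ndim, 3L))
    stop("expected a 3D volume, got dimension ", ndim, call. = FALSE)
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  n <- prod(sizes)
  type <- nrrd_type_map[[tolower(fields[["type"]])]]
  if (is.null(type))
    stop("unsupported NRRD type: ", fields[["type"]], call. = FALSE)
  encoding <- tolower(fields[["encoding"]] %||% "raw")
  endian <- if (identical(tolower(fields[["endian"]] %||% "little"), "big"))
    "big" else "little"

  if (encoding %in% c("raw", "gz", "gzip")) {
    raw_rest <- readBin(con, "raw", n = file.size(path))
    if (encoding != "raw") raw_rest <- memDecompress(raw_rest, type = "gzip")
    vals <- readBin(raw_rest, what = type$what, n = n, size = type$size,
                    signed = if (type$size >= 4) TRUE else type$signed,
                    endian = endian)
  } else if (encoding %in% c("ascii", "text", "txt")) {
    txt <- rawToChar(readBin(con, "raw", n = file.size(path)))
    vals <- as.numeric(strsplit(trimws(txt), "\\s+")[[1]])
  } else stop("unsupported NRRD encoding: ", encoding, call. = FALSE)
  if (length(vals) < n)
    stop("NRRD data shorter than sizes imply", call. = FALSE)

  # spacing: prefer `space directions` row norms, else `spacings`
  spacing <- rep(1, 3)
  if (!is.null(fields[["space directions"]])) {
    toks <- regmatches(fields[["space directions"]],
                       gregexpr("\\([^)]*\\)|none", fields[["space directions"]]))[[1]]
    dirs <- lapply(toks, nrrd_parse_vector)
    spacing <- vapply(dirs, function(v) sqrt(sum(v^2)), numeric(1))
  } else if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  }
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]]))
    origin <- nrrd_parse_vector(fields[["space origin"]])

  list(data = array(vals[seq_len(n)], dim = sizes),
       spacing = spacing, origin = origin)
}

write_nrrd <- function(data, path, spacing, origin = c(0, 0, 0),
                       type = c("uint8", "float", "double")) {
  type <- match.arg(type)
  stopifnot(length(dim(data)) == 3L)
  size <- switch(type, uint8 = 1L, float = 4L, double = 8L)
  what <- if (type == "uint8") as.integer(data) else as.double(data)
  hdr <- c(
    "NRRD0004",
    "# generated by the ipvv R package",
    paste0("type: ", type),
    "dimension: 3",
    "space: left-posterior-superior",
    paste0("sizes: ", paste(dim(data), collapse = " ")),
    sprintf("space directions: (%.10g,0,0) (0,%.10g,0) (0,0,%.10g)",
            spacing[1], spacing[2], spacing[3]),
    "kinds: domain domain domain",
    "endian: little",
    "encoding: raw",
    sprintf("space origin: (%.10g,%.10g,%.10g)",
            origin[1], origin[2], origin[3]),
    "")
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con, sep = "\n")
  writeBin(what, con, size = size, endian = "little")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
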