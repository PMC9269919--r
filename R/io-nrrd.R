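# Minimal NRRD0004 reader/writer for axis-aligned scalar 3D volumes.
# Supports attached and detached data, raw and gzip encodings, the common
# scalar types, and geometry via either `space directions`/`space origin`
# or legacy `spacings`.  Non-axis-aligned direction matrices are rejected:
# the package's physical model is position = origin + spacing * index.

nrrd_types <- list(
  "signed char" = list(what = "integer", size = 1L, signed = TRUE),
  "int8" = list(what = "integer", size = 1L, signed = TRUE),
  "uchar" = list(what = "integer", size = 1L, signed = FALSE),
  "unsigned char" = list(what = "integer", size = 1L, signed = FALSE),
  "uint8" = list(what = "integer", size = 1L, signed = FALSE),
  "short" = list(what = "integer", size = 2L, signed = TRUE),
  "int16" = list(what = "integer", size = 2L, signed = TRUE),
  "ushort" = list(what = "integer", size = 2L, signed = FALSE),
  "uint16" = list(what = "integer", size = 2L, signed = FALSE),
  "int" = list(what = "integer", size = 4L, signed = TRUE),
  "int32" = list(what = "integer", size = 4L, signed = TRUE),
  "uint" = list(what = "integer", size = 4L, signed = FALSE),
  "uint32" = list(what = "integer", size = 4L, signed = FALSE),
  "float" = list(what = "double", size = 4L, signed = TRUE),
  "double" = list(what = "double", size = 8L, signed = TRUE)
)

parse_nrrd_vector <- function(s) {
  s <- gsub("[()]", "", trimws(s))
  as.double(strsplit(s, ",")[[1]])
}

read_nrrd <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8 || !identical(rawToChar(raw[1:4]), "NRRD"))
    stop("not an NRRD file: ", path, call. = FALSE)
  # header ends at the first blank line
  nl <- which(raw == as.raw(10L))
  txt_end <- NA_integer_
  prev <- 0L
  for (p in nl) {
    line_len <- p - prev - 1L
    if (line_len == 0L || (line_len == 1L && raw[prev + 1L] == as.raw(13L))) {
      txt_end <- p
      break
    }
    prev <- p
  }
  header_raw <- if (is.na(txt_end)) raw else raw[seq_len(txt_end)]
  lines <- strsplit(rawToChar(header_raw), "\r?\n")[[1]]
  lines <- lines[nzchar(lines)]
  lines <- lines[-1]                                   # magic
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[!grepl(":=", lines, fixed = TRUE)]    # key/value pairs ignored
  kv <- regmatches(lines, regexpr(": ", lines), invert = TRUE)
  fields <- list()
  for (p in kv) {
    if (length(p) == 2L) fields[[tolower(trimws(p[1]))]] <- trimws(p[2])
  }
  need <- c("type", "dimension", "sizes", "encoding")
  miss <- setdiff(need, names(fields))
  if (length(miss))
    stop("malformed NRRD header (missing ", paste(miss, collapse = ", "),
         "): ", path, call. = FALSE)
  ndim <- as.integer(fields$dimension)
  sizes <- as.integer(strsplit(fields$sizes, "[[:space:]]+")[[1]])
  if (ndim != 3L || length(sizes) != 3L)
    stop("unsupported NRRD content: expected a 3D scalar volume, got ",
         ndim, " dimensions", call. = FALSE)
  tinfo <- nrrd_types[[tolower(fields$type)]]
  if (is.null(tinfo))
    stop("unsupported NRRD type: ", fields$type, call. = FALSE)
  endian <- if (!is.null(fields$endian) && fields$endian == "big")
    "big" else "little"

  spacing <- NULL
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space directions"]])) {
    toks <- regmatches(fields[["space directions"]],
                       gregexpr("\\([^)]*\\)|none", fields[["space directions"]]))[[1]]
    vecs <- toks[toks != "none"]
    if (length(vecs) == 3L) {
      dirmat <- t(vapply(vecs, parse_nrrd_vector, numeric(3)))
      offdiag <- dirmat; diag(offdiag) <- 0
      if (any(abs(offdiag) > 1e-9) || any(diag(dirmat) <= 0))
        stop("non-axis-aligned NRRD space directions are not supported",
             call. = FALSE)
      spacing <- diag(dirmat)
    }
  } else if (!is.null(fields$spacings)) {
    spacing <- as.double(strsplit(fields$spacings, "[[:space:]]+")[[1]])
    spacing <- spacing[is.finite(spacing)]
    if (length(spacing) != 3L) spacing <- NULL
  }
  if (!is.null(fields[["space origin"]]))
    origin <- parse_nrrd_vector(fields[["space origin"]])
  if (is.null(spacing)) {
    warning("NRRD header carries no voxel spacing; ",
            "defaulting to 0.625 x 0.625 x 0.975 mm", call. = FALSE)
    spacing <- c(0.625, 0.625, 0.975)
  }

  n <- prod(sizes)
  if (!is.null(fields[["data file"]]) || !is.null(fields$datafile)) {
    dfile <- if (!is.null(fields[["data file"]])) fields[["data file"]] else
      fields$datafile
    dpath <- file.path(dirname(path), dfile)
    if (!file.exists(dpath))
      stop("detached NRRD data file not found: ", dpath, call. = FALSE)
    payload <- readBin(dpath, "raw", n = file.info(dpath)$size)
  } else {
    if (is.na(txt_end) || txt_end >= length(raw))
      stop("truncated NRRD file (no data segment): ", path, call. = FALSE)
    payload <- raw[(txt_end + 1L):length(raw)]
  }
  payload <- switch(fields$encoding,
    raw = payload,
    gzip = , gz = memDecompress(payload, type = "gzip"),
    stop("unsupported NRRD encoding: ", fields$encoding, call. = FALSE))
  if (length(payload) < n * tinfo$size)
    stop("truncated NRRD data: expected ", n * tinfo$size, " bytes, got ",
         length(payload), call. = FALSE)
  vals <- readBin(payload, what = tinfo$what, n = n, size = tinfo$size,
                  signed = if (tinfo$size >= 4L) TRUE else tinfo$signed,
                  endian = endian)
  list(data = array(as.double(vals), sizes), spacing = spacing,
       origin = origin)
}

write_nrrd <- function(data, path, spacing, origin,
                       type = c("double", "uint8", "int16", "float"),
                       encoding = c("gzip", "raw")) {
  type <- match.arg(type)
  encoding <- match.arg(encoding)
  sizes <- dim(data)
  header <- c(
    "NRRD0004",
    paste0("type: ", type),
    "dimension: 3",
    "space: left-posterior-superior",
    paste0("sizes: ", paste(sizes, collapse = " ")),
    paste0("space directions: ",
           sprintf("(%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
                   spacing[1], spacing[2], spacing[3])),
    "kinds: domain domain domain",
    "endian: little",
    paste0("encoding: ", encoding),
    paste0("space origin: ",
           sprintf("(%.17g,%.17g,%.17g)", origin[1], origin[2], origin[3])),
    ""
  )
  vals <- as.vector(data)
  payload <- switch(type,
    double = writeBin(as.double(vals), raw(), size = 8L, endian = "little"),
    float = writeBin(as.double(vals), raw(), size = 4L, endian = "little"),
    int16 = writeBin(as.integer(vals), raw(), size = 2L, endian = "little"),
    uint8 = as.raw(as.integer(vals)))
  if (encoding == "gzip") payload <- memCompress(payload, type = "gzip")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(paste(header, collapse = "\n"), "\n")), con)
  writeBin(payload, con)
  invisible(path)
}
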