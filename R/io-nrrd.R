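## Minimal NRRD0004 support for integer label volumes (raw encoding only).
## Covers exactly the fields this package writes; arbitrary NRRD files from
## other tools load as long as they use raw encoding and a scalar type.

.nrrd_types <- c(
  "signed char" = "integer", "int8" = "integer", "int8_t" = "integer",
  "uchar" = "integer", "unsigned char" = "integer", "uint8" = "integer",
  "short" = "integer", "int16" = "integer",
  "unsigned short" = "integer", "uint16" = "integer",
  "int" = "integer", "int32" = "integer", "signed int" = "integer",
  "unsigned int" = "integer", "uint32" = "integer",
  "float" = "double", "double" = "double"
)

.nrrd_size <- c(
  "signed char" = 1L, "int8" = 1L, "int8_t" = 1L,
  "uchar" = 1L, "unsigned char" = 1L, "uint8" = 1L,
  "short" = 2L, "int16" = 2L,
  "unsigned short" = 2L, "uint16" = 2L,
  "int" = 4L, "int32" = 4L, "signed int" = 4L,
  "unsigned int" = 4L, "uint32" = 4L,
  "float" = 4L, "double" = 8L
)

#' Read a raw-encoded NRRD volume
#'
#' @param path Path to a `.nrrd` file with attached raw-encoded data.
#' @return A list with `data` (array), `sizes`, and `header` (named list of
#'   raw header fields, including any `key:=value` custom fields).
#' @export
read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD000[0-9]$", magic)) {
    stopf("not an NRRD file: %s", path, class = "atlastrace_format_error")
  }
  header <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L || line == "") break
    if (grepl("^#", line)) next
    if (grepl(":=", line, fixed = TRUE)) {
      kv <- regmatches(line, regexpr(":=", line, fixed = TRUE), invert = TRUE)[[1]]
    } else {
      kv <- regmatches(line, regexpr(": ", line, fixed = TRUE), invert = TRUE)[[1]]
    }
    if (length(kv) != 2L) stopf("malformed NRRD header line: %s", line,
                                class = "atlastrace_format_error")
    header[[kv[1]]] <- kv[2]
  }
  type <- header[["type"]]
  if (is.null(type) || !type %in% names(.nrrd_types)) {
    stopf("unsupported NRRD type: %s", type %||% "<missing>",
          class = "atlastrace_format_error")
  }
  enc <- header[["encoding"]]
  if (!identical(enc, "raw")) {
    stopf("only raw NRRD encoding is supported (got '%s')", enc,
          class = "atlastrace_format_error")
  }
  sizes <- as.integer(strsplit(trimws(header[["sizes"]]), "\\s+")[[1]])
  endian <- header[["endian"]] %||% "little"
  n <- prod(sizes)
  what <- .nrrd_types[[type]]
  sz <- .nrrd_size[[type]]
  signed <- !grepl("^u", type) && !grepl("^unsigned", type)
  data <- readBin(con, what = what, n = n, size = sz,
                  signed = if (what == "integer" && sz < 4L) signed else TRUE,
                  endian = endian)
  if (length(data) != n) {
    stopf("truncated NRRD data: expected %d values, got %d", n, length(data),
          class = "atlastrace_format_error")
  }
  list(data = array(data, dim = sizes), sizes = sizes, header = header)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an integer array as a raw-encoded NRRD volume
#'
#' @param data Integer array (up to 3-D).
#' @param path Output path.
#' @param fields Named character vector of extra `key:=value` custom fields.
#' @param space_um Per-axis spacing in micrometers (scalar or vector),
#'   written as `space directions`.
#' @export
write_nrrd <- function(data, path, fields = character(0), space_um = NULL) {
  sizes <- dim(data)
  if (is.null(sizes)) sizes <- length(data)
  storage.mode(data) <- "integer"
  hdr <- c(
    "NRRD0004",
    "type: int32",
    sprintf("dimension: %d", length(sizes)),
    sprintf("sizes: %s", paste(sizes, collapse = " ")),
    "encoding: raw",
    "endian: little"
  )
  if (!is.null(space_um)) {
    sp <- rep_len(space_um, length(sizes))
    dirs <- vapply(seq_along(sizes), function(a) {
      v <- rep(0, length(sizes)); v[a] <- sp[a]
      sprintf("(%s)", paste(format(v, trim = TRUE), collapse = ","))
    }, character(1))
    hdr <- c(hdr, sprintf("space directions: %s", paste(dirs, collapse = " ")),
             "space units: \"microns\" \"microns\" \"microns\"")
  }
  if (length(fields)) {
    hdr <- c(hdr, sprintf("%s:=%s", names(fields), unname(fields)))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(hdr, ""), con)
  writeBin(as.vector(data), con, size = 4L, endian = "little")
  invisible(path)
}
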