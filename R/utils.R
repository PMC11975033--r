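#' @keywords internal
"_PACKAGE"

## shared internal helpers

stopf <- function(fmt, ..., class = NULL) {
  msg <- sprintf(fmt, ...)
  cnd <- structure(
    class = c(class, "atlastrace_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cnd)
}

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' @noRd
is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && x == floor(x)

## voxel keys: encode integer (i,j,k) triples as single strings for set ops
voxel_keys <- function(vox) {
  if (nrow(vox) == 0L) return(character(0))
  paste(vox[, 1], vox[, 2], vox[, 3], sep = "_")
}

## deterministic CSV writers so repeated runs are byte-identical
write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

read_table_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

read_json_file <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

## sample SEM (n - 1 denominator); NA for n = 1
sem <- function(x) {
  n <- length(x)
  if (n < 2L) return(NA_real_)
  stats::sd(x) / sqrt(n)
}

## largest-remainder apportionment of `total` into integer counts ~ props
apportion_counts <- function(total, props) {
  stopifnot(abs(sum(props) - 1) < 1e-8)
  raw <- total * props
  base <- floor(raw)
  short <- total - sum(base)
  if (short > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
  }
  as.integer(base)
}
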