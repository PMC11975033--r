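## Per-section planar affine transforms: (u, v) section pixels -> (x, z, ml)
## atlas micrometers. 9 free parameters (3x2 linear block + 3 offset).

#' Fit a planar affine transform from control points
#'
#' Least-squares fit of the map `q = A p + b` taking 2-D section pixel
#' coordinates `p = (u, v)` to 3-D atlas coordinates `q` in micrometers.
#' The minimizer of the summed squared residual norm is obtained per output
#' axis by QR decomposition of the common design matrix.
#'
#' @param pixel_points Numeric matrix (n x 2) of `(u, v)` pixel coordinates.
#' @param atlas_points Numeric matrix (n x 3) of matching atlas coordinates
#'   in micrometers.
#' @return An object of class `planar_affine` with elements `A` (3 x 2),
#'   `b` (length 3) and `fit_rms_um` (root-mean-square residual norm).
#' @export
fit_affine <- function(pixel_points, atlas_points) {
  P <- as.matrix(pixel_points)
  Q <- as.matrix(atlas_points)
  if (nrow(P) != nrow(Q) || ncol(P) != 2L || ncol(Q) != 3L) {
    stopf("need n x 2 pixel and n x 3 atlas coordinate matrices")
  }
  if (nrow(P) < 3L) {
    stopf("at least 3 control-point pairs required (got %d)", nrow(P),
          class = "atlastrace_insufficient_points_error")
  }
  if (!all(is.finite(P)) || !all(is.finite(Q))) {
    stopf("control points must be finite")
  }
  X <- cbind(P, 1)
  qrX <- qr(X)
  if (qrX$rank < 3L) {
    stopf("degenerate control points: pixel coordinates are collinear",
          class = "atlastrace_degeneracy_error")
  }
  coef <- qr.coef(qrX, Q)          # 3 x 3: rows u, v, intercept
  A <- t(coef[1:2, , drop = FALSE]) # 3 x 2
  b <- as.numeric(coef[3, ])
  res <- Q - X %*% coef
  rms <- sqrt(mean(rowSums(res^2)))
  structure(list(A = A, b = b, fit_rms_um = rms, n_points = nrow(P)),
            class = "planar_affine")
}

#' @export
print.planar_affine <- function(x, ...) {
  cat(sprintf("<planar_affine> rms %.4g um over %d control points\n",
              x$fit_rms_um, x$n_points))
  invisible(x)
}

#' Apply a planar affine transform
#'
#' @param transform A `planar_affine` object.
#' @param pixel_points Numeric matrix (n x 2) of `(u, v)` pixel coordinates
#'   (n may be 0).
#' @return Numeric matrix (n x 3) of atlas coordinates in micrometers with
#'   columns `x_um`, `z_um`, `ml_um`.
#' @export
apply_affine <- function(transform, pixel_points) {
  stopifnot(inherits(transform, "planar_affine"))
  P <- as.matrix(pixel_points)
  if (length(P) == 0L) {
    return(matrix(numeric(0), ncol = 3,
                  dimnames = list(NULL, c("x_um", "z_um", "ml_um"))))
  }
  out <- P %*% t(transform$A) +
    matrix(transform$b, nrow = nrow(P), ncol = 3, byrow = TRUE)
  colnames(out) <- c("x_um", "z_um", "ml_um")
  out
}

#' Fit one transform per section from a control-point table
#'
#' @param control_points Data frame with columns `section_id`, `u_px`,
#'   `v_px`, `x_um`, `z_um`, `ml_um`.
#' @return Named list of `planar_affine` objects, one per section id.
#' @export
fit_section_transforms <- function(control_points) {
  need <- c("section_id", "u_px", "v_px", "x_um", "z_um", "ml_um")
  missing <- setdiff(need, names(control_points))
  if (length(missing)) {
    stopf("control-point table lacks column(s): %s",
          paste(missing, collapse = ", "))
  }
  split_cp <- split(control_points, control_points$section_id)
  lapply(split_cp, function(cp) {
    fit_affine(as.matrix(cp[, c("u_px", "v_px")]),
               as.matrix(cp[, c("x_um", "z_um", "ml_um")]))
  })
}

#' Serialize section transforms to JSON
#'
#' @param transforms Named list of `planar_affine` objects.
#' @param path Output JSON path.
#' @export
write_transforms <- function(transforms, path) {
  out <- lapply(transforms, function(tr) {
    list(A = apply(tr$A, 1, as.numeric, simplify = FALSE),
         b = as.numeric(tr$b),
         fit_rms_um = tr$fit_rms_um, n_points = tr$n_points)
  })
  write_json_file(out, path)
}

#' Read section transforms from JSON
#'
#' @param path JSON path written by [write_transforms()].
#' @return Named list of `planar_affine` objects.
#' @export
read_transforms <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(js, function(tr) {
    A <- matrix(unlist(tr$A, use.names = FALSE), ncol = 2, byrow = TRUE)
    structure(list(A = A, b = unname(unlist(tr$b)),
                   fit_rms_um = tr$fit_rms_um, n_points = tr$n_points),
              class = "planar_affine")
  })
}
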