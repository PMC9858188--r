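# Stain optical-density vectors and the deconvolution matrix.

#' Stain optical-density vectors for color deconvolution
#'
#' Per-channel optical densities of the pure stains, each normalized to unit
#' Euclidean length. Defaults are the Ruifrok--Johnston H-DAB vectors; the
#' residual vector completes the basis as the unit cross product of the two.
#'
#' @param hematoxylin,dab length-3 non-negative OD vectors (R, G, B).
#' @param residual optional third basis vector; defaults to the unit cross
#'   product of `hematoxylin` and `dab`.
#' @returns Object of class `stain_vectors`: list with unit vectors
#'   `hematoxylin`, `dab`, `residual`.
#' @examples
#' sv <- stain_vectors()
#' stain_matrix(sv)
#' @export
stain_vectors <- function(hematoxylin = c(0.650, 0.704, 0.286),
                          dab = c(0.268, 0.570, 0.776),
                          residual = NULL) {
  unit <- function(v) {
    n <- sqrt(sum(v^2))
    if (n == 0) stop("stain vector must be nonzero", call. = FALSE)
    v / n
  }
  h <- unit(as.numeric(hematoxylin))
  d <- unit(as.numeric(dab))
  if (is.null(residual)) {
    residual <- c(
      h[2] * d[3] - h[3] * d[2],
      h[3] * d[1] - h[1] * d[3],
      h[1] * d[2] - h[2] * d[1]
    )
    if (sqrt(sum(residual^2)) < 1e-12) {
      stop("hematoxylin and DAB vectors are collinear", call. = FALSE)
    }
  }
  r <- unit(as.numeric(residual))
  sv <- structure(
    list(hematoxylin = h, dab = d, residual = r),
    class = "stain_vectors"
  )
  m <- stain_matrix(sv)
  if (kappa(m, exact = TRUE) >= 1e6) {
    stop("stain matrix is ill-conditioned (condition number >= 1e6)",
         call. = FALSE)
  }
  sv
}

#' @export
print.stain_vectors <- function(x, ...) {
  cat("<stain_vectors>\n")
  print(round(stain_matrix(x), 4))
  invisible(x)
}

#' Stain matrix (rows = stains, columns = RGB optical densities)
#' @param sv [stain_vectors()] object.
#' @returns 3 x 3 numeric matrix.
#' @export
stain_matrix <- function(sv) {
  stopifnot(inherits(sv, "stain_vectors"))
  rbind(
    hematoxylin = sv$hematoxylin,
    dab = sv$dab,
    residual = sv$residual
  )
}

#' Deconvolution matrix (inverse of the stain matrix)
#' @param sv [stain_vectors()] object.
#' @returns 3 x 3 numeric matrix mapping OD pixel vectors to concentrations.
#' @export
deconvolution_matrix <- function(sv) {
  solve(stain_matrix(sv))
}
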