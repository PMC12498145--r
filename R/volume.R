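#' Optical properties of a tissue type
#'
#' Absorption `mu_a`, reduced scattering `mu_s'`, anisotropy `g` and refractive
#' index `n`. Transport uses the full scattering coefficient
#' `mu_s = mu_s' / (1 - g)` (similarity relation); the anisotropy default 0.9
#' is the standard intralipid-like value.
#'
#' @param mu_a absorption coefficient, mm^-1 (>= 0).
#' @param mu_s_prime reduced scattering coefficient, mm^-1 (>= 0).
#' @param g scattering anisotropy, -1 < g < 1.
#' @param n refractive index.
#' @return Object of class `optical_properties`.
#' @export
optical_properties <- function(mu_a, mu_s_prime, g = 0.9, n = 1.37) {
  if (!is.finite(mu_a) || mu_a < 0) stop("mu_a must be >= 0", call. = FALSE)
  if (!is.finite(mu_s_prime) || mu_s_prime < 0)
    stop("mu_s_prime must be >= 0", call. = FALSE)
  if (!is.finite(g) || abs(g) >= 1) stop("|g| must be < 1", call. = FALSE)
  mu_s <- mu_s_prime / (1 - g)
  if (!is.finite(mu_s)) stop("derived mu_s is not finite", call. = FALSE)
  structure(list(mu_a = mu_a, mu_s_prime = mu_s_prime, mu_s = mu_s,
                 g = g, n = n),
            class = "optical_properties")
}

#' Voxelized simulation volume
#'
#' A 3-D grid of tissue labels plus per-voxel fluorophore maps. `tissue_label`
#' indexes into the `properties` table; voxels with `fluor_yield > 0` must
#' carry a positive `fluor_lifetime`.
#'
#' Geometry convention: voxel `(i, j, k)` spans
#' `[(i-1)*voxel, i*voxel) x ... x [(k-1)*voxel, k*voxel)` mm with the
#' illuminated (detector-facing) surface at `z = 0` and z growing downward.
#'
#' @param tissue_label integer array `(nx, ny, nz)` of 1-based label values.
#' @param properties list of [optical_properties()], one per label value.
#' @param voxel_size_mm voxel edge length, mm.
#' @param fluor_yield per-voxel relative quantum yield (array like
#'   `tissue_label`, or `NULL` for none).
#' @param fluor_lifetime_ns per-voxel fluorescence lifetime, ns.
#' @param properties_em optional emission-wavelength property table (defaults
#'   to the excitation table).
#' @return Object of class `voxel_volume`.
#' @export
voxel_volume <- function(tissue_label, properties, voxel_size_mm,
                         fluor_yield = NULL, fluor_lifetime_ns = NULL,
                         properties_em = NULL) {
  tissue_label <- as.array(tissue_label)
  if (length(dim(tissue_label)) != 3)
    stop("tissue_label must be a 3-D array", call. = FALSE)
  if (any(dim(tissue_label) < 1)) stop("zero-extent volume", call. = FALSE)
  storage.mode(tissue_label) <- "integer"
  labs <- sort(unique(as.vector(tissue_label)))
  if (min(labs) < 1 || max(labs) > length(properties))
    stop("tissue labels reference undefined property entries", call. = FALSE)
  for (p in properties) {
    stopifnot(inherits(p, "optical_properties"))
    if (anyNA(unlist(p))) stop("NaN optical properties", call. = FALSE)
  }
  if (voxel_size_mm <= 0) stop("voxel_size_mm must be > 0", call. = FALSE)
  if (is.null(fluor_yield)) fluor_yield <- array(0, dim(tissue_label))
  fluor_yield <- as.array(fluor_yield)
  stopifnot(identical(dim(fluor_yield), dim(tissue_label)))
  if (any(fluor_yield < 0)) stop("fluor_yield must be >= 0", call. = FALSE)
  if (is.null(fluor_lifetime_ns)) fluor_lifetime_ns <- array(0, dim(tissue_label))
  fluor_lifetime_ns <- as.array(fluor_lifetime_ns)
  stopifnot(identical(dim(fluor_lifetime_ns), dim(tissue_label)))
  if (any(fluor_yield > 0 & fluor_lifetime_ns <= 0))
    stop("voxels with fluor_yield > 0 must have fluor_lifetime > 0",
         call. = FALSE)
  if (is.null(properties_em)) properties_em <- properties
  structure(list(tissue_label = tissue_label, properties = properties,
                 properties_em = properties_em,
                 voxel_size_mm = voxel_size_mm,
                 fluor_yield = fluor_yield,
                 fluor_lifetime_ns = fluor_lifetime_ns),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$tissue_label)
  cat(sprintf("<voxel_volume> %d x %d x %d voxels @ %g mm (%g x %g x %g mm), %d tissue type(s), %d fluorescent voxel(s)\n",
              d[1], d[2], d[3], x$voxel_size_mm,
              d[1] * x$voxel_size_mm, d[2] * x$voxel_size_mm,
              d[3] * x$voxel_size_mm,
              length(x$properties), sum(x$fluor_yield > 0)))
  invisible(x)
}

# (mua, mus, g) matrix for the C++ engine
props_matrix <- function(properties) {
  m <- t(vapply(properties, function(p) c(p$mu_a, p$mu_s, p$g), numeric(3)))
  colnames(m) <- c("mua", "mus", "g")
  m
}
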