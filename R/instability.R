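#' Displacement fields of the abdominal wall
#'
#' A displacement field holds the 2-D rest-to-Valsalva displacement of each
#' pixel of a planar abdominal-wall projection (in mm), on an isotropic pixel
#' grid, with an optional region mask restricting analysis to the wall or
#' hernia orifice.  Computing the field from CT images (image registration)
#' is outside this package; fields are inputs or synthesized phantoms
#' ([synth_field()]).
#'
#' @param dx,dy numeric matrices of identical shape: displacement components,
#'   mm.  All values must be finite.
#' @param pixel_spacing_mm isotropic pixel spacing, mm/pixel, > 0.
#' @param mask optional logical matrix, same shape, TRUE where the pixel
#'   belongs to the analysed region (default: everywhere).
#' @return object of class `grip_field`.
#' @export
displacement_field <- function(dx, dy, pixel_spacing_mm = 1, mask = NULL) {
  dx <- as.matrix(dx); dy <- as.matrix(dy)
  if (!all(dim(dx) == dim(dy)))
    stop("data error: dx and dy grids must have the same shape", call. = FALSE)
  if (any(!is.finite(dx)) || any(!is.finite(dy)))
    stop("data error: non-finite displacement values", call. = FALSE)
  if (!is.numeric(pixel_spacing_mm) || length(pixel_spacing_mm) != 1L ||
      !is.finite(pixel_spacing_mm) || pixel_spacing_mm <= 0)
    stop("data error: pixel spacing must be a single positive number", call. = FALSE)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(dx), ncol(dx))
  mask <- as.matrix(mask)
  if (!all(dim(mask) == dim(dx)))
    stop("data error: mask shape differs from the displacement grid", call. = FALSE)
  storage.mode(mask) <- "logical"
  structure(list(dx = dx, dy = dy, pixel_spacing_mm = pixel_spacing_mm,
                 mask = mask), class = "grip_field")
}

#' Per-pixel displacement magnitude
#'
#' Euclidean norm of the displacement vector at every pixel, in mm.
#'
#' @param field a [displacement_field()].
#' @return numeric matrix of magnitudes (mm), non-negative.
#' @export
magnitude_map <- function(field) {
  stopifnot(inherits(field, "grip_field"))
  sqrt(field$dx^2 + field$dy^2)
}

#' Segment the unstable abdominal-wall region
#'
#' A pixel is unstable when its rest-to-Valsalva shift strictly exceeds the
#' threshold (15 mm by default; the same quantity expressed in cm is the
#' tissue distension, so the 15 mm shift criterion and the 1.5 cm stability
#' limit coincide).  Area is pixel count times spacing squared, reported in
#' cm^2; the stability verdict comes from [classify_stability()] applied to
#' the maximum distension over the masked region.
#'
#' @param mag magnitude grid in mm ([magnitude_map()]) or a
#'   [displacement_field()] (magnitudes computed internally, mask honoured).
#' @param pixel_spacing_mm pixel spacing, mm (ignored when `mag` is a field).
#' @param shift_threshold_mm instability threshold on the shift, default 15.
#' @param mask optional logical matrix restricting the analysed region.
#' @return list of class `grip_instability`: `max_distension` (cm),
#'   `unstable_area` (cm^2), `unstable_fraction` (of the masked area),
#'   `stable` (logical), `n_unstable_pixels`.
#' @export
unstable_region <- function(mag, pixel_spacing_mm = 1, shift_threshold_mm = 15,
                            mask = NULL) {
  if (inherits(mag, "grip_field")) {
    if (is.null(mask)) mask <- mag$mask
    pixel_spacing_mm <- mag$pixel_spacing_mm
    mag <- magnitude_map(mag)
  }
  mag <- as.matrix(mag)
  if (any(!is.finite(mag)) || any(mag < 0))
    stop("data error: magnitudes must be finite and non-negative", call. = FALSE)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(mag), ncol(mag))
  m <- mag[mask]
  if (!length(m))
    stop("data error: empty mask", call. = FALSE)
  unstable <- m > shift_threshold_mm
  px_cm2 <- (pixel_spacing_mm / 10)^2
  max_dist_cm <- max(m) / 10
  structure(list(
    max_distension = max_dist_cm,
    unstable_area = sum(unstable) * px_cm2,
    unstable_fraction = mean(unstable),
    stable = classify_stability(max_dist_cm) == "stable",
    n_unstable_pixels = sum(unstable)), class = "grip_instability")
}

#' @export
print.grip_instability <- function(x, ...) {
  cat(sprintf("Abdominal wall instability: %s\n",
              if (x$stable) "stable" else "UNSTABLE"))
  cat(sprintf("  max distension %.2f cm; unstable area %.2f cm^2 (%.1f%% of region)\n",
              x$max_distension, x$unstable_area, 100 * x$unstable_fraction))
  invisible(x)
}

#' Elasticity (strain) map
#'
#' Pointwise engineering strain `(stretched - rest) / rest` between a grid of
#' rest lengths and the corresponding stretched lengths, flagging the
#' high-laxity region where the strain strictly exceeds 20%.
#'
#' @param rest_lengths,stretched_lengths numeric matrices of identical shape;
#'   rest lengths strictly positive.
#' @param strain_threshold flag threshold, default 0.20.
#' @return list with `strain` (matrix, fraction), `flagged` (logical matrix,
#'   strain > threshold), `flagged_fraction`.
#' @export
elasticity_map <- function(rest_lengths, stretched_lengths,
                           strain_threshold = 0.20) {
  rest <- as.matrix(rest_lengths); str <- as.matrix(stretched_lengths)
  if (!all(dim(rest) == dim(str)))
    stop("data error: grids must have the same shape", call. = FALSE)
  if (any(!is.finite(rest)) || any(!is.finite(str)))
    stop("data error: non-finite lengths", call. = FALSE)
  if (any(rest <= 0))
    stop("domain error: rest lengths must be strictly positive", call. = FALSE)
  strain <- (str - rest) / rest
  flagged <- strain > strain_threshold
  list(strain = strain, flagged = flagged, flagged_fraction = mean(flagged))
}

#' Synthesize displacement-field phantoms
#'
#' Seeded, reproducible phantom fields emulating the qualitative patterns of
#' rest-to-Valsalva imaging:
#' * `stable` — smooth low-amplitude random displacement with magnitude
#'   bounded by `amplitude_mm` everywhere (so with `amplitude_mm < 15` the
#'   unstable area is zero by construction);
#' * `focal_laxity` — a noise-free radial Gaussian bump of peak magnitude
#'   `amplitude_mm` and width `sigma_mm` centred in the grid, whose exact
#'   unstable area is the analytic level-set area
#'   `2 * pi * sigma^2 * log(amplitude / threshold)`;
#' * `diffuse_laxity` — smoothed random field rescaled so its maximum
#'   magnitude equals `amplitude_mm`.
#'
#' @param scenario one of `"stable"`, `"focal_laxity"`, `"diffuse_laxity"`.
#' @param size grid side length in pixels (square grid).
#' @param amplitude_mm peak displacement magnitude, mm, >= 0.
#' @param sigma_mm Gaussian bump width for the focal scenario, mm.
#' @param pixel_spacing_mm pixel spacing, mm.
#' @param seed integer RNG seed.
#' @return a [displacement_field()].
#' @export
synth_field <- function(scenario = c("stable", "focal_laxity", "diffuse_laxity"),
                        size = 101, amplitude_mm = 5, sigma_mm = 25,
                        pixel_spacing_mm = 1, seed = 1) {
  scenario <- match.arg(scenario)
  stopifnot(amplitude_mm >= 0, size >= 3, sigma_mm > 0)
  smooth_noise <- function() {
    # separable moving-average smoothing of white noise
    z <- matrix(stats::rnorm(size^2), size, size)
    k <- max(3L, round(size / 10))
    ker <- rep(1 / k, k)
    z <- apply(z, 2, function(col) stats::filter(col, ker, circular = TRUE))
    t(apply(t(z), 2, function(col) stats::filter(col, ker, circular = TRUE)))
  }
  out <- withr_seed(seed, {
    switch(scenario,
      stable = {
        dx <- smooth_noise(); dy <- smooth_noise()
        mag <- sqrt(dx^2 + dy^2)
        scl <- amplitude_mm / max(mag)
        list(dx = dx * scl, dy = dy * scl)
      },
      focal_laxity = {
        ctr <- (size + 1) / 2
        xs <- (seq_len(size) - ctr) * pixel_spacing_mm
        r2 <- outer(xs^2, xs^2, `+`)
        bump <- amplitude_mm * exp(-r2 / (2 * sigma_mm^2))
        list(dx = bump, dy = matrix(0, size, size))
      },
      diffuse_laxity = {
        dx <- smooth_noise(); dy <- smooth_noise()
        mag <- sqrt(dx^2 + dy^2)
        scl <- amplitude_mm / max(mag)
        list(dx = dx * scl, dy = dy * scl)
      })
  })
  displacement_field(out$dx, out$dy, pixel_spacing_mm)
}

# evaluate expr under a local RNG state
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Analytic unstable area of the focal phantom
#'
#' Closed-form level-set area of the radial Gaussian bump used by
#' [synth_field()]: the set where `A * exp(-r^2 / (2 sigma^2)) > T` is a disc
#' of area `2 * pi * sigma^2 * log(A / T)` (zero when `A <= T`), reported in
#' cm^2.
#'
#' @param amplitude_mm,sigma_mm bump peak and width, mm.
#' @param shift_threshold_mm instability threshold, mm.
#' @return area in cm^2.
#' @export
focal_unstable_area <- function(amplitude_mm, sigma_mm, shift_threshold_mm = 15) {
  if (amplitude_mm <= shift_threshold_mm) return(0)
  2 * pi * sigma_mm^2 * log(amplitude_mm / shift_threshold_mm) / 100
}

#' Read and write displacement fields
#'
#' A field is stored as two headerless comma-separated grids (`dx`, `dy`, in
#' mm) plus a JSON sidecar holding `pixel_spacing_mm` and, optionally, the
#' path of a 0/1 mask grid (relative paths resolved against the sidecar's
#' directory).
#'
#' @param dx_path,dy_path CSV grid paths.
#' @param meta_path JSON sidecar path.
#' @return `read_field()` returns a [displacement_field()].
#' @export
read_field <- function(dx_path, dy_path, meta_path) {
  read_grid <- function(p) {
    if (!file.exists(p)) stop("data error: file not found: ", p, call. = FALSE)
    as.matrix(utils::read.table(p, sep = ",", header = FALSE))
  }
  meta <- jsonlite::fromJSON(meta_path)
  mask <- NULL
  if (!is.null(meta$mask_path)) {
    mp <- meta$mask_path
    if (!file.exists(mp)) mp <- file.path(dirname(meta_path), meta$mask_path)
    mask <- read_grid(mp) != 0
  }
  displacement_field(read_grid(dx_path), read_grid(dy_path),
                     pixel_spacing_mm = meta$pixel_spacing_mm, mask = mask)
}

#' @rdname read_field
#' @param field a [displacement_field()].
#' @export
write_field <- function(field, dx_path, dy_path, meta_path) {
  stopifnot(inherits(field, "grip_field"))
  utils::write.table(field$dx, dx_path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(field$dy, dy_path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(pixel_spacing_mm = field$pixel_spacing_mm)
  if (!all(field$mask)) {
    mask_path <- paste0(sub("\\.[^.]*$", "", meta_path), "_mask.csv")
    utils::write.table(field$mask * 1L, mask_path, sep = ",",
                       row.names = FALSE, col.names = FALSE)
    meta$mask_path <- basename(mask_path)
  }
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(meta_path)
}
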