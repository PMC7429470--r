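#' Tissue specification for phantom simulation
#'
#' Describes a homogeneous tissue class by one of the three signal models,
#' its generating parameters, the mean unweighted signal and the fractional
#' voxel-to-voxel variability of each parameter within the tumor.
#'
#' @param model one of `"mono"`, `"biexp"`, `"stretched"`.
#' @param params named list of generating parameters for `model`
#'   (diffusivities in mm^2/s).
#' @param s0_mean mean signal at b = 0, arbitrary units.
#' @param intra_tumor_cv coefficient of variation of the voxelwise parameter
#'   draws (>= 0). Default 0.1: a moderate within-tumor heterogeneity.
#' @return A `tissue_spec` object.
#' @export
#' @examples
#' tissue_spec("mono", list(adc = 1.08e-3))
tissue_spec <- function(model, params, s0_mean = 100, intra_tumor_cv = 0.1) {
  model <- match.arg(model, c("mono", "biexp", "stretched"))
  if (intra_tumor_cv < 0) stop("intra_tumor_cv must be >= 0", call. = FALSE)
  if (s0_mean <= 0) stop("s0_mean must be > 0", call. = FALSE)
  missing_p <- setdiff(model_param_names(model), names(params))
  if (length(missing_p)) {
    stop("missing parameters for model '", model, "': ",
         paste(missing_p, collapse = ", "), call. = FALSE)
  }
  model_signal(model, 0, params, 1)  # runs the parameter validity checks
  structure(list(model = model, params = params, s0_mean = s0_mean,
                 intra_tumor_cv = intra_tumor_cv),
            class = "tissue_spec")
}

# Truncated-normal draws by rejection sampling (no point mass at the bounds).
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(pmin(pmax(mean, lower), upper), n))
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  guard <- 0L
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower | out[bad] > upper]
    guard <- guard + 1L
    if (guard > 10000L) stop("truncation bounds too far from the mean", call. = FALSE)
  }
  out
}

#' Apply Rician noise to magnitude signals
#'
#' Magnitude MRI noise: `sqrt((s + n1)^2 + n2^2)` with `n1, n2 ~ N(0, sigma^2)`,
#' the distribution of the modulus of a complex Gaussian perturbation. At
#' high SNR it converges to additive Gaussian noise; near zero signal it
#' produces the familiar positive noise floor.
#'
#' @param s non-negative signal values.
#' @param sigma Gaussian noise standard deviation per channel.
#' @return Noisy magnitude signals, same shape as `s`.
#' @export
rician_noise <- function(s, sigma) {
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (sigma == 0) return(s)
  sqrt((s + rnorm(length(s), 0, sigma))^2 + rnorm(length(s), 0, sigma)^2)
}

# Ellipsoidal tumor mask centered in the grid; semi-axes scale with the grid
# so the lesion always spans >= 3 axial slices on the default shapes.
ellipsoid_mask <- function(grid_shape, semi_frac = c(0.35, 0.35, 0.38)) {
  ctr <- (grid_shape + 1) / 2
  semi <- pmax(grid_shape * semi_frac, c(1, 1, 1.6))
  idx <- expand.grid(x = seq_len(grid_shape[1]), y = seq_len(grid_shape[2]),
                     z = seq_len(grid_shape[3]))
  d2 <- ((idx$x - ctr[1]) / semi[1])^2 + ((idx$y - ctr[2]) / semi[2])^2 +
        ((idx$z - ctr[3]) / semi[3])^2
  array(d2 <= 1, dim = grid_shape)
}

#' Simulate a multi-b-value DWI phantom volume
#'
#' Builds a 4-D DWI volume containing an ellipsoidal "tumor" of the given
#' tissue class inside a uniform mono-exponential background
#' (ADC = 1.5e-3 mm^2/s). Voxelwise ground-truth parameters are drawn from
#' truncated normal distributions around the tissue parameters with
#' coefficient of variation `intra_tumor_cv`, signals are evaluated with the
#' tissue's forward model, and Rician noise with `sigma = s0_mean / snr` is
#' applied to every voxel. The generating parameter maps are stored so
#' fitted maps can be compared against truth.
#'
#' @param spec a [tissue_spec()].
#' @param grid_shape integer triple, the spatial grid (default 24 x 24 x 7).
#' @param snr signal-to-noise ratio at b = 0; `Inf` disables noise.
#' @param seed integer seed; the volume is fully reproducible from it.
#' @param b_values acquisition scheme (default [default_bvalues()]).
#' @param background_adc ADC of the background tissue, mm^2/s.
#' @return A `dwi_phantom`: list with `image` (4-D array), `mask` (3-D
#'   logical), `b_values`, `truth` (list of 3-D parameter maps, NA outside
#'   the mask), plus the generating spec, snr and seed.
#' @export
#' @examples
#' ph <- make_phantom(tissue_spec("mono", list(adc = 1.08e-3)),
#'                    grid_shape = c(12, 12, 5), snr = 50, seed = 1)
make_phantom <- function(spec, grid_shape = c(24, 24, 7), snr = 50,
                         seed = NULL, b_values = default_bvalues(),
                         background_adc = 1.5e-3) {
  stopifnot(inherits(spec, "tissue_spec"))
  if (!is.numeric(snr) || snr <= 0) stop("snr must be > 0", call. = FALSE)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape < 3)) {
    stop("grid_shape must be three dimensions of at least 3 voxels", call. = FALSE)
  }
  b_values <- unclass(bvalue_scheme(b_values))
  if (!is.null(seed)) set.seed(seed)

  mask <- ellipsoid_mask(grid_shape)
  n_in <- sum(mask)
  if (n_in == 0) stop("tumor mask is empty; enlarge the grid", call. = FALSE)
  z_span <- range(which(apply(mask, 3, any)))
  if (diff(z_span) < 2) {
    stop("tumor mask must span at least 3 axial slices; enlarge the grid",
         call. = FALSE)
  }

  pnames <- model_param_names(spec$model)
  bounds <- list(adc = c(1e-6, Inf), d_slow = c(1e-6, Inf),
                 d_fast = c(1e-6, Inf), f_p = c(0, 1),
                 ddc = c(1e-6, Inf), alpha = c(1e-3, 1))
  truth <- list()
  draws <- list()
  for (p in pnames) {
    mu <- spec$params[[p]]
    v <- rnorm_trunc(n_in, mu, spec$intra_tumor_cv * abs(mu),
                     bounds[[p]][1], bounds[[p]][2])
    draws[[p]] <- v
    m <- array(NA_real_, dim = grid_shape)
    m[mask] <- v
    truth[[p]] <- m
  }
  if (spec$model == "biexp") {
    # keep the compartments ordered voxel by voxel
    swap <- draws$d_fast <= draws$d_slow
    if (any(swap)) {
      draws$d_fast[swap] <- draws$d_slow[swap] * 10
      truth$d_fast[mask] <- draws$d_fast
    }
  }

  nb <- length(b_values)
  image <- array(NA_real_, dim = c(grid_shape, nb))
  decay_bg <- exp(-b_values * background_adc)
  in_idx <- which(mask); out_idx <- which(!mask)
  for (k in seq_len(nb)) {
    plane <- array(0, dim = grid_shape)
    plane[out_idx] <- spec$s0_mean * decay_bg[k]
    sig <- rep(spec$s0_mean, n_in)
    args <- lapply(draws, identity)
    plane[in_idx] <- switch(spec$model,
      mono = sig * exp(-b_values[k] * args$adc),
      biexp = sig * ((1 - args$f_p) * exp(-b_values[k] * args$d_slow) +
                     args$f_p * exp(-b_values[k] * args$d_fast)),
      stretched = sig * exp(-(b_values[k] * args$ddc)^args$alpha))
    image[, , , k] <- plane
  }
  if (is.finite(snr)) {
    sigma <- spec$s0_mean / snr
    image <- array(rician_noise(as.vector(image), sigma),
                   dim = c(grid_shape, nb))
  }
  structure(list(image = image, mask = mask, b_values = b_values,
                 truth = truth, spec = spec, snr = snr, seed = seed),
            class = "dwi_phantom")
}

#' @export
print.dwi_phantom <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("DWI phantom %dx%dx%d, %d b-values, %d tumor voxels, SNR %s\n",
              d[1], d[2], d[3], d[4], sum(x$mask), format(x$snr)))
  invisible(x)
}

#' Write a phantom to NIfTI files with an FSL-style .bval sidecar
#'
#' Writes `<prefix>.nii.gz` (4-D image), `<prefix>_mask.nii.gz`,
#' `<prefix>.bval` (single space-separated line), and one
#' `<prefix>_truth_<param>.nii.gz` per ground-truth map.
#'
#' @param phantom a `dwi_phantom`.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return Named list of the written paths, invisibly.
#' @export
write_phantom <- function(phantom, dir, prefix = "phantom") {
  stopifnot(inherits(phantom, "dwi_phantom"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(
    image = file.path(dir, paste0(prefix, ".nii.gz")),
    mask = file.path(dir, paste0(prefix, "_mask.nii.gz")),
    bval = file.path(dir, paste0(prefix, ".bval"))
  )
  RNifti::writeNifti(RNifti::asNifti(phantom$image), paths$image)
  RNifti::writeNifti(RNifti::asNifti(phantom$mask * 1), paths$mask)
  writeLines(paste(phantom$b_values, collapse = " "), paths$bval)
  for (p in names(phantom$truth)) {
    tp <- file.path(dir, sprintf("%s_truth_%s.nii.gz", prefix, p))
    RNifti::writeNifti(RNifti::asNifti(phantom$truth[[p]]), tp)
    paths[[paste0("truth_", p)]] <- tp
  }
  invisible(paths)
}

#' Read a b-value sidecar file
#'
#' Reads an FSL-style `.bval` file (whitespace-separated values on one line).
#'
#' @param path file path.
#' @return Numeric vector of b-values.
#' @export
read_bval <- function(path) {
  if (!file.exists(path)) stop("bval file not found: ", path, call. = FALSE)
  vals <- tryCatch(
    suppressWarnings(scan(path, what = numeric(), quiet = TRUE)),
    error = function(e) NULL)
  if (is.null(vals) || !length(vals) || anyNA(vals)) {
    stop("could not parse b-values from ", path, call. = FALSE)
  }
  vals
}
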