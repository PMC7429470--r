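#' Fit signal models to every masked voxel of a volume
#'
#' Runs the requested fitters independently on each voxel inside the mask
#' and assembles per-parameter 3-D maps plus convergence-flag grids.
#' Unmasked voxels are left `NA`.
#'
#' @param volume a `dwi_phantom` or a list with elements `image` (4-D
#'   array, 4th dimension indexing b-values), `mask` (3-D logical) and
#'   `b_values`.
#' @param models character subset of `c("mono", "biexp", "stretched")`.
#' @param b_threshold segmentation threshold forwarded to
#'   [fit_biexp_segmented()].
#' @return A `dwi_maps` object: `maps[[model]][[parameter]]` 3-D arrays of
#'   fitted values (diffusivities in mm^2/s), `converged[[model]]` logical
#'   grids, plus the mask and scheme.
#' @export
fit_volume <- function(volume, models = c("mono", "biexp", "stretched"),
                       b_threshold = 200) {
  models <- match.arg(models, c("mono", "biexp", "stretched"),
                      several.ok = TRUE)
  image <- volume$image; mask <- volume$mask; b <- volume$b_values
  if (is.null(image) || is.null(mask) || is.null(b)) {
    stop("volume must provide image, mask and b_values", call. = FALSE)
  }
  d <- dim(image)
  if (length(d) != 4 || d[4] != length(b)) {
    stop(sprintf("scheme/volume mismatch: image has %d b-frames but the scheme has %d b-values",
                 if (length(d) == 4) d[4] else NA_integer_, length(b)),
         call. = FALSE)
  }
  mask <- array(as.logical(mask), dim = d[1:3])
  vox <- which(mask)
  if (!length(vox)) stop("mask is empty: no voxels to fit", call. = FALSE)

  sig <- matrix(image, nrow = prod(d[1:3]), ncol = d[4])[vox, , drop = FALSE]
  out <- list(maps = list(), converged = list(), sse = list(),
              mask = mask, b_values = b)
  for (m in models) {
    pn <- model_param_names(m)
    vals <- matrix(NA_real_, nrow = length(vox), ncol = length(pn),
                   dimnames = list(NULL, pn))
    conv <- logical(length(vox)); ss <- rep(NA_real_, length(vox))
    for (i in seq_along(vox)) {
      fit <- tryCatch({
        dec <- signal_decay(sig[i, ], b)
        if (m == "biexp") fit_biexp_segmented(dec, b_threshold = b_threshold)
        else fit_model(m, dec)
      }, error = function(e) NULL)
      if (!is.null(fit)) {
        vals[i, ] <- unlist(fit$params)[pn]
        conv[i] <- isTRUE(fit$converged)
        ss[i] <- fit$residual_sse
      }
    }
    out$maps[[m]] <- lapply(pn, function(p) {
      a <- array(NA_real_, dim = d[1:3]); a[vox] <- vals[, p]; a
    })
    names(out$maps[[m]]) <- pn
    cg <- array(NA, dim = d[1:3]); cg[vox] <- conv
    out$converged[[m]] <- cg
    sg <- array(NA_real_, dim = d[1:3]); sg[vox] <- ss
    out$sse[[m]] <- sg
  }
  structure(out, class = "dwi_maps")
}

#' Select the three consecutive maximal tumor slices
#'
#' Returns the window of three consecutive axial slices (third array
#' dimension) with the largest total in-mask voxel count, mirroring the ROI
#' protocol of delineating the three consecutive maximal tumor slices. Ties
#' are broken toward the lowest starting slice. If the mask spans fewer than
#' three slices, all spanned slices are returned with a warning.
#'
#' @param mask 3-D logical array.
#' @return Integer vector of slice indices (1-based).
#' @export
#' @examples
#' m <- array(FALSE, c(3, 3, 5))
#' m[2, 2, 2:4] <- TRUE; m[1:3, 1:3, 3] <- TRUE
#' select_slices(m)
select_slices <- function(mask) {
  counts <- apply(mask, 3, sum)
  if (sum(counts) == 0) stop("mask is empty", call. = FALSE)
  spanned <- which(counts > 0)
  span <- range(spanned)
  if (diff(span) < 2) {
    warning(sprintf("mask spans only %d slice(s); using all of them",
                    length(seq(span[1], span[2]))), call. = FALSE)
    return(seq(span[1], span[2]))
  }
  starts <- seq_len(length(counts) - 2)
  window_totals <- counts[starts] + counts[starts + 1] + counts[starts + 2]
  s <- starts[which.max(window_totals)]   # which.max takes the first maximum
  s:(s + 2)
}

#' Mean of a parameter map over an ROI
#'
#' The ROI mean is computed per the three-slice protocol: the in-mask mean
#' of each selected slice is taken first, then the slice means are averaged
#' without weighting (`pooled = FALSE`, the default). `pooled = TRUE`
#' instead averages all in-mask voxels of the selected slices together.
#'
#' @param map 3-D array of parameter values.
#' @param mask 3-D logical array.
#' @param slices slice indices (default: [select_slices()]).
#' @param pooled logical; pool voxels across slices instead of averaging
#'   slice means.
#' @return Scalar mean (NA values inside the mask are dropped).
#' @export
roi_mean <- function(map, mask, slices = select_slices(mask), pooled = FALSE) {
  vals <- lapply(slices, function(z) {
    v <- map[, , z][mask[, , z]]
    v[!is.na(v)]
  })
  if (pooled) return(mean(unlist(vals)))
  mean(vapply(vals, mean, numeric(1)), na.rm = TRUE)
}

#' Summarize fitted parameter maps over the tumor ROI
#'
#' Applies [roi_mean()] to every parameter map of a [fit_volume()] result,
#' excluding non-converged voxels (their count is reported).
#'
#' @param maps a `dwi_maps` object.
#' @param mask ROI mask (default: the mask stored in `maps`).
#' @param slices slice indices (default: [select_slices()] on the mask).
#' @param pooled see [roi_mean()].
#' @return A `roi_summary` data frame with columns `model`, `parameter`,
#'   `value` (diffusivities in mm^2/s), `n_voxels`, `n_excluded`; the slice
#'   window is attached as attribute `slices`.
#' @export
summarize_roi <- function(maps, mask = maps$mask,
                          slices = select_slices(mask), pooled = FALSE) {
  stopifnot(inherits(maps, "dwi_maps"))
  if (any(slices < 1) || any(slices > dim(mask)[3])) {
    stop("slice indices out of bounds", call. = FALSE)
  }
  rows <- list()
  for (m in names(maps$maps)) {
    conv <- maps$converged[[m]]
    roi_conv <- conv[, , slices, drop = FALSE] & mask[, , slices, drop = FALSE]
    n_conv <- sum(roi_conv, na.rm = TRUE)
    n_roi <- sum(mask[, , slices, drop = FALSE])
    if (n_conv == 0) {
      stop(sprintf("all ROI voxels failed to converge for model '%s'", m),
           call. = FALSE)
    }
    for (p in names(maps$maps[[m]])) {
      map <- maps$maps[[m]][[p]]
      map[!conv | is.na(conv)] <- NA_real_   # excluded from the means
      rows[[length(rows) + 1L]] <- data.frame(
        model = m, parameter = p,
        value = roi_mean(map, mask, slices, pooled = pooled),
        n_voxels = n_conv, n_excluded = n_roi - n_conv)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "slices") <- slices
  class(out) <- c("roi_summary", class(out))
  out
}

#' Parameter change between two time-points
#'
#' Computes delta = value(T1) - value(T0) for each parameter shared by two
#' ROI summaries; the sign is preserved (decreases are negative).
#'
#' @param t0,t1 `roi_summary` data frames from [summarize_roi()].
#' @return Data frame with columns `model`, `parameter`, `t0`, `t1`, `delta`.
#' @export
compute_delta <- function(t0, t1) {
  key0 <- paste(t0$model, t0$parameter); key1 <- paste(t1$model, t1$parameter)
  if (!setequal(key0, key1) || length(key0) != length(key1)) {
    stop("time-points carry different parameter sets", call. = FALSE)
  }
  t1 <- t1[match(key0, key1), , drop = FALSE]
  data.frame(model = t0$model, parameter = t0$parameter,
             t0 = t0$value, t1 = t1$value, delta = t1$value - t0$value)
}

#' Write an ROI summary table to CSV in reporting units
#'
#' Diffusivities are converted from mm^2/s to the conventional
#' 1e-3 mm^2/s reporting unit (exactly x1000); `f_p` and `alpha` are
#' unchanged.
#'
#' @param summary a `roi_summary`.
#' @param path output CSV path.
#' @param patient_id,timepoint identifiers written into the table.
#' @export
write_roi_summary <- function(summary, path, patient_id = "P001",
                              timepoint = "T0") {
  diff_par <- summary$parameter %in% c("adc", "d_slow", "d_fast", "ddc")
  out <- data.frame(patient_id = patient_id, timepoint = timepoint,
                    parameter = summary$parameter,
                    value = ifelse(diff_par, summary$value * 1e3, summary$value),
                    n_voxels = summary$n_voxels)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
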