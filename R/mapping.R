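# ROI extraction, background masking, pixel-wise prediction and rendering.

#' Extract ROI-mean spectra from a hypercube
#'
#' One spectrum per region of interest (pixel mean over a square block) plus
#' the grand mean across ROIs as the sample spectrum — the standard scheme of
#' averaging 10 symmetrically placed ROIs per image.
#'
#' @param cube a `hyper_cube`.
#' @param roi_centers two-column matrix/data frame of (row, col) centers.
#' @param roi_size odd block side length in pixels.
#' @return `spectra_set` with one row per ROI (`roi_id` "roi01", ...) and a
#'   final `sample_mean` row.
#' @export
extract_roi_spectra <- function(cube, roi_centers, roi_size = 5) {
  stopifnot(inherits(cube, "hyper_cube"))
  rc <- as.matrix(roi_centers)
  if (roi_size %% 2 == 0 || roi_size < 1) stop("`roi_size` must be odd.", call. = FALSE)
  h <- dim(cube$values)[1]; w <- dim(cube$values)[2]
  half <- (roi_size - 1) / 2
  spectra <- matrix(0, nrow(rc), length(cube$grid))
  for (i in seq_len(nrow(rc))) {
    r0 <- rc[i, 1] - half; r1 <- rc[i, 1] + half
    c0 <- rc[i, 2] - half; c1 <- rc[i, 2] + half
    if (r0 < 1 || c0 < 1 || r1 > h || c1 > w) {
      stop(sprintf("ROI %d at (%d, %d) falls outside the %d x %d frame.",
                   i, rc[i, 1], rc[i, 2], h, w), call. = FALSE)
    }
    block <- cube$values[r0:r1, c0:c1, , drop = FALSE]
    spectra[i, ] <- apply(block, 3, mean)
  }
  values <- rbind(spectra, colMeans(spectra))
  meta <- tibble::tibble(
    spectrum_id = c(sprintf("roi%02d", seq_len(nrow(rc))), "sample_mean"),
    kind = c(rep("roi", nrow(rc)), "sample_mean")
  )
  spectra_set(values, cube$grid, meta, quantity = "reflectance")
}

# Otsu's threshold on a numeric vector: maximizes between-class variance over
# a 256-bin histogram. Returns the threshold and the achieved criterion.
otsu_threshold <- function(v, n_bins = 256) {
  rng <- range(v)
  if (diff(rng) == 0) return(list(threshold = rng[1], between_var = 0))
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(v, breaks, all.inside = TRUE), n_bins)
  pr <- h / sum(h)
  mids <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  w0 <- cumsum(pr)
  mu <- cumsum(pr * mids)
  mu_t <- mu[n_bins]
  bv <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  bv[!is.finite(bv)] <- 0
  k <- which.max(bv)
  list(threshold = mids[k], between_var = bv[k])
}

#' Binarize a cube into tea and background pixels
#'
#' Otsu thresholding on a single contrast-band image. When `contrast_band` is
#' missing, the band whose image maximizes the Otsu between-class variance is
#' chosen automatically. The tea class is the one with the lower mean
#' reflectance (the background reference panel is bright). Isolated pixels
#' are removed by a 3 x 3 majority vote. A near-unimodal image (empty or full
#' mask) triggers a warning.
#'
#' @param cube a `hyper_cube`.
#' @param contrast_band optional band index.
#' @param cleanup apply the 3 x 3 majority filter (default TRUE).
#' @return logical matrix, TRUE = tea.
#' @export
background_mask <- function(cube, contrast_band = NULL, cleanup = TRUE) {
  stopifnot(inherits(cube, "hyper_cube"))
  nb <- dim(cube$values)[3]
  if (is.null(contrast_band)) {
    bv <- vapply(seq_len(nb), function(b) {
      otsu_threshold(as.vector(cube$values[, , b]))$between_var
    }, numeric(1))
    contrast_band <- which.max(bv)
  }
  if (contrast_band < 1 || contrast_band > nb) {
    stop("`contrast_band` outside the grid.", call. = FALSE)
  }
  img <- cube$values[, , contrast_band]
  ot <- otsu_threshold(as.vector(img))
  low <- img <= ot$threshold
  # tea = class with lower mean reflectance at the contrast band
  mask <- if (!any(low) || !any(!low)) {
    matrix(FALSE, nrow(img), ncol(img))
  } else if (mean(img[low]) < mean(img[!low])) low else !low
  if (cleanup) mask <- majority_filter(mask)
  if (all(mask) || !any(mask)) {
    warning("contrast-band image looks unimodal: mask is ",
            if (any(mask)) "full." else "empty.", call. = FALSE)
  }
  mask
}

# 3x3 neighborhood cleanup: drop isolated tea pixels (< 2 tea neighbors) and
# fill pinholes (background with >= 7 tea neighbors); region shapes, including
# corners, are preserved
majority_filter <- function(mask) {
  m <- mask * 1
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(0, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- m
  pad[1, ] <- pad[2, ]; pad[h + 2, ] <- pad[h + 1, ]
  pad[, 1] <- pad[, 2]; pad[, w + 2] <- pad[, w + 1]
  acc <- matrix(0, h, w)
  for (di in 0:2) for (dj in 0:2) {
    acc <- acc + pad[(1 + di):(h + di), (1 + dj):(w + dj)]
  }
  neigh <- acc - m  # tea neighbors excluding self
  (mask & neigh >= 2) | (!mask & neigh >= 7)
}

#' Pixel-wise content prediction over a masked cube
#'
#' Tea pixels are flattened to spectra, pushed through the trained
#' preprocessing chain (with its stored calibration statistics), reduced to
#' the selected bands, projected with the calibration PCA and predicted by
#' the fitted model. Background pixels are exactly 0; negative predictions
#' are clipped to 0 and counted.
#'
#' @param cube a `hyper_cube` on the training grid.
#' @param mask logical tea mask (e.g. from [background_mask()]).
#' @param chain fitted `preproc_chain`.
#' @param selection the `selection_result` used in training.
#' @param pca the `tea_pca` used in training (its subset must equal the
#'   selection's indices).
#' @param model fitted model (`tea_pls`, `tea_elm` or `tea_svr`).
#' @param component component name carried into the result.
#' @return object of class `pixel_map`: list with `values` (matrix, % dry
#'   mass, background 0), `mask`, `component`, `n_clipped`.
#' @export
predict_map <- function(cube, mask, chain, selection, pca, model,
                        component = "content") {
  stopifnot(inherits(cube, "hyper_cube"), inherits(selection, "selection_result"),
            inherits(pca, "tea_pca"))
  nb <- dim(cube$values)[3]
  if (selection$n_bands != nb ||
      !isTRUE(all.equal(as.numeric(cube$grid)[selection$indices],
                        selection$selected_nm))) {
    stop("cube grid does not match the grid the model was trained on.",
         call. = FALSE)
  }
  if (!identical(pca$subset, selection$indices)) {
    stop("PCA subset and selection indices disagree.", call. = FALSE)
  }
  idx <- which(mask)
  values <- matrix(0, nrow(mask), ncol(mask))
  n_clipped <- 0L
  if (length(idx) > 0) {
    flat <- matrix(cube$values, ncol = nb)  # (h*w) x bands, column-major pixels
    pix <- flat[idx, , drop = FALSE]
    pp <- apply_preproc_chain(pix, chain)
    scores <- project_pca(pca, pp)
    pred <- predict(model, scores)
    n_clipped <- sum(pred < 0)
    values[idx] <- pmax(pred, 0)
  }
  structure(list(values = values, mask = mask, component = component,
                 n_clipped = n_clipped),
            class = "pixel_map")
}

#' @export
print.pixel_map <- function(x, ...) {
  tea <- x$values[x$mask]
  cat(sprintf("<pixel_map> %s: %d x %d px, %d tea px, range %.4g-%.4g\n",
              x$component, nrow(x$values), ncol(x$values), sum(x$mask),
              if (length(tea)) min(tea) else NA, if (length(tea)) max(tea) else NA))
  invisible(x)
}

#' Render a pixel map to a PNG file
#'
#' The color scale spans the tea-pixel min/max (or a fixed `limits` range for
#' cross-stage comparison); background pixels use a reserved dark color.
#' Deterministic: the same map renders to a byte-identical file.
#'
#' @param map a `pixel_map`.
#' @param out_path output PNG path.
#' @param palette a grDevices palette name (default "viridis").
#' @param limits optional fixed c(min, max) content scale.
#' @return the output path, invisibly; attribute "scale" carries the limits.
#' @export
render_map <- function(map, out_path, palette = "viridis", limits = NULL) {
  stopifnot(inherits(map, "pixel_map"))
  if (!all(is.finite(map$values))) stop("map must be finite.", call. = FALSE)
  tea <- map$values[map$mask]
  if (is.null(limits)) {
    limits <- if (length(tea) == 0) c(0, 1) else range(tea)
  }
  cols <- grDevices::hcl.colors(256, palette)
  rgbm <- grDevices::col2rgb(cols) / 255
  h <- nrow(map$values); w <- ncol(map$values)
  img <- array(0.12, dim = c(h, w, 3))  # reserved background
  if (length(tea) > 0) {
    span <- limits[2] - limits[1]
    rel <- if (span == 0) rep(0.5, length(tea)) else
      pmin(pmax((tea - limits[1]) / span, 0), 1)
    ci <- pmin(255L, as.integer(rel * 255)) + 1L
    idx <- which(map$mask)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[idx] <- rgbm[ch, ci]
      img[, , ch] <- plane
    }
  }
  png::writePNG(img, out_path)
  attr(out_path, "scale") <- limits
  invisible(out_path)
}

#' Plot a pixel map
#' @param object a `pixel_map`.
#' @param ... unused.
#' @export
autoplot.pixel_map <- function(object, ...) {
  df <- tibble::tibble(
    row = as.vector(row(object$values)),
    col = as.vector(col(object$values)),
    content = ifelse(as.vector(object$mask), as.vector(object$values), NA)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$content)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey20",
                                  name = "% dry mass") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = object$component, x = NULL, y = NULL)
}
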