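# Morphological and spatial quantification of instance masks: per-cell
# records by connected-region analysis, then six summary metrics
# (mean nearest-neighbour distance, compactness, density, distribution
# heterogeneity, shape complexity, edge contrast).

#' Per-cell records from an instance mask
#'
#' Connected-region analysis of the label image: for each positive label,
#' area (pixel count), perimeter, and centroid. The perimeter convention is
#' the count of pixel edges between the cell and any non-cell pixel
#' (4-neighbourhood; pixels on the image border contribute their outside
#' edges), which is exactly `4s` for an `s` x `s` square. Centroids are the
#' mean of the cell's 0-based pixel coordinates, `x` = column, `y` = row.
#'
#' @param mask Integer instance mask (0 = background).
#' @return Data frame with columns `label`, `area_px2`, `perimeter_px`,
#'   `centroid_x`, `centroid_y`; zero rows for an empty mask.
#' @export
extract_cell_records <- function(mask) {
  check_mask(mask)
  idx <- which(mask > 0)
  empty <- data.frame(label = numeric(0), area_px2 = numeric(0),
                      perimeter_px = numeric(0),
                      centroid_x = numeric(0), centroid_y = numeric(0))
  if (!length(idx)) return(empty)
  h <- nrow(mask); w <- ncol(mask)
  lab <- mask[idx]
  r <- ((idx - 1L) %% h) + 1L
  cc <- ((idx - 1L) %/% h) + 1L
  labels <- sort(unique(lab))
  li <- match(lab, labels)
  area <- tabulate(li, nbins = length(labels))
  cx <- rowsum(cc - 1, li)[, 1] / area   # 0-based column = x
  cy <- rowsum(r - 1, li)[, 1] / area    # 0-based row = y
  # perimeter: for each 4-direction, neighbour label (out of bounds = -1)
  perim <- numeric(length(labels))
  for (o in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
    r2 <- r + o[1]; c2 <- cc + o[2]
    inside <- r2 >= 1L & r2 <= h & c2 >= 1L & c2 <= w
    nb <- rep(-1, length(idx))
    nb[inside] <- mask[(c2[inside] - 1L) * h + r2[inside]]
    edge <- nb != lab
    if (any(edge)) {
      add <- rowsum(as.numeric(edge), li)
      perim[as.integer(rownames(add))] <- perim[as.integer(rownames(add))] + add[, 1]
    }
  }
  data.frame(label = labels, area_px2 = as.numeric(area),
             perimeter_px = perim, centroid_x = as.numeric(cx),
             centroid_y = as.numeric(cy))
}

#' Spatial arrangement metrics from cell records
#'
#' From per-cell centroids and areas, computes:
#' \describe{
#'   \item{mean_distance}{mean over cells of the nearest-neighbour centroid
#'     distance \eqn{d_{min,i}} (Euclidean). Needs N >= 2.}
#'   \item{compactness}{\eqn{(\mathrm{mean\ distance})^2 / \bar A}, the
#'     squared mean nearest-neighbour distance normalised by mean cell area.}
#'   \item{density}{\eqn{N / A_{total}}, cells per image pixel, where
#'     \eqn{A_{total}} is the full image pixel count.}
#'   \item{distribution}{coefficient of variation (population sd / mean) of
#'     the local densities \eqn{3 / D_{i,3}}, where \eqn{D_{i,3}} is the sum
#'     of cell i's three smallest neighbour distances. Needs N >= 4.}
#' }
#' Metrics whose minimum N is not met are returned as `NA` with a reason in
#' the `flags` element, never silently zero.
#'
#' @param records Data frame from [extract_cell_records()].
#' @param image_area_px Total image pixel count \eqn{A_{total}}.
#' @return List with `mean_distance`, `compactness`, `density`,
#'   `distribution`, and `flags` (named character vector of reasons for any
#'   undefined metric).
#' @export
spatial_metrics <- function(records, image_area_px) {
  n <- nrow(records)
  flags <- character(0)
  density <- if (n > 0) n / image_area_px else NA_real_
  if (n == 0) flags["density"] <- "no cells"
  mean_distance <- compactness <- distribution <- NA_real_
  if (n >= 2) {
    dmat <- as.matrix(stats::dist(records[, c("centroid_x", "centroid_y")]))
    diag(dmat) <- Inf
    d_min <- apply(dmat, 1, min)
    mean_distance <- mean(d_min)
    compactness <- mean_distance^2 / mean(records$area_px2)
    if (n >= 4) {
      d3 <- apply(dmat, 1, function(z) sum(sort(z)[1:3]))
      local_density <- 3 / d3
      mu <- mean(local_density)
      sigma <- sqrt(mean((local_density - mu)^2))  # population sd
      distribution <- sigma / mu
    } else {
      flags["distribution"] <- "fewer than 4 cells (needs 3 nearest neighbours)"
    }
  } else {
    flags["mean_distance"] <- "fewer than 2 cells"
    flags["compactness"] <- "fewer than 2 cells"
    flags["distribution"] <- "fewer than 4 cells (needs 3 nearest neighbours)"
  }
  list(mean_distance = mean_distance, compactness = compactness,
       density = density, distribution = distribution, flags = flags)
}

#' Shape complexity of a cell population
#'
#' `mean(P^2) / mean(A)`: the mean squared perimeter divided by the mean
#' area. Under the pixel-edge perimeter convention, identical squares give
#' exactly 16; irregular boundaries push the value higher. Note this is the
#' ratio of means, not the mean of per-cell ratios.
#'
#' @param records Data frame from [extract_cell_records()].
#' @return A single numeric; `NA` with a warning-free flag when no cells.
#' @export
shape_complexity <- function(records) {
  if (nrow(records) == 0) return(NA_real_)
  mean(records$perimeter_px^2) / mean(records$area_px2)
}

# 3x3 Sobel gradient magnitude with mirrored borders (1-pixel pad, the
# border row/column reflected onto itself).
sobel_magnitude <- function(gray) {
  h <- nrow(gray); w <- ncol(gray)
  ri <- c(1L, seq_len(h), h)
  ci <- c(1L, seq_len(w), w)
  p <- gray[ri, ci]
  # neighbourhood slices of the padded image, centred on each pixel
  nw <- p[1:h, 1:w];         nn <- p[1:h, 2:(w + 1)];         ne <- p[1:h, 3:(w + 2)]
  ww <- p[2:(h + 1), 1:w];                                   ee <- p[2:(h + 1), 3:(w + 2)]
  sw <- p[3:(h + 2), 1:w];   ss <- p[3:(h + 2), 2:(w + 1)];   se <- p[3:(h + 2), 3:(w + 2)]
  gx <- (ne + 2 * ee + se) - (nw + 2 * ww + sw)
  gy <- (sw + 2 * ss + se) - (nw + 2 * nn + ne)
  sqrt(gx^2 + gy^2)
}

# Binary dilation by the 4-connected cross, n times (grows the city-block
# distance-1 neighbourhood per application).
dilate4 <- function(fg, n = 1L) {
  h <- nrow(fg); w <- ncol(fg)
  for (k in seq_len(n)) {
    out <- fg
    out[-1, ] <- out[-1, ] | fg[-h, ]
    out[-h, ] <- out[-h, ] | fg[-1, ]
    out[, -1] <- out[, -1] | fg[, -w]
    out[, -w] <- out[, -w] | fg[, -1]
    fg <- out
  }
  fg
}

#' Edge contrast between cell boundaries and background
#'
#' Ratio of the mean Sobel gradient magnitude over cell-edge pixels to that
#' over background pixels. Edge pixels are cell pixels with at least one
#' 4-neighbour of a different label (background counts; so do image
#' borders). Background pixels are label-0 pixels at city-block distance
#' greater than 2 from any cell — the 2-pixel exclusion ring keeps
#' cell-edge gradients from bleeding into the background estimate. RGB
#' images are converted to luminance grayscale first.
#'
#' @param image Intensity image matching the mask.
#' @param mask Instance mask.
#' @return List with `edge_contrast` (numeric or `NA`) and `flags`.
#' @export
edge_contrast <- function(image, mask) {
  check_image(image); check_mask(mask)
  gray <- to_gray(image)
  if (!identical(dim(gray), dim(mask))) stop("image and mask shapes differ")
  if (!any(mask > 0)) {
    return(list(edge_contrast = NA_real_, flags = c(edge_contrast = "no cells")))
  }
  grad <- sobel_magnitude(gray)
  h <- nrow(mask); w <- ncol(mask)
  idx <- which(mask > 0)
  r <- ((idx - 1L) %% h) + 1L
  cc <- ((idx - 1L) %/% h) + 1L
  lab <- mask[idx]
  is_edge <- rep(FALSE, length(idx))
  for (o in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
    r2 <- r + o[1]; c2 <- cc + o[2]
    inside <- r2 >= 1L & r2 <= h & c2 >= 1L & c2 <= w
    nb <- rep(-1, length(idx))
    nb[inside] <- mask[(c2[inside] - 1L) * h + r2[inside]]
    is_edge <- is_edge | nb != lab
  }
  bg_ok <- !dilate4(mask > 0, 2L) & mask == 0
  if (!any(bg_ok)) {
    return(list(edge_contrast = NA_real_,
                flags = c(edge_contrast = "no background beyond the 2-px exclusion ring")))
  }
  mu_cell <- mean(grad[idx[is_edge]])
  mu_bg <- mean(grad[bg_ok])
  if (mu_bg == 0) {
    return(list(edge_contrast = NA_real_,
                flags = c(edge_contrast = "background gradient is zero (uniform background)")))
  }
  list(edge_contrast = mu_cell / mu_bg, flags = character(0))
}

#' Six-metric morphology report for one image/mask pair
#'
#' Bundles cell count, the four spatial metrics, shape complexity and edge
#' contrast into one report row. Undefined metrics are `NA` and explained in
#' the `flags` attribute.
#'
#' @param image Intensity image.
#' @param mask Instance mask of the same height/width.
#' @param image_id Optional identifier.
#' @return An object of class `morpho_report`: one-row data frame with
#'   columns image_id, n_cells, mean_distance, compactness, density,
#'   distribution, shape_complexity, edge_contrast, flags (semicolon-joined
#'   reasons), plus a `flags` attribute with the named vector.
#' @export
morpho_report <- function(image, mask, image_id = NA_character_) {
  records <- extract_cell_records(mask)
  sp <- spatial_metrics(records, image_area_px = prod(dim(mask)))
  sc <- shape_complexity(records)
  ec <- edge_contrast(image, mask)
  flags <- c(sp$flags, ec$flags)
  if (nrow(records) == 0) flags["shape_complexity"] <- "no cells"
  out <- data.frame(
    image_id = image_id, n_cells = nrow(records),
    mean_distance = sp$mean_distance, compactness = sp$compactness,
    density = sp$density, distribution = sp$distribution,
    shape_complexity = sc, edge_contrast = ec$edge_contrast,
    flags = if (length(flags)) paste(names(flags), flags, sep = ": ", collapse = "; ") else "",
    stringsAsFactors = FALSE)
  attr(out, "flags") <- flags
  class(out) <- c("morpho_report", "data.frame")
  out
}

#' Write morphology reports to CSV
#'
#' @param reports A `morpho_report` or list of them.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_morphology <- function(reports, path) {
  if (inherits(reports, "morpho_report")) reports <- list(reports)
  df <- do.call(rbind, lapply(reports, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
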