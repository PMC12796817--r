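# Deterministic synthetic tissue generator: paired intensity image,
# instance mask and expression point table emulating two staining regimes —
# dense, tightly packed, low-contrast tissue (hippocampus-like) and sparse,
# well-separated, high-contrast tissue.

#' Parameters for the synthetic tissue generator
#'
#' The two regimes differ in packing and contrast: `dense_lowcontrast`
#' places cells with small inter-cell gaps and a foreground/background
#' intensity gap of 3x the noise standard deviation;
#' `sparse_highcontrast` uses wide gaps and a 10x gap. Intensities are on
#' a 0..255 scale with additive Gaussian noise clipped to range.
#'
#' @param height,width Image size in pixels (>= 64).
#' @param n_cells Number of cells to place.
#' @param radius_range Min/max ellipse semi-axis, pixels (min >= 2).
#' @param regime `"dense_lowcontrast"` or `"sparse_highcontrast"`.
#' @param overlap_allowed Allow cells to overlap (later cells overwrite).
#' @param noise_sd Gaussian noise standard deviation, intensity units.
#' @param n_genes Number of genes in the expression fixture.
#' @param points_per_cell Expression points sampled inside each cell.
#' @param background_point_fraction Background points as a fraction of
#'   total in-cell points, in `[0, 1]`.
#' @param seed Integer seed; identical parameters give identical fixtures.
#' @return A `synth_params` list.
#' @export
synth_params <- function(height = 256, width = 256, n_cells = 50,
                         radius_range = c(4, 8),
                         regime = c("sparse_highcontrast", "dense_lowcontrast"),
                         overlap_allowed = FALSE, noise_sd = 8,
                         n_genes = 20, points_per_cell = 10,
                         background_point_fraction = 0.1, seed = 0) {
  regime <- match.arg(regime)
  if (height < 64 || width < 64) stop("image dimensions must be >= 64")
  if (radius_range[1] < 2) stop("minimum radius must be >= 2")
  if (n_cells < 0) stop("n_cells must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(height = height, width = width, n_cells = n_cells,
                 radius_range = radius_range, regime = regime,
                 overlap_allowed = overlap_allowed, noise_sd = noise_sd,
                 n_genes = n_genes, points_per_cell = points_per_cell,
                 background_point_fraction = background_point_fraction,
                 seed = seed),
            class = "synth_params")
}

# Pixels inside a rotated ellipse centred at (cx, cy) (0-based coords).
ellipse_pixels <- function(cx, cy, a, b, theta, h, w) {
  rmax <- ceiling(max(a, b))
  rows <- max(0, floor(cy - rmax)):min(h - 1, ceiling(cy + rmax))
  cols <- max(0, floor(cx - rmax)):min(w - 1, ceiling(cx + rmax))
  gr <- expand.grid(r = rows, cc = cols)
  dx <- gr$cc - cx; dy <- gr$r - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  cbind(row = gr$r[inside] + 1L, col = gr$cc[inside] + 1L)
}

#' Generate a synthetic tissue image, instance mask and ground truth
#'
#' Elliptical cells are placed by rejection sampling. Unless
#' `overlap_allowed`, a candidate is rejected if any of its pixels — grown
#' by a regime-dependent gap margin (1 px dense, 4 px sparse) — touches an
#' existing cell. Cell interiors are brighter than background by
#' 3x `noise_sd` (dense regime) or 10x `noise_sd` (sparse); Gaussian noise
#' is added and clipped to 0..255. The planted per-cell records (area,
#' perimeter, centroid) are returned as ground truth.
#'
#' @param params A [synth_params()] object.
#' @return List with `image` (numeric matrix), `mask` (instance mask) and
#'   `records` (planted cell records as from [extract_cell_records()]).
#' @export
generate_tissue <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  h <- params$height; w <- params$width
  mask <- matrix(0, h, w)
  margin <- if (params$regime == "dense_lowcontrast") 1L else 4L
  gap_mult <- if (params$regime == "dense_lowcontrast") 3 else 10
  with_seed(params$seed, {
    placed <- 0L
    tries <- 0L
    max_tries <- 200L * max(1L, params$n_cells)
    while (placed < params$n_cells && tries < max_tries) {
      tries <- tries + 1L
      a <- stats::runif(1, params$radius_range[1], params$radius_range[2])
      b <- stats::runif(1, params$radius_range[1], params$radius_range[2])
      theta <- stats::runif(1, 0, pi)
      rmax <- max(a, b)
      cx <- stats::runif(1, rmax + 1, w - rmax - 2)
      cy <- stats::runif(1, rmax + 1, h - rmax - 2)
      px <- ellipse_pixels(cx, cy, a, b, theta, h, w)
      if (!nrow(px)) next
      if (!params$overlap_allowed) {
        halo <- ellipse_pixels(cx, cy, a + margin, b + margin, theta, h, w)
        if (any(mask[halo] > 0)) next
      }
      placed <- placed + 1L
      mask[px] <- placed
    }
    if (placed < params$n_cells) {
      stop(sprintf(paste0("placed only %d of %d cells after %d tries; ",
                          "reduce n_cells or the radius range"),
                   placed, params$n_cells, tries))
    }
    bg_level <- 60
    fg_level <- bg_level + gap_mult * params$noise_sd
    image <- matrix(bg_level, h, w)
    image[mask > 0] <- fg_level
    if (params$noise_sd > 0) {
      image <- image + matrix(stats::rnorm(h * w, 0, params$noise_sd), h, w)
    }
    image <- pmin(pmax(image, 0), 255)
    list(image = image, mask = mask, records = extract_cell_records(mask))
  })
}

#' Perturb an instance mask with known edits
#'
#' Introduces controlled under- and over-segmentation for evaluation tests:
#' deletes `floor(drop_fraction * N)` cells (known false negatives), splits
#' `floor(split_fraction * N)` of the remaining cells in two along their
#' centroid column (known extra predictions), and shifts each remaining
#' cell by up to `shift_px` pixels in each axis. Returns the edited mask
#' plus a ledger of the applied edits.
#'
#' @param mask Instance mask.
#' @param drop_fraction,split_fraction Fractions of cells in `[0, 1]`.
#' @param shift_px Maximum per-axis shift, pixels.
#' @param seed Integer seed.
#' @return List with `mask` and `ledger` (lists `dropped`, `split`,
#'   `shifts`: labels dropped, labels split, per-label shift vectors).
#' @export
perturb_mask <- function(mask, drop_fraction = 0, split_fraction = 0,
                         shift_px = 0, seed = 0) {
  check_mask(mask)
  labels <- sort(setdiff(unique(as.vector(mask)), 0))
  n <- length(labels)
  with_seed(seed, {
    out <- mask
    n_drop <- floor(drop_fraction * n)
    dropped <- if (n_drop > 0) sort(sample(labels, n_drop)) else numeric(0)
    out[out %in% dropped] <- 0
    remaining <- setdiff(labels, dropped)
    n_split <- min(length(remaining), floor(split_fraction * n))
    split <- if (n_split > 0) sort(sample(remaining, n_split)) else numeric(0)
    next_label <- max(labels) + 1
    h <- nrow(out); w <- ncol(out)
    for (lb in split) {
      idx <- which(out == lb)
      cols <- ((idx - 1L) %/% h) + 1L
      right <- idx[cols > mean(cols)]
      if (length(right) > 0 && length(right) < length(idx)) {
        out[right] <- next_label
        next_label <- next_label + 1
      }
    }
    shifts <- list()
    if (shift_px > 0) {
      shifted <- matrix(0, h, w)
      for (lb in setdiff(sort(unique(as.vector(out))), 0)) {
        dx <- sample(-shift_px:shift_px, 1)
        dy <- sample(-shift_px:shift_px, 1)
        idx <- which(out == lb)
        r <- ((idx - 1L) %% h) + 1L + dy
        cc <- ((idx - 1L) %/% h) + 1L + dx
        ok <- r >= 1L & r <= h & cc >= 1L & cc <= w
        shifted[(cc[ok] - 1L) * h + r[ok]] <- lb
        shifts[[as.character(lb)]] <- c(dx = dx, dy = dy)
      }
      out <- shifted
    }
    list(mask = out,
         ledger = list(dropped = dropped, split = split, shifts = shifts))
  })
}

#' Generate a synthetic expression point table for a mask
#'
#' Samples `points_per_cell` points uniformly (with replacement) from each
#' cell's pixels, assigns gene identities from a seeded categorical
#' distribution, and adds background points on label-0 pixels at
#' `background_point_fraction` of the total in-cell points. Per-point
#' counts are drawn uniformly from 1..3. The planted per-cell totals are
#' returned for conservation tests.
#'
#' @param mask Instance mask.
#' @param params A [synth_params()] object (uses `n_genes`,
#'   `points_per_cell`, `background_point_fraction`, `seed`).
#' @return List with `points` (GEM-style data frame, 0-based x/y),
#'   `cell_totals` (named numeric: planted total count per cell label) and
#'   `background_total`.
#' @export
generate_expression <- function(mask, params) {
  check_mask(mask)
  if (params$n_genes < 1) stop("n_genes must be >= 1")
  genes <- sprintf("gene%03d", seq_len(params$n_genes))
  h <- nrow(mask)
  labels <- sort(setdiff(unique(as.vector(mask)), 0))
  with_seed(params$seed + 1L, {
    gene_probs <- stats::runif(params$n_genes)
    gene_probs <- gene_probs / sum(gene_probs)
    rows <- list()
    for (lb in labels) {
      idx <- which(mask == lb)
      pick <- idx[sample.int(length(idx), params$points_per_cell, replace = TRUE)]
      rows[[as.character(lb)]] <- data.frame(
        gene_id = sample(genes, params$points_per_cell, replace = TRUE,
                         prob = gene_probs),
        x = ((pick - 1L) %/% h),
        y = ((pick - 1L) %% h),
        count = sample(1:3, params$points_per_cell, replace = TRUE),
        label = lb)
    }
    pts <- do.call(rbind, rows)
    n_bg <- round(params$background_point_fraction *
                    length(labels) * params$points_per_cell)
    bg_idx <- which(mask == 0)
    if (n_bg > 0 && length(bg_idx)) {
      pick <- bg_idx[sample.int(length(bg_idx), n_bg, replace = TRUE)]
      bg <- data.frame(
        gene_id = sample(genes, n_bg, replace = TRUE, prob = gene_probs),
        x = ((pick - 1L) %/% h),
        y = ((pick - 1L) %% h),
        count = sample(1:3, n_bg, replace = TRUE),
        label = 0)
      pts <- rbind(pts, bg)
    }
    if (is.null(pts)) {
      pts <- data.frame(gene_id = character(0), x = numeric(0),
                        y = numeric(0), count = numeric(0), label = numeric(0))
    }
    rownames(pts) <- NULL
    cell_totals <- if (length(labels)) {
      stats::setNames(as.numeric(rowsum(pts$count[pts$label > 0],
                                        pts$label[pts$label > 0])[, 1]),
                      as.character(labels))
    } else stats::setNames(numeric(0), character(0))
    list(points = pts[, c("gene_id", "x", "y", "count")],
         cell_totals = cell_totals,
         background_total = sum(pts$count[pts$label == 0]))
  })
}

#' Write a full synthetic fixture to disk
#'
#' Writes `image.tif`, `mask.tif`, `expr.gem` and `truth.json` (planted
#' records and expression totals) into a directory.
#'
#' @param params A [synth_params()] object.
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_fixture <- function(params, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  tissue <- generate_tissue(params)
  expr <- generate_expression(tissue$mask, params)
  write_image(tissue$image, file.path(out_dir, "image.tif"))
  write_mask(tissue$mask, file.path(out_dir, "mask.tif"))
  write_gem(expr$points, file.path(out_dir, "expr.gem"))
  jsonlite::write_json(
    list(params = unclass(params),
         records = tissue$records,
         cell_totals = as.list(expr$cell_totals),
         background_total = expr$background_total),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
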