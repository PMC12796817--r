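# Training-set preparation: patch cropping, reflection padding,
# semantic-to-instance conversion, grouped train/validation lists.

#' Crop fixed-size patches from a whole-tissue image
#'
#' Tiles the image with `patch_size` x `patch_size` windows at the given
#' stride, starting at the top-left corner. Partial windows at the right and
#' bottom edges are dropped, so every returned patch has the full size and a
#' recorded origin traceable to whole-slide coordinates. If a paired label
#' mask is supplied it is cropped with identical windows.
#'
#' @param image Numeric matrix (grayscale) or H x W x 3 array.
#' @param mask Optional integer label mask of the same height/width.
#' @param patch_size Side length of the square patches, in pixels.
#' @param stride Step between window origins, in pixels (>= 1). Strides
#'   smaller than `patch_size` produce overlapping patches.
#' @return A list of patches; each element has `image`, `mask` (or `NULL`),
#'   and `origin`, the 0-based `(row, col)` of the patch's top-left pixel.
#' @examples
#' img <- matrix(runif(64 * 64), 64, 64)
#' ps <- crop_patches(img, patch_size = 32, stride = 32)
#' length(ps)  # 4
#' @export
crop_patches <- function(image, mask = NULL, patch_size, stride = patch_size) {
  check_image(image)
  hw <- image_hw(image)
  patch_size <- as.integer(patch_size)
  stride <- as.integer(stride)
  if (patch_size < 1L || stride < 1L) stop("patch_size and stride must be positive")
  if (patch_size > min(hw)) {
    stop(sprintf("patch_size (%d) exceeds image extent (%d x %d)",
                 patch_size, hw[1], hw[2]))
  }
  if (!is.null(mask)) {
    check_mask(mask)
    if (!identical(image_hw(mask), hw)) stop("mask shape does not match image")
  }
  rows <- seq.int(0L, hw[1] - patch_size, by = stride)
  cols <- seq.int(0L, hw[2] - patch_size, by = stride)
  out <- vector("list", length(rows) * length(cols))
  k <- 1L
  for (r in rows) {
    for (cc in cols) {
      ri <- (r + 1L):(r + patch_size)
      ci <- (cc + 1L):(cc + patch_size)
      pimg <- if (length(dim(image)) == 3L) image[ri, ci, , drop = FALSE] else image[ri, ci]
      pmsk <- if (is.null(mask)) NULL else mask[ri, ci]
      out[[k]] <- list(image = pimg, mask = pmsk, origin = c(row = r, col = cc))
      k <- k + 1L
    }
  }
  out
}

#' Reassemble patches cropped at stride = patch size
#'
#' Inverse of [crop_patches()] for non-overlapping tilings: places each patch
#' back at its recorded origin. Used for round-trip checks and for stitching
#' per-patch segmentations back onto slide coordinates.
#'
#' @param patches List as returned by [crop_patches()].
#' @param height,width Dimensions of the output canvas.
#' @param what `"image"` or `"mask"` — which component of each patch to place.
#' @return A numeric matrix of the requested size.
#' @export
stitch_patches <- function(patches, height, width, what = c("image", "mask")) {
  what <- match.arg(what)
  out <- matrix(0, height, width)
  for (p in patches) {
    x <- p[[what]]
    if (is.null(x)) stop("patch has no ", what, " component")
    n <- nrow(x)
    r <- p$origin[["row"]]
    cc <- p$origin[["col"]]
    out[(r + 1L):(r + n), (cc + 1L):(cc + ncol(x))] <- x
  }
  out
}

# 1-D mirror-reflection index map without border duplication:
# positions 1..n_out map into 1..n for a pad of p per side (requires p <= n-1).
reflect_index <- function(n, pad) {
  if (pad > n - 1L) {
    stop(sprintf("reflection pad (%d) exceeds extent - 1 (%d)", pad, n - 1L))
  }
  c(rev(seq_len(pad) + 1L), seq_len(n), n - seq_len(pad))
}

#' Expand a patch by mirror reflection about its borders
#'
#' Pads symmetrically to `target_size` x `target_size` using reflection that
#' does not duplicate the border pixel, so cell morphology at the seam is
#' preserved without 2-pixel-wide artifacts. For label masks, each reflected
#' copy of a cell receives a new unique label: a cell and its mirror image
#' are distinct instances.
#'
#' @param patch Numeric matrix, H x W x 3 array, or (with
#'   `is_mask = TRUE`) an integer label matrix.
#' @param target_size Output side length; `target_size - extent` must be even
#'   (asymmetric padding is not supported).
#' @param is_mask Treat `patch` as an instance mask and relabel reflections.
#' @return Padded array of size `target_size` x `target_size`.
#' @examples
#' p <- matrix(1:9, 3, 3)
#' reflect_pad(p, 5)
#' @export
reflect_pad <- function(patch, target_size, is_mask = FALSE) {
  d <- dim(patch)
  h <- d[1]; w <- d[2]
  target_size <- as.integer(target_size)
  if (target_size < max(h, w)) stop("target_size is smaller than the patch")
  if ((target_size - h) %% 2L != 0L || (target_size - w) %% 2L != 0L) {
    stop("padding amount must be even on each axis (asymmetric padding not supported)")
  }
  ph <- (target_size - h) %/% 2L
  pw <- (target_size - w) %/% 2L
  ri <- reflect_index(h, ph)
  ci <- reflect_index(w, pw)
  if (length(d) == 3L) {
    out <- patch[ri, ci, , drop = FALSE]
    return(out)
  }
  out <- patch[ri, ci]
  if (is_mask && (ph > 0L || pw > 0L)) {
    out <- relabel_reflections(out, patch, ph, pw)
  }
  out
}

# Assign fresh labels to every mirrored copy of every cell. The padded canvas
# splits into a 3x3 grid of zones (row zones: top reflection / centre / bottom
# reflection, same for columns); the centre zone keeps the original labels and
# each other (zone, label) combination becomes one new instance.
relabel_reflections <- function(padded, original, ph, pw) {
  h <- nrow(original); w <- ncol(original)
  H <- nrow(padded); W <- ncol(padded)
  row_zone <- c(rep(1L, ph), rep(2L, h), rep(3L, ph))
  col_zone <- c(rep(1L, pw), rep(2L, w), rep(3L, pw))
  zone <- outer(row_zone, col_zone, function(r, cc) (r - 1L) * 3L + cc)  # 5 = centre
  lab <- padded
  fg <- which(lab > 0 & zone != 5L)
  if (length(fg)) {
    key <- paste(zone[fg], lab[fg])
    new_ids <- max(original) + as.integer(factor(key, levels = unique(key)))
    lab[fg] <- new_ids
  }
  lab
}

#' Convert a semantic (binary) mask to an instance mask
#'
#' Each connected foreground component becomes one cell with a unique
#' positive label. Labels are assigned 1..K in raster order (row-major) of
#' each component's first pixel, so conversion is deterministic.
#'
#' @param mask Binary matrix (0 background, 1 foreground).
#' @param connectivity 4 (edge-adjacent) or 8 (edge- or corner-adjacent,
#'   the default — standard for nuclei blobs).
#' @return Integer instance mask with the same foreground pixel set.
#' @export
semantic_to_instance <- function(mask, connectivity = 8) {
  if (!is.matrix(mask)) stop("`mask` must be a matrix")
  bad <- setdiff(unique(as.vector(mask)), c(0, 1))
  if (length(bad)) {
    stop("semantic mask is not binary; offending values: ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  label_components(mask > 0, connectivity)
}

# Connected-component labelling of a logical matrix via an adjacency graph
# over foreground pixels; components relabelled 1..K by raster order of each
# component's first pixel (row-major, matching image scan order).
label_components <- function(fg, connectivity = 8) {
  h <- nrow(fg); w <- ncol(fg)
  idx <- which(fg)
  out <- matrix(0, h, w)
  if (!length(idx)) return(out)
  r <- ((idx - 1L) %% h) + 1L
  cc <- ((idx - 1L) %/% h) + 1L
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  from <- integer(0); to <- integer(0)
  for (o in offs) {
    r2 <- r + o[1]; c2 <- cc + o[2]
    ok <- r2 >= 1L & r2 <= h & c2 >= 1L & c2 <= w
    nb <- (c2[ok] - 1L) * h + r2[ok]
    hit <- fg[nb]
    from <- c(from, idx[ok][hit])
    to <- c(to, nb[hit])
  }
  map <- integer(h * w)
  map[idx] <- seq_along(idx)
  g <- igraph::graph_from_edgelist(cbind(map[from], map[to]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  # raster order: pixels sorted by (row, col) = order of (r, cc)
  raster <- order(r, cc)
  first_seen <- !duplicated(comp[raster])
  relabel <- integer(max(comp))
  relabel[comp[raster][first_seen]] <- seq_len(sum(first_seen))
  out[idx] <- relabel[comp]
  out
}

#' Build a train/validation list grouped by sample identifier
#'
#' Splits entries into train and validation sets within each sample (SN)
#' group, so every sample contributes proportionally. The validation count
#' per group is `round-half-up(group size * val_fraction)`; assignment is a
#' deterministic seeded shuffle within each group.
#'
#' @param entries Data frame with columns `image_path`, `mask_path`, `sn`.
#' @param val_fraction Fraction of each group assigned to validation, in
#'   `[0, 1)`.
#' @param seed Integer seed controlling the within-group shuffle.
#' @return Data frame with columns `image_path`, `mask_path`, `sn`, `split`
#'   (`"train"` or `"val"`), one row per input entry.
#' @export
build_trainset_list <- function(entries, val_fraction, seed) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  need <- c("image_path", "mask_path", "sn")
  if (!all(need %in% names(entries))) {
    stop("entries must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(entries) == 0L) stop("entry list is empty")
  if (anyDuplicated(entries$image_path)) {
    stop("duplicate image paths: ",
         paste(unique(entries$image_path[duplicated(entries$image_path)]), collapse = ", "))
  }
  if (val_fraction < 0 || val_fraction >= 1) stop("val_fraction must be in [0, 1)")
  entries$split <- "train"
  with_seed(seed, {
    for (g in unique(entries$sn)) {
      rows <- which(entries$sn == g)
      n_val <- min(length(rows), round_half_up(length(rows) * val_fraction))
      if (n_val > 0L) {
        pick <- rows[sample.int(length(rows), n_val)]
        entries$split[pick] <- "val"
      }
    }
  })
  entries[, c("image_path", "mask_path", "sn", "split")]
}

#' Write or read a trainset list as TSV
#'
#' The on-disk format is tab-separated with header
#' `image_path  mask_path  sn  split`.
#'
#' @param trainset Data frame as returned by [build_trainset_list()].
#' @param path TSV file path.
#' @return `write_trainset_list` returns the path invisibly;
#'   `read_trainset_list` returns the data frame.
#' @export
write_trainset_list <- function(trainset, path) {
  utils::write.table(trainset, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trainset_list
#' @export
read_trainset_list <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Canonical patch file stem from slide coordinates
#'
#' @param sn Sample identifier.
#' @param row,col 0-based origin of the patch on the whole slide.
#' @return A string `{sn}_r{row}_c{col}`.
#' @export
patch_stem <- function(sn, row, col) sprintf("%s_r%d_c%d", sn, row, col)
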