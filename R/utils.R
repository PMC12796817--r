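#' @keywords internal
"_PACKAGE"

# Run an expression under a temporary RNG state seeded by `seed`, restoring
# the caller's .Random.seed afterwards. All stochastic operations in the
# package go through this so that a seed argument never clobbers user RNG.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Round half away from zero (R's round() is banker's rounding).
round_half_up <- function(x) floor(x + 0.5)

# Validate an instance mask: integer-valued matrix, no negatives, finite.
check_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask)) stop(sprintf("`%s` must be a matrix", arg))
  if (any(!is.finite(mask))) stop(sprintf("`%s` contains non-finite values", arg))
  if (any(mask < 0)) stop(sprintf("`%s` contains negative labels", arg))
  if (any(mask != floor(mask))) stop(sprintf("`%s` contains non-integer labels", arg))
  invisible(mask)
}

# Validate an intensity image: H x W or H x W x 3 finite non-negative array.
check_image <- function(image, arg = "image") {
  d <- dim(image)
  if (is.null(d) || !(length(d) == 2L || (length(d) == 3L && d[3] == 3L))) {
    stop(sprintf("`%s` must be an H x W matrix or H x W x 3 array", arg))
  }
  if (any(!is.finite(image))) stop(sprintf("`%s` contains non-finite values", arg))
  if (any(image < 0)) stop(sprintf("`%s` contains negative intensities", arg))
  invisible(image)
}

# Collapse an RGB array to luminance grayscale (Rec. 601 weights).
to_gray <- function(image) {
  if (length(dim(image)) == 3L) {
    0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  } else {
    image
  }
}

image_hw <- function(x) {
  d <- dim(x)
  c(d[1], d[2])
}
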