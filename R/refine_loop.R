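# Iterative refinement workflow: a pluggable segmenter contract, a
# classical watershed baseline so the loop runs without deep-learning
# backends, and the segment -> evaluate -> extend-trainset -> re-fit loop.
# Fine-tuning always restarts from the adapter's base state, never from a
# previously fine-tuned state, to avoid catastrophic forgetting.

#' Classical baseline instance segmentation
#'
#' Reference segmenter: global threshold by between-class-variance
#' maximisation (Otsu) on the intensity histogram, then instance splitting
#' by distance-transform watershed, then removal of components smaller
#' than `min_area_px`. Deterministic; a blank image yields an empty mask.
#'
#' @param image Grayscale matrix or RGB array, any non-negative scale.
#' @param min_area_px Minimum instance area kept, pixels.
#' @return Integer instance mask.
#' @export
baseline_segment <- function(image, min_area_px = 15) {
  check_image(image)
  gray <- to_gray(image)
  rng <- range(gray)
  if (rng[2] <= rng[1]) return(matrix(0, nrow(gray), ncol(gray)))
  norm <- (gray - rng[1]) / (rng[2] - rng[1])
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  fg <- norm > thr
  if (!any(fg)) return(matrix(0, nrow(gray), ncol(gray)))
  dm <- EBImage::distmap(EBImage::Image(fg * 1))
  ws <- EBImage::watershed(dm, tolerance = 1, ext = 1)
  mask <- matrix(as.integer(EBImage::imageData(ws)), nrow(gray), ncol(gray))
  drop_small_components(mask, min_area_px)
}

# Remove labels whose pixel count is below min_area_px; relabel 1..K in
# ascending original-label order.
drop_small_components <- function(mask, min_area_px) {
  if (!any(mask > 0)) return(mask)
  tab <- table(mask[mask > 0])
  keep <- as.numeric(names(tab)[tab >= min_area_px])
  out <- matrix(0, nrow(mask), ncol(mask))
  for (i in seq_along(keep)) out[mask == keep[i]] <- i
  out
}

#' Construct a segmenter adapter
#'
#' The pluggable contract the refinement loop drives. `segment(image,
#' state)` returns an instance mask; `finetune(entries, base_state)`
#' returns a new model state and is always called with the ORIGINAL base
#' state, never with a previously fine-tuned one. Deep-learning backends
#' (Cellpose, StarDist, U-Net) register through this same interface; the
#' package ships the classical baseline.
#'
#' @param name Adapter name.
#' @param segment Function `(image, state) -> mask`.
#' @param finetune Function `(entries, base_state) -> state`; defaults to a
#'   no-op returning the base state.
#' @param base_state Opaque model state the adapter starts from.
#' @return An object of class `segmenter_adapter`.
#' @export
segmenter_adapter <- function(name, segment, finetune = NULL, base_state = NULL) {
  if (is.null(finetune)) finetune <- function(entries, base_state) base_state
  structure(list(name = name, segment = segment, finetune = finetune,
                 base_state = base_state),
            class = "segmenter_adapter")
}

#' @export
print.segmenter_adapter <- function(x, ...) {
  cat(sprintf("segmenter_adapter '%s'\n", x$name))
  invisible(x)
}

#' The built-in classical baseline adapter
#'
#' Wraps [baseline_segment()] in the adapter contract; its fine-tune step
#' is a no-op (the classical segmenter has no trainable state).
#'
#' @param min_area_px Minimum instance area kept, pixels.
#' @return A `segmenter_adapter`.
#' @export
baseline_adapter <- function(min_area_px = 15) {
  segmenter_adapter(
    name = "baseline",
    segment = function(image, state) baseline_segment(image, state$min_area_px),
    base_state = list(min_area_px = min_area_px))
}

#' Refinement run configuration
#'
#' @param iou_threshold IoU threshold for evaluation (default 0.5).
#' @param target_f1 Mean F1 on the held-out pairs at which the loop stops.
#' @param max_rounds Maximum refinement rounds (>= 1).
#' @param output_dir Parent directory for the timestamped run directory.
#' @param seed Integer seed.
#' @return A `refine_config` list.
#' @export
refine_config <- function(iou_threshold = 0.5, target_f1 = 0.85,
                          max_rounds = 5, output_dir = tempdir(), seed = 0) {
  if (max_rounds < 1) stop("max_rounds must be >= 1")
  if (target_f1 <= 0 || target_f1 > 1) stop("target_f1 must be in (0, 1]")
  structure(list(iou_threshold = iou_threshold, target_f1 = target_f1,
                 max_rounds = max_rounds, output_dir = output_dir, seed = seed),
            class = "refine_config")
}

#' Run the iterative refinement cycle
#'
#' Each round adds the next batch of annotated pool patches to the
#' cumulative training set, fine-tunes the adapter FROM ITS BASE STATE on
#' the cumulative set, segments the held-out test images, and logs the
#' five evaluation metrics. The loop stops when the mean F1 reaches
#' `target_f1` or after `max_rounds` rounds. All rounds are logged to a
#' timestamped directory (`run_YYYYMMDD_HHMMSS`) as JSON-lines plus CSV,
#' with a trainset-list snapshot per round; an adapter failure marks the
#' round failed and stops the loop with a partial log.
#'
#' @param adapter A [segmenter_adapter()].
#' @param pool List of batches; each batch is a list of annotated patches
#'   `list(image =, mask =, sn =)` to add that round.
#' @param test_pairs List of held-out `list(image =, mask =)` pairs,
#'   disjoint from the pool.
#' @param config A [refine_config()].
#' @return An object of class `refine_log`: data frame with one row per
#'   round (round, n_train, precision, recall, f1, jaccard, dice,
#'   reached_target, failed) and attribute `run_dir`.
#' @export
run_refinement_cycle <- function(adapter, pool, test_pairs, config = refine_config()) {
  stopifnot(inherits(adapter, "segmenter_adapter"))
  if (!length(pool)) stop("annotated pool is empty")
  if (!length(test_pairs)) stop("no held-out test pairs")
  run_dir <- file.path(config$output_dir,
                       format(Sys.time(), "run_%Y%m%d_%H%M%S"))
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(run_dir, "rounds.jsonl")
  rows <- list()
  trainset <- list()
  n_rounds <- min(config$max_rounds, length(pool))
  for (round in seq_len(n_rounds)) {
    trainset <- c(trainset, pool[[round]])
    snapshot <- data.frame(
      image_path = sprintf("patch_%03d", seq_along(trainset)),
      mask_path = sprintf("patch_%03d_mask", seq_along(trainset)),
      sn = vapply(trainset, function(p) p$sn %||% "pool", character(1)),
      split = "train")
    write_trainset_list(snapshot,
                        file.path(run_dir, sprintf("trainset_round%02d.tsv", round)))
    res <- tryCatch({
      state <- adapter$finetune(trainset, adapter$base_state)
      reports <- lapply(seq_along(test_pairs), function(i) {
        pred <- adapter$segment(test_pairs[[i]]$image, state)
        evaluate_masks(test_pairs[[i]]$mask, pred,
                       threshold = config$iou_threshold,
                       image_id = sprintf("test_%d", i))
      })
      per_image <- do.call(rbind, reports)
      colMeans(per_image[, c("precision", "recall", "f1", "jaccard", "dice")])
    }, error = function(e) e)
    failed <- inherits(res, "error")
    row <- data.frame(round = round, n_train = length(trainset),
                      precision = NA_real_, recall = NA_real_, f1 = NA_real_,
                      jaccard = NA_real_, dice = NA_real_,
                      reached_target = FALSE, failed = failed)
    if (!failed) {
      row[, names(res)] <- as.list(res)
      row$reached_target <- res[["f1"]] >= config$target_f1
    }
    rows[[round]] <- row
    cat(jsonlite::toJSON(as.list(row), auto_unbox = TRUE, digits = NA), "\n",
        file = log_path, append = TRUE)
    if (failed) {
      warning(sprintf("round %d failed: %s", round, conditionMessage(res)),
              call. = FALSE)
      break
    }
    if (row$reached_target) break
  }
  out <- do.call(rbind, rows)
  utils::write.csv(out, file.path(run_dir, "rounds.csv"), row.names = FALSE)
  attr(out, "run_dir") <- run_dir
  class(out) <- c("refine_log", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.refine_log <- function(x, ...) {
  cat(sprintf("Refinement run (%d rounds), logs in %s\n",
              nrow(x), attr(x, "run_dir")))
  print.data.frame(x, ...)
  invisible(x)
}
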