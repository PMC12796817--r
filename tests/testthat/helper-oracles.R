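# Independent oracles used by the tests; deliberately naive implementations
# kept separate from the package's own code paths.

# Stack-based flood fill connected-component count/labelling.
flood_fill_label <- function(fg, connectivity = 8) {
  h <- nrow(fg); w <- ncol(fg)
  lab <- matrix(0L, h, w)
  offs <- if (connectivity == 8) {
    list(c(-1,-1), c(-1,0), c(-1,1), c(0,-1), c(0,1), c(1,-1), c(1,0), c(1,1))
  } else {
    list(c(-1,0), c(1,0), c(0,-1), c(0,1))
  }
  k <- 0L
  for (cc in seq_len(w)) for (r in seq_len(h)) {
    if (fg[r, cc] && lab[r, cc] == 0L) {
      k <- k + 1L
      stack <- list(c(r, cc))
      lab[r, cc] <- k
      while (length(stack)) {
        cur <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (o in offs) {
          r2 <- cur[1] + o[1]; c2 <- cur[2] + o[2]
          if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w &&
              fg[r2, c2] && lab[r2, c2] == 0L) {
            lab[r2, c2] <- k
            stack[[length(stack) + 1L]] <- c(r2, c2)
          }
        }
      }
    }
  }
  lab
}

# Exhaustive optimal one-to-one assignment: maximum-cardinality matching on
# the bipartite graph of candidate pairs at/above the threshold.
optimal_match_tp <- function(pairs, threshold) {
  cand <- pairs[pairs$iou >= threshold, , drop = FALSE]
  if (!nrow(cand)) return(0L)
  gts <- unique(cand$gt_label); prs <- unique(cand$pred_label)
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(paste0("g", gts), type = TRUE) +
    igraph::vertices(paste0("p", prs), type = FALSE)
  g <- igraph::add_edges(g, rbind(paste0("g", cand$gt_label),
                                  paste0("p", cand$pred_label)))
  igraph::max_bipartite_match(g)$matching_size
}

# Brute-force 3x3 Sobel gradient magnitude with 1-px mirrored (replicated)
# border, computed pixel by pixel.
brute_sobel <- function(gray) {
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)        # columns: -1,0,+1
  ky <- t(kx)
  h <- nrow(gray); w <- ncol(gray)
  out <- matrix(0, h, w)
  clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)
  for (r in seq_len(h)) for (cc in seq_len(w)) {
    gx <- 0; gy <- 0
    for (dr in -1:1) for (dc in -1:1) {
      v <- gray[clamp(r + dr, 1, h), clamp(cc + dc, 1, w)]
      gx <- gx + v * kx[dr + 2, dc + 2]
      gy <- gy + v * ky[dr + 2, dc + 2]
    }
    out[r, cc] <- sqrt(gx^2 + gy^2)
  }
  out
}

# Small helper: mask with axis-aligned rectangles, one label per rectangle.
# rects: list of c(r1, r2, c1, c2)
rect_mask <- function(h, w, rects) {
  m <- matrix(0, h, w)
  for (i in seq_along(rects)) {
    rc <- rects[[i]]
    m[rc[1]:rc[2], rc[3]:rc[4]] <- i
  }
  m
}
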