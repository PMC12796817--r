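# Cell-bin expression: map spot-level expression points into an instance
# mask, aggregate per-cell gene counts, and read/write the open
# MTX + TSV stand-in for a cell-level expression file.

#' Read a spot-level expression table (GEM format)
#'
#' GEM is tab-delimited with a header naming at least gene, x, y and count
#' columns; `MIDCount`/`MIDCounts`/`UMICount` are accepted as count
#' synonyms and `geneID` as a gene synonym. Leading lines starting with
#' `#` are skipped. `.gz` files are decompressed transparently. Rows with
#' non-integer coordinates or count < 1 are rejected and reported with
#' their line numbers in the `rejected` attribute.
#'
#' @param path Path to a `.gem` or `.gem.gz` file.
#' @return Data frame with columns `gene_id`, `x`, `y`, `count`; attribute
#'   `rejected` holds a data frame of (line, reason) for dropped rows.
#' @export
read_gem <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (nrow(raw) == 0L) stop("GEM file has no data rows: ", path)
  nm <- tolower(names(raw))
  pick <- function(cands, what) {
    hit <- which(nm %in% cands)
    if (!length(hit)) stop("GEM file is missing a ", what, " column (looked for: ",
                           paste(cands, collapse = ", "), ")")
    hit[1]
  }
  gi <- pick(c("geneid", "gene", "gene_id"), "gene")
  xi <- pick("x", "x")
  yi <- pick("y", "y")
  ci <- pick(c("midcount", "midcounts", "umicount", "umicounts", "count", "counts"),
             "count")
  df <- data.frame(gene_id = as.character(raw[[gi]]),
                   x = suppressWarnings(as.numeric(raw[[xi]])),
                   y = suppressWarnings(as.numeric(raw[[yi]])),
                   count = suppressWarnings(as.numeric(raw[[ci]])),
                   stringsAsFactors = FALSE)
  bad_coord <- !is.finite(df$x) | !is.finite(df$y) | df$x != floor(df$x) | df$y != floor(df$y)
  bad_count <- !bad_coord & (!is.finite(df$count) | df$count < 1 | df$count != floor(df$count))
  bad_gene <- !bad_coord & !bad_count & (is.na(df$gene_id) | df$gene_id == "")
  bad <- bad_coord | bad_count | bad_gene
  rejected <- data.frame(
    line = which(bad) + 1L,  # +1 for the header line
    reason = ifelse(bad_coord[bad], "non-integer or missing coordinate",
                    ifelse(bad_count[bad], "count < 1 or non-integer", "empty gene id")))
  out <- df[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Write an expression point table in GEM format
#'
#' @param points Data frame with `gene_id`, `x`, `y`, `count`.
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return The path, invisibly.
#' @export
write_gem <- function(points, path) {
  df <- data.frame(geneID = points$gene_id, x = points$x, y = points$y,
                   MIDCount = points$count)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assign expression points to mask instances
#'
#' Each point is assigned the mask label at its pixel `(y, x)` — exact
#' lookup, no interpolation; label 0 means background. Coordinates are
#' 0-based with `x` = column and `y` = row (set `one_based = TRUE` for
#' exports whose coordinates start at 1). Out-of-bounds points are
#' rejected with a report; if more than half the points fall outside the
#' mask, the function stops and suggests a coordinate-frame mismatch.
#'
#' @param points Data frame from [read_gem()].
#' @param mask Instance mask.
#' @param one_based Shift coordinates down by 1 before lookup.
#' @return Data frame with `point` (row index into `points`) and `label`
#'   (assigned mask label, 0 = background); attribute `out_of_bounds`
#'   holds rejected point indices.
#' @export
assign_points <- function(points, mask, one_based = FALSE) {
  check_mask(mask)
  h <- nrow(mask); w <- ncol(mask)
  x <- points$x - if (one_based) 1L else 0L
  y <- points$y - if (one_based) 1L else 0L
  oob <- x < 0 | x >= w | y < 0 | y >= h
  if (sum(oob) > length(oob) / 2) {
    stop(sprintf(paste0("%d of %d points fall outside the %dx%d mask; ",
                        "check the coordinate frame (one_based?)"),
                 sum(oob), length(oob), h, w))
  }
  keep <- which(!oob)
  label <- mask[(x[keep]) * h + y[keep] + 1L]  # column-major: (col)*h + row + 1
  out <- data.frame(point = keep, label = label)
  attr(out, "out_of_bounds") <- which(oob)
  out
}

#' Aggregate assigned points into a cells x genes matrix
#'
#' `count(cell, gene)` is the sum of the counts of all points assigned to
#' that cell with that gene; background points (label 0) are excluded, not
#' redistributed. Per-cell centroid and area metadata come from
#' connected-region analysis of the mask. Cells with no assigned points
#' are kept as zero rows by default so the metadata is complete.
#'
#' @param assignments Data frame from [assign_points()].
#' @param points The point table the assignments refer to.
#' @param mask The instance mask (for cell metadata).
#' @param drop_empty_cells Drop mask labels with no assigned points.
#' @return An object of class `cell_expression`: list with `counts`
#'   (dgCMatrix, cells x genes), `cells` (metadata data frame: label,
#'   centroid_x, centroid_y, area_px2), `genes` (character vector), and
#'   `background_total` (summed counts of background points).
#' @export
aggregate_expression <- function(assignments, points, mask,
                                 drop_empty_cells = FALSE) {
  records <- extract_cell_records(mask)
  in_cell <- assignments$label > 0
  pts <- points[assignments$point[in_cell], , drop = FALSE]
  labs <- assignments$label[in_cell]
  genes <- sort(unique(points$gene_id))
  cells <- records
  if (drop_empty_cells) cells <- cells[cells$label %in% unique(labs), , drop = FALSE]
  counts <- Matrix::sparseMatrix(
    i = match(labs, cells$label),
    j = match(pts$gene_id, genes),
    x = pts$count,
    dims = c(nrow(cells), length(genes)),
    dimnames = list(as.character(cells$label), genes))
  counts <- methods::as(counts, "CsparseMatrix")
  bg <- sum(points$count[assignments$point[!in_cell]])
  structure(list(counts = counts,
                 cells = cells[, c("label", "centroid_x", "centroid_y", "area_px2")],
                 genes = genes,
                 background_total = bg),
            class = "cell_expression")
}

#' @export
print.cell_expression <- function(x, ...) {
  cat(sprintf("cell_expression: %d cells x %d genes, total counts %g (+%g background)\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts), x$background_total))
  invisible(x)
}

#' One-call cell-bin pipeline
#'
#' Reads (or accepts) a point table, assigns points to the mask, and
#' aggregates into a `cell_expression` matrix.
#'
#' @param gem Path to a GEM file, or a point data frame.
#' @param mask Instance mask or path to a mask TIFF.
#' @param one_based Coordinate convention flag, see [assign_points()].
#' @param drop_empty_cells See [aggregate_expression()].
#' @return A `cell_expression` object.
#' @export
cellbin <- function(gem, mask, one_based = FALSE, drop_empty_cells = FALSE) {
  points <- if (is.character(gem)) read_gem(gem) else gem
  if (is.character(mask)) mask <- read_mask(mask)
  asg <- assign_points(points, mask, one_based = one_based)
  aggregate_expression(asg, points, mask, drop_empty_cells = drop_empty_cells)
}

#' Write a cell expression matrix as MTX plus TSV sidecars
#'
#' Writes `matrix.mtx` (MatrixMarket coordinate format, cells x genes),
#' `genes.tsv` (one gene id per line) and `cells.tsv`
#' (label, centroid_x, centroid_y, area_px2). Round-trips losslessly
#' through [read_cell_matrix()].
#'
#' @param x A `cell_expression` object.
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_cell_matrix <- function(x, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  Matrix::writeMM(x$counts, file.path(out_dir, "matrix.mtx"))
  writeLines(x$genes, file.path(out_dir, "genes.tsv"))
  utils::write.table(x$cells, file.path(out_dir, "cells.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' @rdname write_cell_matrix
#' @export
read_cell_matrix <- function(out_dir) {
  counts <- methods::as(Matrix::readMM(file.path(out_dir, "matrix.mtx")),
                        "CsparseMatrix")
  genes <- readLines(file.path(out_dir, "genes.tsv"))
  cells <- utils::read.delim(file.path(out_dir, "cells.tsv"),
                             stringsAsFactors = FALSE)
  dimnames(counts) <- list(as.character(cells$label), genes)
  structure(list(counts = counts, cells = cells, genes = genes,
                 background_total = NA_real_),
            class = "cell_expression")
}
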