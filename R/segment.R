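# Segmentation of nuclei, whole cells and intracellular puncta from
# multi-channel fields. EBImage provides the classical primitives (Gaussian
# smoothing, hole filling, distance-map watershed, Voronoi propagation,
# morphological top-hat); puncta connected components are 8-connected
# (diagonal contact joins), computed over the pixel adjacency graph.

new_label_map <- function(labels, kind, parent_of = NULL, orphan_count = 0L) {
  labels <- matrix(as.integer(round(labels)), nrow(labels), ncol(labels))
  lm <- structure(list(labels = labels, kind = kind, parent_of = parent_of,
                       orphan_count = as.integer(orphan_count)),
                  class = "label_map")
  validate_label_map(lm)
}

validate_label_map <- function(lm) {
  labs <- sort(unique(as.vector(lm$labels)))
  labs <- labs[labs > 0]
  if (length(labs) && !identical(labs, seq_along(labs))) {
    abort("label map labels must be consecutive positive integers.",
          class = "ldscreen_bad_labels")
  }
  if (!is.null(lm$parent_of)) {
    if (is.null(names(lm$parent_of)) ||
        !all(names(lm$parent_of) %in% as.character(labs))) {
      abort("parent_of must be named by existing puncta labels.",
            class = "ldscreen_bad_labels")
    }
  }
  lm
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map:%s> %d objects on %dx%d px%s\n", x$kind,
              max(x$labels), nrow(x$labels), ncol(x$labels),
              if (x$orphan_count > 0)
                sprintf(" (%d orphan puncta dropped)", x$orphan_count) else ""))
  invisible(x)
}

#' Number of labelled objects in a label map
#' @param labels A `label_map`.
#' @return Integer count.
#' @export
n_objects <- function(labels) {
  stopifnot(inherits(labels, "label_map"))
  max(labels$labels)
}

# Map arbitrary positive labels to 1..k preserving first-appearance order
# (column-major scan), so output is deterministic.
relabel_consecutive <- function(labels) {
  pos <- labels > 0
  if (!any(pos)) return(matrix(0L, nrow(labels), ncol(labels)))
  u <- unique(labels[pos])
  out <- labels
  out[pos] <- match(labels[pos], u)
  storage.mode(out) <- "integer"
  out
}

# Otsu threshold on an intensity vector (histogram, maximal between-class
# variance). EBImage::otsu works only on whole images; this variant accepts
# the masked pixel subsets the puncta detector thresholds within.
otsu_threshold <- function(v, n_breaks = 256L) {
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(pmax(findInterval(
    v, seq(rng[1], rng[2], length.out = n_breaks + 1), rightmost.closed = TRUE),
    1L), n_breaks), nbins = n_breaks)
  p <- h / sum(h)
  mids <- seq(rng[1], rng[2], length.out = n_breaks + 1)[-1] -
    diff(rng) / (2 * n_breaks)
  w1 <- cumsum(p)
  mu1 <- cumsum(p * mids)
  mu_t <- mu1[n_breaks]
  sigma_b <- (mu_t * w1 - mu1)^2 / (w1 * (1 - w1))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

resolve_threshold <- function(v, threshold_method) {
  if (is.numeric(threshold_method)) return(threshold_method)
  switch(threshold_method,
         otsu = otsu_threshold(v),
         abort(sprintf("unknown threshold method '%s'.", threshold_method),
               class = "ldscreen_bad_spec"))
}

# 8-connected component labelling of a logical mask via the pixel adjacency
# graph (igraph components). Deterministic: labels ordered by first pixel in
# column-major order.
label_components_8 <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  idx <- which(mask)
  out <- matrix(0L, H, W)
  if (!length(idx)) return(out)
  rows <- ((idx - 1L) %% H) + 1L
  edge_list <- list()
  # neighbour offsets: down, right, down-right, up-right
  offs <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  in_mask <- logical(H * W); in_mask[idx] <- TRUE
  for (o in offs) {
    nb <- idx + o[1] + o[2] * H
    valid <- (rows + o[1] >= 1L) & (rows + o[1] <= H) & (nb >= 1L) & (nb <= H * W)
    valid[valid] <- in_mask[nb[valid]]
    if (any(valid)) edge_list[[length(edge_list) + 1L]] <- cbind(idx[valid], nb[valid])
  }
  comp_id <- match(idx, idx)
  if (length(edge_list)) {
    ed <- do.call(rbind, edge_list)
    g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
    g <- igraph::add_edges(g, t(cbind(match(ed[, 1], idx), match(ed[, 2], idx))))
    comp_id <- igraph::components(g)$membership
  }
  out[idx] <- comp_id
  relabel_consecutive(out)
}

sizes_of <- function(labels) {
  if (max(labels) == 0) return(integer())
  tabulate(labels[labels > 0], nbins = max(labels))
}

blank_channel <- function(ch) diff(range(ch)) == 0

#' Segment nuclei from the nuclear-stain channel
#'
#' Gaussian smoothing, global threshold (Otsu by default), hole filling,
#' small-object removal, then a distance-transform watershed to split
#' touching nuclei.
#'
#' @param img An `image_set` with a `nucleus` channel.
#' @param smooth_sigma Gaussian smoothing sigma (px).
#' @param min_area Minimum nucleus area (px^2).
#' @param threshold_method `"otsu"` or a numeric absolute threshold.
#' @return A `label_map` of kind `"nuclei"`. A blank channel yields an empty
#'   map with a warning.
#' @export
segment_nuclei <- function(img, smooth_sigma = 2, min_area = 60,
                           threshold_method = "otsu") {
  stopifnot(inherits(img, "image_set"))
  ch <- img$channels$nucleus
  if (is.null(ch)) abort("nucleus channel missing.", class = "ldscreen_missing_channel")
  if (blank_channel(ch)) {
    warn("nucleus channel is blank; returning an empty label map.")
    return(new_label_map(matrix(0L, nrow(ch), ncol(ch)), "nuclei"))
  }
  sm <- if (smooth_sigma > 0) {
    as.matrix(EBImage::gblur(EBImage::Image(ch), sigma = smooth_sigma))
  } else ch
  thr <- resolve_threshold(as.vector(sm), threshold_method)
  mask <- sm > thr
  if (!any(mask)) {
    warn("no foreground above threshold; returning an empty label map.")
    return(new_label_map(matrix(0L, nrow(ch), ncol(ch)), "nuclei"))
  }
  mask <- as.matrix(EBImage::fillHull(EBImage::Image(mask))) > 0
  # split touching nuclei on the distance transform
  dm <- EBImage::distmap(EBImage::Image(mask))
  labs <- as.matrix(EBImage::watershed(dm, tolerance = 1, ext = 1))
  sz <- sizes_of(labs)
  keep <- which(sz >= min_area)
  labs[!(labs %in% keep)] <- 0L
  new_label_map(relabel_consecutive(labs), "nuclei")
}

#' Segment whole cells seeded by nuclei
#'
#' Thresholds the whole-cell stain into a foreground mask (always including
#' nucleus pixels) and partitions it among the nuclei seeds by Voronoi-based
#' propagation, giving one cell per nucleus. Border-touching cells are
#' removed by default to avoid truncated-cell bias.
#'
#' @param img An `image_set` with a `cell` channel.
#' @param nuclei `label_map` from [segment_nuclei()] on the same field.
#' @param threshold_method `"otsu"` or a numeric threshold.
#' @param exclude_border Drop cells touching the field border (default TRUE).
#' @return A `label_map` of kind `"cells"`.
#' @export
segment_cells <- function(img, nuclei, threshold_method = "otsu",
                          exclude_border = TRUE) {
  stopifnot(inherits(img, "image_set"), inherits(nuclei, "label_map"))
  ch <- img$channels$cell
  if (is.null(ch)) abort("cell channel missing.", class = "ldscreen_missing_channel")
  if (!identical(dim(ch), dim(nuclei$labels))) {
    abort("nuclei map and image shapes differ.", class = "ldscreen_shape_mismatch")
  }
  if (max(nuclei$labels) == 0) {
    return(new_label_map(matrix(0L, nrow(ch), ncol(ch)), "cells"))
  }
  thr <- resolve_threshold(as.vector(ch), threshold_method)
  mask <- (ch > thr) | (nuclei$labels > 0)
  labs <- as.matrix(EBImage::propagate(EBImage::Image(ch),
                                       EBImage::Image(nuclei$labels),
                                       mask = EBImage::Image(mask)))
  if (exclude_border) {
    border <- unique(c(labs[1, ], labs[nrow(labs), ], labs[, 1], labs[, ncol(labs)]))
    border <- border[border > 0]
    labs[labs %in% border] <- 0L
  }
  new_label_map(relabel_consecutive(labs), "cells")
}

#' Detect intracellular puncta (lipid droplets, peroxisomes)
#'
#' White top-hat background suppression, threshold estimated within the union
#' of the cell masks, area filtering, 8-connected component labelling, and
#' parent-cell assignment by centroid location. Puncta whose centroid falls
#' outside every cell are dropped and tallied in the map's `orphan_count`.
#'
#' @param img An `image_set` with a `puncta` channel.
#' @param cells `label_map` from [segment_cells()] on the same field.
#' @param tophat_radius Radius (px) of the top-hat structuring disc; should
#'   exceed the largest punctum radius.
#' @param threshold_method `"otsu"` (within the cell mask) or a numeric
#'   threshold.
#' @param min_area,max_area Retained punctum area range (px^2).
#' @param split_touching Split merged puncta by a distance-map watershed
#'   before size filtering (default TRUE); turn off to count raw connected
#'   components.
#' @param parent_method `"centroid"` (default) or `"overlap"` (majority
#'   overlap).
#' @return A `label_map` of kind `"puncta"` with `parent_of` mapping each
#'   punctum label to its parent cell label.
#' @export
segment_puncta <- function(img, cells, tophat_radius = 6,
                           threshold_method = "otsu", min_area = 3,
                           max_area = Inf, split_touching = TRUE,
                           parent_method = c("centroid", "overlap")) {
  parent_method <- match.arg(parent_method)
  stopifnot(inherits(img, "image_set"), inherits(cells, "label_map"))
  if (min_area > max_area) {
    abort("min_area must be <= max_area.", class = "ldscreen_bad_spec")
  }
  ch <- img$channels$puncta
  if (is.null(ch)) abort("puncta channel missing.", class = "ldscreen_missing_channel")
  if (!identical(dim(ch), dim(cells$labels))) {
    abort("cells map and image shapes differ.", class = "ldscreen_shape_mismatch")
  }
  empty <- function() new_label_map(matrix(0L, nrow(ch), ncol(ch)), "puncta",
                                    parent_of = NULL)
  cellmask <- cells$labels > 0
  if (!any(cellmask)) return(empty())
  brush <- EBImage::makeBrush(2 * tophat_radius + 1, shape = "disc")
  th <- as.matrix(EBImage::whiteTopHat(EBImage::Image(ch), brush))
  vals <- th[cellmask]
  if (diff(range(vals)) == 0) return(empty())
  thr <- resolve_threshold(vals, threshold_method)
  mask <- (th > thr) & cellmask
  if (!any(mask)) return(empty())
  labs <- if (split_touching) {
    dm <- EBImage::distmap(EBImage::Image(mask))
    relabel_consecutive(as.matrix(EBImage::watershed(dm, tolerance = 1, ext = 1)))
  } else {
    label_components_8(mask)
  }
  sz <- sizes_of(labs)
  keep <- which(sz >= min_area & sz <= max_area)
  labs[!(labs %in% keep)] <- 0L
  labs <- relabel_consecutive(labs)
  k <- max(labs)
  if (k == 0) return(empty())

  parents <- integer(k)
  H <- nrow(labs)
  idx <- which(labs > 0)
  lab_v <- labs[idx]
  rows <- ((idx - 1L) %% H) + 1L
  cols <- ((idx - 1L) %/% H) + 1L
  if (parent_method == "centroid") {
    cy <- round(tapply(rows, lab_v, mean))
    cx <- round(tapply(cols, lab_v, mean))
    parents <- cells$labels[cbind(as.integer(cy), as.integer(cx))]
  } else {
    for (l in seq_len(k)) {
      ov <- cells$labels[idx[lab_v == l]]
      ov <- ov[ov > 0]
      parents[l] <- if (length(ov)) as.integer(names(which.max(table(ov)))) else 0L
    }
  }
  orphan <- which(parents == 0L)
  if (length(orphan)) {
    labs[labs %in% orphan] <- 0L
    labs <- relabel_consecutive(labs)
    parents <- parents[-orphan]
  }
  if (max(labs) == 0) {
    lm <- empty()
    lm$orphan_count <- length(orphan)
    return(lm)
  }
  new_label_map(labs, "puncta",
                parent_of = setNames(as.integer(parents),
                                     as.character(seq_along(parents))),
                orphan_count = length(orphan))
}
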