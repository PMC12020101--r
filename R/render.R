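# Synthetic field rendering: non-overlapping elliptical cells with interior
# nuclei and Poisson-distributed lipid droplets, drawn as digitised disks,
# blurred by a Gaussian PSF and degraded with additive Gaussian noise.
# Stage-wise sub-seeds (placement / LD counts / LD geometry / noise) make
# each stochastic stage independently replayable.

#' Construct a multi-channel field
#'
#' Bundles named 2-D intensity matrices (at minimum `nucleus`, `cell` and
#' `puncta` for the standard pipeline; optionally `active_mito` and
#' `total_mito`) with the pixel size and identifiers. All channels must share
#' one shape and contain finite, non-negative intensities.
#'
#' @param channels Named list of numeric matrices.
#' @param pixel_size Pixel size in um/px.
#' @param well,field Optional identifiers.
#' @return An object of class `image_set`.
#' @export
image_set <- function(channels, pixel_size, well = NA_character_,
                      field = NA_integer_) {
  stopifnot(is.list(channels), length(channels) > 0, !is.null(names(channels)))
  if (length(unique(lapply(channels, dim))) != 1) {
    abort("all channels must share one shape.", class = "ldscreen_shape_mismatch")
  }
  if (any(vapply(channels, function(m) any(!is.finite(m)) || any(m < 0),
                 logical(1)))) {
    abort("channel intensities must be finite and >= 0.",
          class = "ldscreen_bad_spec")
  }
  structure(list(channels = channels, pixel_size = pixel_size,
                 well = well, field = field),
            class = "image_set")
}

new_image_set <- image_set

#' @export
print.image_set <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<image_set> %dx%d px, channels: %s\n", d[1], d[2],
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

# Logical mask of an ellipse on an H x W grid (row = y, col = x).
ellipse_mask <- function(shape, cy, cx, a, b, theta) {
  H <- shape[1]; W <- shape[2]
  y0 <- max(1L, floor(cy - a)); y1 <- min(H, ceiling(cy + a))
  x0 <- max(1L, floor(cx - a)); x1 <- min(W, ceiling(cx + a))
  out <- matrix(FALSE, H, W)
  if (y0 > y1 || x0 > x1) return(out)
  ys <- y0:y1; xs <- x0:x1
  dy <- outer(ys - cy, rep(1, length(xs)))
  dx <- outer(rep(1, length(ys)), xs - cx)
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  out[ys, xs] <- (u^2 + v^2) <= 1
  out
}

inside_ellipse <- function(y, x, cy, cx, a, b, theta) {
  dy <- y - cy; dx <- x - cx
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  (u^2 + v^2) <= 1
}

disk_mask <- function(shape, cy, cx, r) {
  H <- shape[1]; W <- shape[2]
  y0 <- max(1L, floor(cy - r)); y1 <- min(H, ceiling(cy + r))
  x0 <- max(1L, floor(cx - r)); x1 <- min(W, ceiling(cx + r))
  out <- matrix(FALSE, H, W)
  if (y0 > y1 || x0 > x1) return(out)
  ys <- y0:y1; xs <- x0:x1
  dy2 <- outer((ys - cy)^2, rep(1, length(xs)))
  dx2 <- outer(rep(1, length(ys)), (xs - cx)^2)
  out[ys, xs] <- (dy2 + dx2) <= r^2
  out
}

# Rejection-sample non-overlapping cell ellipses. Overlap is tested on the
# circumscribing circles (semi-major axes), which is conservative.
place_cells <- function(spec) {
  H <- spec$image_shape[1]; W <- spec$image_shape[2]
  n <- spec$n_cells
  if (n == 0) {
    return(tibble(cell = integer(), cy = numeric(), cx = numeric(),
                  a = numeric(), b = numeric(), theta = numeric()))
  }
  rr <- spec$cell_radius_range
  if (2 * rr[2] + 4 > min(H, W)) {
    abort("cell radius too large for the field.", class = "ldscreen_placement")
  }
  # sequential rejection packing, with whole-field restarts when a draw
  # paints itself into a corner
  for (restart in seq_len(25L)) {
    cy <- cx <- a <- b <- theta <- numeric(n)
    placed <- 0L
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in seq_len(400L)) {
        ai <- runif(1, rr[1], rr[2])
        bi <- ai * runif(1, 0.65, 1)
        ti <- runif(1, 0, pi)
        yi <- runif(1, ai + 2, H - ai - 1)
        xi <- runif(1, ai + 2, W - ai - 1)
        if (i == 1 ||
            all(sqrt((cy[seq_len(i - 1)] - yi)^2 + (cx[seq_len(i - 1)] - xi)^2) >
                (a[seq_len(i - 1)] + ai + 1))) {
          cy[i] <- yi; cx[i] <- xi; a[i] <- ai; b[i] <- bi; theta[i] <- ti
          ok <- TRUE
          placed <- i
          break
        }
      }
      if (!ok) break
    }
    if (placed == n) {
      return(tibble(cell = seq_len(n), cy = cy, cx = cx, a = a, b = b,
                    theta = theta))
    }
  }
  abort(sprintf("cell placement failed after bounded retries (placed %d of %d): too many cells for the field area.",
                placed, n),
        class = "ldscreen_placement")
}

# Place one LD centre inside the cytoplasm (inside the cell ellipse shrunk by
# the LD radius, outside the nucleus), avoiding earlier LDs of the same cell.
place_ld <- function(cellrow, nfrac, r, prev_y, prev_x, prev_r) {
  for (try in seq_len(150L)) {
    # uniform in the unit disk, mapped through the (shrunk) ellipse axes
    repeat {
      u <- runif(1, -1, 1); v <- runif(1, -1, 1)
      if (u^2 + v^2 <= 1) break
    }
    sa <- max(cellrow$a - r - 1, 1); sb <- max(cellrow$b - r - 1, 1)
    dx <- u * sa * cos(cellrow$theta) - v * sb * sin(cellrow$theta)
    dy <- u * sa * sin(cellrow$theta) + v * sb * cos(cellrow$theta)
    y <- cellrow$cy + dy; x <- cellrow$cx + dx
    in_nuc <- inside_ellipse(y, x, cellrow$cy, cellrow$cx,
                             cellrow$a * nfrac + r, cellrow$b * nfrac + r,
                             cellrow$theta)
    if (in_nuc && try <= 100L) next
    if (length(prev_y) && try < 150L) {
      if (any(sqrt((prev_y - y)^2 + (prev_x - x)^2) < (prev_r + r + 2))) next
    }
    return(c(y, x))
  }
  c(y, x) # crowded cytoplasm: accept the last candidate
}

#' Render one synthetic multi-channel microscopy field
#'
#' Draws the field described by `spec` under a phenotype `profile` and returns
#' the image set together with its exact ground truth (per-cell and per-LD
#' records, label maps, and closed-form parameter expectations). The rendered
#' channels are `nucleus` (Hoechst-like), `cell` (whole-cell stain) and
#' `puncta` (BODIPY-like LD stain); with `include_mito = TRUE` two extra
#' channels emulate a potential-independent total-mitochondria stain and a
#' potential-dependent stain at `mito_active_fraction` of its signal.
#'
#' @param spec A [scene_spec()].
#' @param profile A [phenotype_profile()]; multipliers act on the LD Poisson
#'   rate and median radius.
#' @param seed Integer seed (defaults to `spec$seed`). Identical spec,
#'   profile and seed give a pixel-identical field.
#' @param include_mito Render the optional mitochondrial channel pair.
#' @param mito_active_fraction True active/total signal ratio used for the
#'   mitochondrial channels.
#' @return A list with elements `image` (an [image_set()]) and
#'   `truth` (list: `cells`, `lds` tibbles, `cell_labels`/`nucleus_labels`
#'   integer matrices, `expected` named vector, `seed`).
#' @export
render_field <- function(spec, profile = profile_patient(), seed = spec$seed,
                         include_mito = FALSE, mito_active_fraction = 0.5) {
  validate_scene_spec(spec)
  stopifnot(inherits(profile, "phenotype_profile"))
  shape <- spec$image_shape
  H <- shape[1]; W <- shape[2]

  cells <- with_seed(derive_seed(seed, 1L), place_cells(spec))
  lambda <- spec$ld_count_mean * profile$ld_count_multiplier
  ld_counts <- with_seed(derive_seed(seed, 2L),
                         if (nrow(cells)) rpois(nrow(cells), lambda) else integer())

  nfrac <- spec$nucleus_radius_fraction
  med_r <- spec$ld_radius_median * profile$ld_radius_multiplier

  lds <- with_seed(derive_seed(seed, 3L), {
    recs <- vector("list", nrow(cells))
    for (i in seq_len(nrow(cells))) {
      k <- ld_counts[i]
      if (k == 0) next
      rs <- rlnorm(k, meanlog = log(med_r), sdlog = spec$ld_radius_sigma)
      ys <- xs <- numeric(k)
      for (j in seq_len(k)) {
        p <- place_ld(cells[i, ], nfrac, rs[j],
                      ys[seq_len(j - 1)], xs[seq_len(j - 1)], rs[seq_len(j - 1)])
        ys[j] <- p[1]; xs[j] <- p[2]
      }
      recs[[i]] <- tibble(cell = i, y = ys, x = xs, r_px = rs)
    }
    out <- bind_rows(recs)
    if (!nrow(out)) out <- tibble(cell = integer(), y = numeric(),
                                  x = numeric(), r_px = numeric())
    out
  })
  if (nrow(lds)) {
    lds$ld <- seq_len(nrow(lds))
    lds$area_px2 <- pi * lds$r_px^2
    lds$area_um2 <- lds$area_px2 * spec$pixel_size^2
    lds <- lds[, c("ld", "cell", "y", "x", "r_px", "area_px2", "area_um2")]
  } else {
    lds <- tibble(ld = integer(), cell = integer(), y = numeric(), x = numeric(),
                  r_px = numeric(), area_px2 = numeric(), area_um2 = numeric())
  }

  # ground-truth label maps
  cell_labels <- matrix(0L, H, W)
  nucleus_labels <- matrix(0L, H, W)
  for (i in seq_len(nrow(cells))) {
    cm <- ellipse_mask(shape, cells$cy[i], cells$cx[i], cells$a[i], cells$b[i],
                       cells$theta[i])
    cell_labels[cm] <- i
    nm <- ellipse_mask(shape, cells$cy[i], cells$cx[i], cells$a[i] * nfrac,
                       cells$b[i] * nfrac, cells$theta[i])
    nucleus_labels[nm] <- i
  }

  ci <- spec$channel_intensities
  chan <- function(levels, mask) {
    m <- matrix(levels[["bg"]], H, W)
    m[mask] <- levels[["fg"]]
    m
  }
  nucleus <- chan(ci$nucleus, nucleus_labels > 0)
  cellch <- chan(ci$cell, cell_labels > 0)
  puncta <- matrix(ci$puncta[["bg"]], H, W)
  for (i in seq_len(nrow(lds))) {
    puncta[disk_mask(shape, lds$y[i], lds$x[i], lds$r_px[i])] <- ci$puncta[["fg"]]
  }
  channels <- list(nucleus = nucleus, cell = cellch, puncta = puncta)

  if (include_mito) {
    cyto <- cell_labels > 0 & nucleus_labels == 0
    total <- matrix(0.04, H, W); total[cyto] <- 0.6
    active <- matrix(0.04, H, W)
    active[cyto] <- 0.04 + mito_active_fraction * (0.6 - 0.04)
    channels$active_mito <- active
    channels$total_mito <- total
  }

  blur <- function(m) {
    if (spec$psf_sigma > 0) {
      as.matrix(EBImage::gblur(EBImage::Image(m), sigma = spec$psf_sigma))
    } else m
  }
  channels <- lapply(channels, blur)
  channels <- with_seed(derive_seed(seed, 4L), {
    lapply(channels, function(m) pmax(m + rnorm(length(m), 0, spec$noise_sd), 0))
  })

  truth <- list(
    cells = cells, lds = lds,
    cell_labels = cell_labels, nucleus_labels = nucleus_labels,
    ld_counts = ld_counts,
    expected = expected_ld_params(spec, profile),
    profile = profile$name, seed = seed
  )
  list(image = new_image_set(channels, spec$pixel_size), truth = truth)
}
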