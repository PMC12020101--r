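# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: sort-based median, two-pass SD, a boundary-walk
# perimeter and hand-built masks.

# Boundary-walk perimeter for convex shapes: boundary pixels (foreground with
# an exposed 4-neighbour) ordered by angle around the centroid, summing
# consecutive centre-to-centre distances around the closed contour.
oracle_perimeter_convex <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  idx <- which(mask)
  rows <- ((idx - 1L) %% H) + 1L
  cols <- ((idx - 1L) %/% H) + 1L
  exposed <- vapply(seq_along(idx), function(k) {
    r <- rows[k]; c <- cols[k]
    r == 1 || r == H || c == 1 || c == W ||
      !mask[r - 1, c] || !mask[r + 1, c] || !mask[r, c - 1] || !mask[r, c + 1]
  }, logical(1))
  br <- rows[exposed]; bc <- cols[exposed]
  ang <- atan2(br - mean(br), bc - mean(bc))
  o <- order(ang)
  br <- br[o]; bc <- bc[o]
  sum(sqrt(diff(c(br, br[1]))^2 + diff(c(bc, bc[1]))^2))
}

# Brute-force SD-distance scores: sort-based median, two-pass SD, explicit
# loops. Mirrors the scoring definition, not the implementation.
oracle_scores <- function(wells, reference_source = "all_samples",
                          params = ld_params()) {
  ref <- if (reference_source == "all_samples") {
    wells[wells$role == "compound", ]
  } else {
    wells[wells$role == "negative_control", ]
  }
  cmp <- wells[wells$role == "compound", ]
  out <- list()
  for (p in params) {
    v <- sort(ref[[p]])
    n <- length(v)
    med <- if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
    m <- sum(v) / n
    s <- sqrt(sum((v - m)^2) / (n - 1))
    for (i in seq_len(nrow(cmp))) {
      out[[length(out) + 1]] <- data.frame(
        compound_id = cmp$compound_id[i], parameter = p,
        z = (cmp[[p]][i] - med) / s, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# Digitised disk mask.
oracle_disk <- function(H, W, cy, cx, r) {
  m <- matrix(FALSE, H, W)
  for (y in seq_len(H)) for (x in seq_len(W)) {
    if ((y - cy)^2 + (x - cx)^2 <= r^2) m[y, x] <- TRUE
  }
  m
}

# Label map from a mask with a single label (for feature tests).
mask_as_puncta <- function(mask, parent = 1L) {
  labs <- matrix(0L, nrow(mask), ncol(mask))
  labs[mask] <- 1L
  ldscreen:::new_label_map(labs, "puncta",
                           parent_of = stats::setNames(as.integer(parent), "1"))
}

# Wells tibble with negative controls fixing median 0, SD 1, plus compounds
# at chosen parameter values (defaults: exact z units).
wells_with_z <- function(z_by_compound, neg_values = c(-1, 0, 1)) {
  params <- ld_params()
  neg <- tibble::tibble(
    well = sprintf("N%02d", seq_along(neg_values)),
    role = "negative_control", compound_id = NA_character_)
  for (p in params) neg[[p]] <- neg_values
  cmps <- purrr::imap(z_by_compound, function(z, id) {
    row <- tibble::tibble(well = id, role = "compound", compound_id = id)
    zv <- stats::setNames(rep(0, 4), params)
    zv[names(z)] <- z
    for (p in params) row[[p]] <- zv[[p]]
    row
  })
  dplyr::bind_rows(neg, dplyr::bind_rows(cmps))
}

# Random feature-mode plate wells for oracle comparisons.
random_wells <- function(n_compounds = 40, n_neg = 6, seed = 1) {
  set.seed(seed)
  params <- ld_params()
  w <- tibble::tibble(
    well = sprintf("W%03d", seq_len(n_compounds + n_neg)),
    role = c(rep("negative_control", n_neg), rep("compound", n_compounds)),
    compound_id = c(rep(NA_character_, n_neg),
                    sprintf("CMP-%04d", seq_len(n_compounds))))
  for (p in params) w[[p]] <- rnorm(n_compounds + n_neg, 10, 3)
  w
}

acceptance_layout <- function() {
  plate_layout(n_compounds = 360L, n_negative = 12L, n_positive_per_line = 6L)
}
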