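#' Configuration of the single-particle pipeline
#'
#' Numeric stand-ins for the qualitative rules of the semiautomated
#' routine: the size window brackets "the size expected for mitochondria",
#' and a particle is called ramified when its skeleton has more than
#' `max_branch_points` branch points (after pruning spurs shorter than
#' `spur_prune` pixels) or its solidity falls below `min_solidity`.
#'
#' @param min_area,max_area Retained-particle area window (um^2).
#' @param max_branch_points Maximum skeleton branch points for a
#'   non-ramified particle.
#' @param min_solidity Minimum solidity (component area / convex hull
#'   area) for a non-ramified particle.
#' @param collapse_half_window Planes collapsed on each side of the focal
#'   plane (default 2, i.e. a 5-plane mean).
#' @param deconv_iterations Richardson-Lucy iterations (0 disables).
#' @param threshold_method Automatic global threshold; only `"otsu"` is
#'   implemented.
#' @param spur_prune Skeleton spurs up to this length (px) are ignored
#'   when counting branch points.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(min_area = 0.1, max_area = 20,
                            max_branch_points = 0, min_solidity = 0.6,
                            collapse_half_window = 2,
                            deconv_iterations = 20,
                            threshold_method = "otsu",
                            spur_prune = 2) {
  if (min_area >= max_area) stopf("pipeline_config: min_area must be < max_area")
  if (collapse_half_window < 0) stopf("pipeline_config: half-window must be >= 0")
  if (deconv_iterations < 0) stopf("pipeline_config: iterations must be >= 0")
  if (!threshold_method %in% "otsu")
    stopf("pipeline_config: unknown threshold method '%s'", threshold_method)
  structure(list(min_area = min_area, max_area = max_area,
                 max_branch_points = max_branch_points,
                 min_solidity = min_solidity,
                 collapse_half_window = as.integer(collapse_half_window),
                 deconv_iterations = as.integer(deconv_iterations),
                 threshold_method = threshold_method,
                 spur_prune = as.integer(spur_prune)),
            class = "pipeline_config")
}

#' Richardson-Lucy deconvolution with a measured Gaussian PSF
#'
#' Deterministic surrogate for the blind deconvolution used at
#' acquisition time: iterative Richardson-Lucy restoration with the PSF
#' estimated from bead stacks. Both channels are restored with the same
#' PSF. Output is non-negative and conserves per-channel total intensity
#' to within a percent; `iterations = 0` returns the input unchanged.
#'
#' @param stack A [channel_stack()] (or `jc1_scene`).
#' @param psf A `psf_estimate`.
#' @param iterations Number of RL iterations (default 20).
#' @return A `channel_stack` of the same geometry.
#' @export
deconvolve <- function(stack, psf, iterations = 20) {
  stack <- as_channel_stack(stack)
  if (iterations < 0) stopf("deconvolve: iterations must be >= 0")
  if (iterations == 0) return(stack)
  d <- dim(stack$green)
  nz <- if (length(d) == 3) d[3] else 1L
  sig <- c(psf$sigma_xy / stack$pixel_size_xy,
           psf$sigma_xy / stack$pixel_size_xy,
           if (nz > 1) psf$sigma_z / stack$z_step else 0)
  if (psf$fwhm_xy / stack$pixel_size_xy < 1 ||
      (nz > 1 && psf$fwhm_z / stack$z_step < 1))
    stopf("deconvolve: PSF below one voxel; nothing to restore")
  rl <- function(obs) {
    eps <- 1e-8 * max(obs)
    est <- pmax(obs, 0)
    for (i in seq_len(iterations)) {
      conv <- blur_gaussian(est, sig)
      ratio <- obs / (conv + eps)
      est <- est * blur_gaussian(ratio, sig)   # Gaussian PSF is symmetric
    }
    pmax(est, 0)
  }
  channel_stack(rl(stack$green), rl(stack$red),
                stack$pixel_size_xy, stack$z_step)
}

#' Select the best focal plane
#'
#' Automated surrogate for by-eye focal-plane selection: the plane with
#' the maximum integrated (green + red) intensity. Ties break toward the
#' lower index.
#'
#' @param stack A [channel_stack()] with at least one plane.
#' @return 1-based plane index.
#' @export
select_focal_plane <- function(stack) {
  stack <- as_channel_stack(stack)
  d <- dim(stack$green)
  if (is.null(d) || any(d == 0)) stopf("select_focal_plane: empty stack")
  if (length(d) == 2) return(1L)
  tot <- stack$green + stack$red
  sums <- apply(tot, 3, sum)
  which.max(sums)
}

#' Collapse the focal plane with its neighbours
#'
#' Pointwise per-channel mean over `2 * half_window + 1` planes centred on
#' the focal plane (default: the plane plus its two upper and two lower
#' neighbours). The mean — not a maximum projection — preserves the
#' green/red proportion on which the ratio depends; the ratio must be
#' computed on the collapsed channels, never by averaging ratio planes.
#'
#' @param stack A [channel_stack()].
#' @param center 1-based focal-plane index.
#' @param half_window Planes on each side (default 2).
#' @return A 2-D `channel_stack`.
#' @export
collapse_planes <- function(stack, center, half_window = 2) {
  stack <- as_channel_stack(stack)
  d <- dim(stack$green)
  nz <- if (length(d) == 3) d[3] else 1L
  if (center - half_window < 1 || center + half_window > nz)
    stopf(paste("collapse_planes: window [%d, %d] exceeds stack bounds",
                "(1..%d); re-centre the acquisition or shift the plane"),
          center - half_window, center + half_window, nz)
  zs <- (center - half_window):(center + half_window)
  mean_planes <- function(a) {
    if (length(d) == 2) return(a)
    out <- a[, , zs[1]]
    for (z in zs[-1]) out <- out + a[, , z]
    out / length(zs)
  }
  channel_stack(mean_planes(stack$green), mean_planes(stack$red),
                stack$pixel_size_xy, stack$z_step)
}

# Otsu's threshold on a 256-bin histogram of v.
otsu_threshold <- function(v) {
  rng <- range(v)
  if (diff(rng) <= 0) stopf("otsu_threshold: constant image")
  nb <- 256L
  brk <- seq(rng[1], rng[2], length.out = nb + 1L)
  h <- tabulate(pmin(findInterval(v, brk, rightmost.closed = TRUE), nb), nb)
  p <- h / sum(h)
  mids <- (brk[-1] + brk[-(nb + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nb]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

#' Threshold the collapsed image into a mitochondria/background mask
#'
#' Global Otsu threshold computed on the summed-channel image; the mask is
#' every pixel above threshold. Errors on constant images.
#'
#' @param img A 2-D [channel_stack()] (or a plain matrix).
#' @param method Threshold method (only `"otsu"`).
#' @return Logical matrix.
#' @export
threshold_mask <- function(img, method = "otsu") {
  summed <- if (is.matrix(img)) img else {
    s <- as_channel_stack(img)
    s$green + s$red
  }
  thr <- switch(method, otsu = otsu_threshold(as.vector(summed)),
                stopf("threshold_mask: unknown method '%s'", method))
  summed > thr
}

# --- skeleton helpers ---------------------------------------------------

# Graph over skeleton pixels (8-connectivity); returns coords and a
# neighbour list with step weights (1 orthogonal, sqrt(2) diagonal).
skel_graph <- function(sk) {
  idx <- which(sk, arr.ind = TRUE)
  n <- nrow(idx)
  key <- (idx[, 2] - 1L) * nrow(sk) + idx[, 1]
  lut <- integer(nrow(sk) * ncol(sk)); lut[key] <- seq_len(n)
  nbrs <- vector("list", n); wts <- vector("list", n)
  offs <- cbind(dy = c(-1, -1, -1, 0, 0, 1, 1, 1),
                dx = c(-1, 0, 1, -1, 1, -1, 0, 1))
  ww <- sqrt(offs[, 1]^2 + offs[, 2]^2)
  for (i in seq_len(n)) {
    yy <- idx[i, 1] + offs[, 1]; xx <- idx[i, 2] + offs[, 2]
    ok <- yy >= 1 & yy <= nrow(sk) & xx >= 1 & xx <= ncol(sk)
    j <- lut[(xx[ok] - 1L) * nrow(sk) + yy[ok]]
    keep <- j > 0
    nbrs[[i]] <- j[keep]; wts[[i]] <- ww[ok][keep]
  }
  list(coords = idx, nbrs = nbrs, wts = wts, n = n)
}

# Dijkstra from a source over the (tiny) skeleton graph.
skel_dist <- function(g, from) {
  dist <- rep(Inf, g$n); dist[from] <- 0
  done <- rep(FALSE, g$n); prev <- integer(g$n)
  for (it in seq_len(g$n)) {
    u <- which.min(ifelse(done, Inf, dist))
    if (!is.finite(dist[u])) break
    done[u] <- TRUE
    for (k in seq_along(g$nbrs[[u]])) {
      v <- g$nbrs[[u]][k]
      alt <- dist[u] + g$wts[[u]][k]
      if (alt < dist[v]) { dist[v] <- alt; prev[v] <- u }
    }
  }
  list(dist = dist, prev = prev)
}

# Longest geodesic path through the skeleton (double-Dijkstra), returned
# as pixel coordinates in order, with its weighted length.
skel_longest_path <- function(sk) {
  g <- skel_graph(sk)
  if (g$n == 0) return(list(coords = NULL, length = 0))
  if (g$n == 1) return(list(coords = g$coords, length = 0))
  d1 <- skel_dist(g, 1L)
  a <- which.max(ifelse(is.finite(d1$dist), d1$dist, -1))
  d2 <- skel_dist(g, a)
  b <- which.max(ifelse(is.finite(d2$dist), d2$dist, -1))
  path <- b
  while (path[1] != a) path <- c(d2$prev[path[1]], path)
  list(coords = g$coords[path, , drop = FALSE], length = d2$dist[b])
}

# Number of skeleton branch points after ignoring short spurs. A pixel is
# a branch point when its crossing number (0-to-1 transitions around its
# 8-neighbour ring) is >= 3; this is robust to the 2-pixel staircases that
# thinning leaves on diagonals, where plain neighbour counts overcount.
skel_branch_points <- function(sk, prune = 2) {
  ring <- function(m, y, x) {
    # neighbours clockwise from north, with zero padding
    get <- function(yy, xx) {
      if (yy < 1 || yy > nrow(m) || xx < 1 || xx > ncol(m)) 0 else m[yy, xx]
    }
    c(get(y - 1, x), get(y - 1, x + 1), get(y, x + 1), get(y + 1, x + 1),
      get(y + 1, x), get(y + 1, x - 1), get(y, x - 1), get(y - 1, x - 1))
  }
  crossing <- function(m, y, x) {
    r <- ring(m, y, x)
    sum(r == 0 & c(r[-1], r[1]) == 1)
  }
  m <- sk * 1
  for (i in seq_len(prune)) {
    idx <- which(m == 1, arr.ind = TRUE)
    ends <- idx[apply(idx, 1, function(p) crossing(m, p[1], p[2]) <= 1), ,
                drop = FALSE]
    if (nrow(ends) == 0) break
    m[ends] <- 0
  }
  idx <- which(m == 1, arr.ind = TRUE)
  if (nrow(idx) == 0) return(0L)
  cr <- apply(idx, 1, function(p) crossing(m, p[1], p[2]))
  # junction pixels, or excess line-ends beyond the two of a simple rod
  # (thick junction clusters can hide from the crossing-number test)
  max(sum(cr >= 3), sum(cr == 1) - 2L, 0L)
}

# Component solidity: pixel count over convex-hull area of pixel centres
# (capped at 1; thin components have hull area below their pixel count).
comp_solidity <- function(coords) {
  n <- nrow(coords)
  if (n < 4) return(1)
  hull <- grDevices::chull(coords[, 2], coords[, 1])
  hx <- coords[hull, 2]; hy <- coords[hull, 1]
  a <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  min(1, n / max(a, n))
}

#' Label and spatially filter particles
#'
#' 8-connected components of the binary mask each receive exactly one
#' status: `excluded_truncated` for components touching the image margin,
#' `excluded_size` for areas outside the configured window (single bright
#' pixels, unresolvable aggregates), `excluded_ramified` for branched or
#' low-solidity components (overlapping organelles), and `retained`
#' otherwise. Statuses are assigned in that priority order.
#'
#' @param mask Logical matrix.
#' @param config A [pipeline_config()].
#' @param pixel_size Lateral pixel size (um).
#' @return List of class `particle_set`: `labels` (integer matrix),
#'   `records` (data frame: id, n_pixels, area_um2, status), `pixel_size`.
#' @export
filter_particles <- function(mask, config = pipeline_config(),
                             pixel_size = 0.08) {
  stopifnot(is.matrix(mask))
  lab <- .label_components(mask)
  ncomp <- max(lab)
  if (ncomp == 0)
    return(structure(list(labels = lab,
                          records = data.frame(id = integer(0),
                                               n_pixels = integer(0),
                                               area_um2 = numeric(0),
                                               status = character(0)),
                          pixel_size = pixel_size),
                     class = "particle_set"))
  ny <- nrow(mask); nx <- ncol(mask)
  ord <- order(lab[lab > 0])
  coords_all <- which(lab > 0, arr.ind = TRUE)
  labs <- lab[lab > 0]
  split_idx <- split(seq_along(labs), labs)
  status <- character(ncomp); npx <- integer(ncomp)
  for (i in seq_len(ncomp)) {
    co <- coords_all[split_idx[[i]], , drop = FALSE]
    npx[i] <- nrow(co)
    area <- npx[i] * pixel_size^2
    if (any(co[, 1] == 1 | co[, 1] == ny | co[, 2] == 1 | co[, 2] == nx)) {
      status[i] <- "excluded_truncated"
    } else if (area < config$min_area || area > config$max_area) {
      status[i] <- "excluded_size"
    } else {
      y0 <- min(co[, 1]) - 1L; x0 <- min(co[, 2]) - 1L
      sub <- matrix(FALSE, max(co[, 1]) - y0 + 1L, max(co[, 2]) - x0 + 1L)
      sub[cbind(co[, 1] - y0, co[, 2] - x0)] <- TRUE
      sk <- .thin_mask(sub)
      bp <- skel_branch_points(sk, config$spur_prune)
      sol <- comp_solidity(co)
      status[i] <- if (bp > config$max_branch_points ||
                       sol < config$min_solidity)
        "excluded_ramified" else "retained"
    }
  }
  structure(list(labels = lab,
                 records = data.frame(id = seq_len(ncomp), n_pixels = npx,
                                      area_um2 = npx * pixel_size^2,
                                      status = status),
                 pixel_size = pixel_size),
            class = "particle_set")
}

# March from a path end along its local direction until leaving the mask;
# returns the extension length in pixels. Recovers the tip retraction
# inherent to thinning (skeletons stop about half a width short of each
# end of a rod).
end_extension <- function(mask, path, from_start) {
  n <- nrow(path)
  if (n < 2) return(0)
  k <- min(4L, n - 1L)
  if (from_start) {
    tip <- path[1, ]; ref <- path[1 + k, ]
  } else {
    tip <- path[n, ]; ref <- path[n - k, ]
  }
  v <- tip - ref
  nv <- sqrt(sum(v^2))
  if (nv == 0) return(0)
  v <- v / nv
  step <- 0.25
  ext <- 0
  repeat {
    cand <- tip + v * (ext + step)
    yy <- round(cand[1]); xx <- round(cand[2])
    if (yy < 1 || yy > nrow(mask) || xx < 1 || xx > ncol(mask) ||
        !mask[yy, xx]) break
    ext <- ext + step
    if (ext > 1e4) break
  }
  ext
}

#' Measure retained particles on the ratio image
#'
#' For every retained component: length as the geodesic skeleton length
#' (longest path through the morphological skeleton, extended to the
#' component boundary to undo thinning's tip retraction) plus a one-pixel
#' end-cap correction, in um; area as pixel count times pixel area; mean
#' JC-1 ratio over the component's valid ratio voxels; and the centroid in
#' physical coordinates (pixel centre times pixel size, 0-based indices).
#'
#' @param particles A `particle_set` from [filter_particles()].
#' @param ratio A `ratio_image` aligned with the mask.
#' @return The particle records with `length_um`, `mean_ratio`,
#'   `centroid_y_um`, `centroid_x_um` filled for retained rows (`NA`
#'   elsewhere). A particle lying fully in the invalid-ratio mask gets
#'   `mean_ratio = NA` with a warning.
#' @export
measure_particles <- function(particles, ratio) {
  stopifnot(inherits(particles, "particle_set"))
  rec <- particles$records
  px <- particles$pixel_size
  rec$length_um <- NA_real_
  rec$mean_ratio <- NA_real_
  rec$centroid_y_um <- NA_real_
  rec$centroid_x_um <- NA_real_
  lab <- particles$labels
  if (nrow(rec) == 0) return(rec)
  coords_all <- which(lab > 0, arr.ind = TRUE)
  labs <- lab[lab > 0]
  split_idx <- split(seq_along(labs), labs)
  for (i in which(rec$status == "retained")) {
    co <- coords_all[split_idx[[as.character(i)]], , drop = FALSE]
    y0 <- min(co[, 1]) - 2L; x0 <- min(co[, 2]) - 2L
    sub <- matrix(FALSE, max(co[, 1]) - y0 + 2L, max(co[, 2]) - x0 + 2L)
    sub[cbind(co[, 1] - y0, co[, 2] - x0)] <- TRUE
    sk <- .thin_mask(sub)
    lp <- skel_longest_path(sk)
    ext <- if (!is.null(lp$coords) && nrow(lp$coords) >= 2)
      end_extension(sub, lp$coords, TRUE) +
      end_extension(sub, lp$coords, FALSE) else 0
    rec$length_um[i] <- (lp$length + ext + 1) * px
    vals <- ratio$values[cbind(co[, 1], co[, 2])]
    if (all(is.na(vals))) {
      warning(sprintf("particle %d lies fully in the invalid-ratio mask", i),
              call. = FALSE)
    } else {
      rec$mean_ratio[i] <- mean(vals, na.rm = TRUE)
    }
    rec$centroid_y_um[i] <- mean(co[, 1] - 1) * px
    rec$centroid_x_um[i] <- mean(co[, 2] - 1) * px
  }
  rec
}

#' Run the full single-particle pipeline on one stack
#'
#' Deconvolution, automatic focal-plane selection, +/- 2-plane collapse,
#' emission-ratio computation on the collapsed channels, Otsu
#' thresholding of the summed channels, spatial filtering, and
#' per-particle measurement.
#'
#' @param stack A [channel_stack()] or `jc1_scene`.
#' @param psf A `psf_estimate`.
#' @param config A [pipeline_config()].
#' @param focal_plane Optional manual focal-plane override (1-based).
#' @return List of class `segmentation`: `records` (all components with
#'   statuses and measurements), `mask`, `labels`, `collapsed`
#'   (2-D `channel_stack`), `ratio` (`ratio_image`), `focal_plane`.
#' @export
segment_particles <- function(stack, psf, config = pipeline_config(),
                              focal_plane = NULL) {
  stack <- as_channel_stack(stack)
  dec <- deconvolve(stack, psf, config$deconv_iterations)
  fp <- focal_plane %||% select_focal_plane(dec)
  coll <- collapse_planes(dec, fp, config$collapse_half_window)
  ratio <- jc1_ratio(coll)
  mask <- threshold_mask(coll, config$threshold_method)
  parts <- filter_particles(mask, config, stack$pixel_size_xy)
  records <- measure_particles(parts, ratio)
  structure(list(records = records, mask = mask, labels = parts$labels,
                 collapsed = coll, ratio = ratio, focal_plane = fp),
            class = "segmentation")
}
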