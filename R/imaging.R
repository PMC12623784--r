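## Synthetic fluorescence microscopy with known ground truth, and the image
## quantification algorithms (cluster area, ring diameter, FWHM, actin
## cluster, cell volume) exercised against it.
##
## Images are numeric matrices indexed [x, y] (EBImage convention), label
## masks are integer matrices (0 = background), intensities are arbitrary
## units. All pixel coordinates are 1-based.

.need_ebimage <- function() {
  if (!requireNamespace("EBImage", quietly = TRUE))
    stop("the imaging module requires the EBImage package", call. = FALSE)
}

#' Imaging quantification configuration
#'
#' @param sigma Gaussian filter sigma in px (default 2).
#' @param k_std Threshold offset in standard deviations (default 2:
#'   median + 2 sd for cluster detection, mean + 2 sd for phalloidin).
#' @param ring_short_axis Short axis (px) of the elliptical neck region for
#'   ring detection (default 10).
#' @param ring_overlap Minimum object/ellipse intersection-over-area for a
#'   septin ring object (default 0.5).
#' @param phalloidin_axes Long and short axis (px) of the phalloidin neck
#'   ellipse (default `c(30, 20)`).
#' @param phalloidin_overlap Minimum overlap for actin clusters (0.8).
#' @param order_stat Which order statistic builds the cell-cycle intensity
#'   curve (default 10: the 10th-brightest pixel).
#' @param max_ring_objects Maximum retained objects (2 for septin rings,
#'   set 1 for Exo84 clusters).
#' @return Object of class `imaging_config`.
#' @export
imaging_config <- function(sigma = 2, k_std = 2, ring_short_axis = 10,
                           ring_overlap = 0.5, phalloidin_axes = c(30, 20),
                           phalloidin_overlap = 0.8, order_stat = 10L,
                           max_ring_objects = 2L) {
  stopifnot(sigma > 0, ring_overlap > 0, ring_overlap <= 1,
            phalloidin_overlap > 0, phalloidin_overlap <= 1)
  structure(list(sigma = sigma, k_std = k_std,
                 ring_short_axis = ring_short_axis,
                 ring_overlap = ring_overlap,
                 phalloidin_axes = phalloidin_axes,
                 phalloidin_overlap = phalloidin_overlap,
                 order_stat = as.integer(order_stat),
                 max_ring_objects = as.integer(max_ring_objects)),
            class = "imaging_config")
}

# Filled ellipse indicator on a pixel grid.
.ellipse_mask <- function(nx, ny, cx, cy, a, b, theta = 0) {
  x <- matrix(seq_len(nx), nx, ny)
  y <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  dx <- x - cx; dy <- y - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

#' Generate a synthetic fluorescence scene
#'
#' Renders mother-bud cell pairs as ellipses in a labelled mask, a
#' septin-ring signal at each mother-bud neck (the 2D cross-section of a
#' ring seen side-on: a bar across the neck, perpendicular to the
#' mother-bud axis, whose length is the ring diameter), a disc-shaped
#' Cdc42 cluster signal in the mother near the neck, plus Gaussian read
#' noise on a constant background. Ground truth (cluster pixel area, ring
#' diameter, neck position, per-cell geometry) is stored alongside.
#'
#' @param n_cells Number of mother-bud pairs.
#' @param canvas Canvas size `c(nx, ny)` in px.
#' @param mother_axes Range of mother semi-axes (px).
#' @param bud_frac Bud size relative to mother.
#' @param ring_diameter Range of ring outer diameters (px).
#' @param ring_width Ring band thickness (px).
#' @param cluster_radius Range of cluster disc radii (px).
#' @param intensity Peak signal intensity.
#' @param background Background level.
#' @param noise_sd Gaussian read-noise standard deviation.
#' @param seed RNG seed (same seed, identical scene).
#' @return Object of class `synthetic_scene`: `mask` (labelled mother
#'   cells; buds are labelled `label + 1000`), `ring_channel`,
#'   `cluster_channel` (matrices), and `truth` (data frame).
#' @export
generate_scene <- function(n_cells = 4, canvas = c(256, 256),
                           mother_axes = c(18, 24), bud_frac = 0.55,
                           ring_diameter = c(14, 24), ring_width = 2,
                           cluster_radius = c(5, 9),
                           intensity = 1000, background = 100,
                           noise_sd = 0, seed = 1L) {
  set.seed(seed)
  nx <- canvas[1]; ny <- canvas[2]
  mask <- matrix(0L, nx, ny)
  ring <- matrix(0, nx, ny)
  clus <- matrix(0, nx, ny)
  # cells on a jittered grid so they cannot overlap
  ngrid <- ceiling(sqrt(n_cells))
  pitch_x <- nx / ngrid; pitch_y <- ny / ngrid
  truth <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    gx <- (i - 1) %% ngrid; gy <- (i - 1) %/% ngrid
    am <- runif(1, mother_axes[1], mother_axes[2])
    bm <- am * runif(1, 0.75, 0.95)
    ab <- am * bud_frac; bb <- bm * bud_frac
    cx <- (gx + 0.5) * pitch_x - ab / 2
    cy <- (gy + 0.5) * pitch_y
    if (am + ab > min(pitch_x, pitch_y) * 0.9)
      stop("cells too large for canvas; enlarge `canvas` or shrink cells",
           call. = FALSE)
    m_m <- .ellipse_mask(nx, ny, cx, cy, am, bm)
    bx <- cx + am + ab * 0.8      # bud centre; slight neck overlap
    m_b <- .ellipse_mask(nx, ny, bx, cy, ab, bb) & !m_m
    mask[m_m] <- i
    mask[m_b] <- i + 1000L
    neck <- c(cx + am, cy)
    d_out <- runif(1, ring_diameter[1], ring_diameter[2])
    r_out <- d_out / 2
    dx <- matrix(seq_len(nx), nx, ny) - neck[1]
    dy <- matrix(seq_len(ny), nx, ny, byrow = TRUE) - neck[2]
    # ring seen side-on: a thin filled ellipse across the neck whose
    # major axis is the ring diameter (the moment-based major-axis
    # length of a filled ellipse equals its geometric axis)
    band <- (dy / r_out)^2 + (dx / ring_width)^2 <= 1
    ring[band] <- ring[band] + intensity
    mask[band & mask == 0L] <- i     # the neck belongs to the mother cell
    rc <- runif(1, cluster_radius[1], cluster_radius[2])
    ccx <- cx + am - rc - 2      # cluster inside the mother, near the neck
    cpix <- (dx + neck[1] - ccx)^2 + dy^2 <= rc^2
    cpix <- cpix & m_m
    clus[cpix] <- clus[cpix] + intensity
    truth[[i]] <- data.frame(label = i, mother_x = cx, mother_y = cy,
                             mother_a = am, mother_b = bm,
                             bud_x = bx, bud_a = ab,
                             neck_x = neck[1], neck_y = neck[2],
                             ring_outer_diameter = d_out,
                             cluster_area_px = sum(cpix),
                             cluster_radius = rc)
  }
  add_noise <- function(img) {
    img <- img + background
    if (noise_sd > 0) img <- img + matrix(rnorm(nx * ny, 0, noise_sd), nx, ny)
    img
  }
  structure(list(mask = mask, ring_channel = add_noise(ring),
                 cluster_channel = add_noise(clus),
                 truth = do.call(rbind, truth),
                 background = background, noise_sd = noise_sd),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("synthetic_scene: %d cells on %d x %d px, noise sd = %g\n",
              nrow(x$truth), nrow(x$mask), ncol(x$mask), x$noise_sd))
  invisible(x)
}

#' Cdc42 cluster area from a fluorescence image
#'
#' Per cell: Gaussian filter (sigma from config), threshold strictly above
#' `median + k_std * sd` of the filtered intensities within the cell mask,
#' label connected components and keep only the largest one.
#'
#' @param image Intensity matrix.
#' @param mask Integer label mask (mother labels).
#' @param config An [imaging_config()].
#' @param labels Labels to quantify (default: all positive labels).
#' @return Data frame with `label` and `cluster_area_px`.
#' @export
cdc42_cluster_area_image <- function(image, mask, config = imaging_config(),
                                     labels = NULL) {
  .need_ebimage()
  if (is.null(labels)) labels <- setdiff(sort(unique(as.integer(mask))), 0L)
  labels <- labels[labels < 1000L]
  sm <- as.matrix(EBImage::gblur(EBImage::Image(image), sigma = config$sigma))
  out <- lapply(labels, function(lb) {
    cellpix <- mask == lb
    if (!any(cellpix)) stop("empty cell mask for label ", lb, call. = FALSE)
    v <- sm[cellpix]
    thr <- median(v) + config$k_std * sd(v)
    bin <- matrix(0L, nrow(image), ncol(image))
    bin[cellpix & sm > thr] <- 1L
    if (!any(bin == 1L)) return(data.frame(label = lb, cluster_area_px = 0))
    lab <- EBImage::bwlabel(EBImage::Image(bin))
    sizes <- tabulate(as.integer(lab)[as.integer(lab) > 0])
    data.frame(label = lb, cluster_area_px = max(sizes))
  })
  do.call(rbind, out)
}

# Major-axis length (px) of a binary object via image moments.
.major_axis_length <- function(binmat) {
  idx <- which(binmat, arr.ind = TRUE)
  if (nrow(idx) < 2L) return(as.numeric(nrow(idx)))
  x <- idx[, 1]; y <- idx[, 2]
  cxx <- var(x) * (length(x) - 1) / length(x)
  cyy <- var(y) * (length(y) - 1) / length(y)
  cxy <- cov(x, y) * (length(x) - 1) / length(x)
  ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2), symmetric = TRUE)$values
  4 * sqrt(max(ev[1], 0))   # major axis length of the equivalent ellipse
}

#' Septin ring (or Exo84 cluster) diameter from an image time series
#'
#' Implements the neck-ellipse procedure: an elliptical region is centred
#' on the mother-bud neck (short axis `ring_short_axis` px along the
#' mother-bud axis, long axis spanning the combined cell hull); per frame
#' the `order_stat`-th brightest pixel inside the mother-bud object builds
#' an intensity curve over the series; the threshold is the midpoint of the
#' curve's minimum and maximum; each frame is segmented at that threshold
#' within the mother-bud object, objects overlapping the ellipse by at
#' least `ring_overlap` (intersection / object area) are kept (at most
#' `max_ring_objects`), and the ring diameter of a frame is the largest
#' major-axis length among kept objects. The maximum over frames is
#' reported.
#'
#' @param frames List of intensity matrices (one per time point) or a
#'   single matrix.
#' @param mask Label mask; the mother-bud object is
#'   `mask == label | mask == label + 1000`.
#' @param label Mother label.
#' @param neck Neck position `c(x, y)` in px.
#' @param axis_dir Unit 2-vector of the mother-bud axis (default along x).
#' @param config An [imaging_config()].
#' @return List: `diameter` (px; `NA` with `discarded = TRUE` when no frame
#'   has a qualifying object), `per_frame`, `curve`, `threshold`.
#' @export
ring_diameter_image <- function(frames, mask, label, neck,
                                axis_dir = c(1, 0),
                                config = imaging_config()) {
  .need_ebimage()
  if (is.matrix(frames)) frames <- list(frames)
  obj <- mask == label | mask == label + 1000L
  if (!any(obj)) stop("no pixels for label ", label, call. = FALSE)
  nx <- nrow(mask); ny <- ncol(mask)
  axis_dir <- axis_dir / sqrt(sum(axis_dir^2))
  theta <- atan2(axis_dir[2], axis_dir[1])
  # long axis: to the hull of the combined object, perpendicular to the
  # mother-bud axis
  idx <- which(obj, arr.ind = TRUE)
  perp <- c(-axis_dir[2], axis_dir[1])
  span <- (idx[, 1] - neck[1]) * perp[1] + (idx[, 2] - neck[2]) * perp[2]
  long_ax <- max(abs(span))
  ell <- .ellipse_mask(nx, ny, neck[1], neck[2],
                       a = config$ring_short_axis / 2, b = long_ax,
                       theta = theta)
  curve <- vapply(frames, function(fr) {
    v <- sort(fr[obj], decreasing = TRUE)
    v[min(config$order_stat, length(v))]
  }, numeric(1))
  thr <- (max(curve) + min(curve)) / 2
  if (max(curve) - min(curve) < 1e-9 * max(abs(curve), 1)) {
    # flat cell-cycle curve (e.g. a single frame): fall back to the
    # midpoint between the peak statistic and the dimmest object pixel
    thr <- (max(curve) + min(frames[[1]][obj])) / 2
  }
  per_frame <- rep(NA_real_, length(frames))
  for (k in seq_along(frames)) {
    bin <- matrix(0L, nx, ny)
    bin[obj & frames[[k]] > thr] <- 1L
    if (!any(bin == 1L)) next
    lab <- as.matrix(EBImage::bwlabel(EBImage::Image(bin)))
    keep_d <- c()
    for (ob in seq_len(max(lab))) {
      pix <- lab == ob
      ov <- sum(pix & ell) / sum(pix)
      if (ov >= config$ring_overlap)
        keep_d <- c(keep_d, .major_axis_length(pix))
    }
    if (length(keep_d)) {
      keep_d <- sort(keep_d, decreasing = TRUE)
      keep_d <- keep_d[seq_len(min(length(keep_d), config$max_ring_objects))]
      per_frame[k] <- max(keep_d)
    }
  }
  if (all(is.na(per_frame)))
    return(list(diameter = NA_real_, discarded = TRUE,
                per_frame = per_frame, curve = curve, threshold = thr))
  list(diameter = max(per_frame, na.rm = TRUE), discarded = FALSE,
       per_frame = per_frame, curve = curve, threshold = thr)
}

#' Ring diameter as full width at half maximum of a contour profile
#'
#' The minimum of the 1D intensity profile is the baseline; the FWHM of the
#' profile above baseline estimates the ring diameter. Crossings are
#' linearly interpolated. With multiple equal maxima the widest contiguous
#' half-maximum crossing is reported with a warning.
#'
#' @param profile Numeric intensity profile (e.g. along the cell contour).
#' @return FWHM in profile units (px).
#' @export
ring_diameter_fwhm <- function(profile) {
  n <- length(profile)
  if (n < 3L) stop("profile too short", call. = FALSE)
  base <- min(profile)
  peak <- max(profile)
  if (peak <= base) stop("flat profile: no peak", call. = FALSE)
  half <- base + (peak - base) / 2
  above <- profile >= half
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ridx <- which(runs$values)
  if (length(ridx) > 1L)
    warning("multiple half-maximum crossings; reporting the widest",
            call. = FALSE)
  widths <- numeric(length(ridx))
  for (q in seq_along(ridx)) {
    i0 <- starts[ridx[q]]; i1 <- ends[ridx[q]]
    left <- if (i0 > 1L)
      (i0 - 1) + (half - profile[i0 - 1]) / (profile[i0] - profile[i0 - 1])
    else i0
    right <- if (i1 < n)
      i1 + (profile[i1] - half) / (profile[i1] - profile[i1 + 1])
    else i1
    widths[q] <- right - left
  }
  max(widths)
}

#' Actin cluster area from phalloidin staining
#'
#' Gaussian filter; an ellipse (`phalloidin_axes`, long axis perpendicular
#' to the mother-bud axis) is centred at the neck; threshold is the ellipse
#' mean plus `k_std` standard deviations; the whole image is thresholded,
#' clusters overlapping the ellipse by less than `phalloidin_overlap`
#' (intersection / cluster area) are dropped, and the remaining pixel
#' count is returned.
#'
#' @param image Intensity matrix.
#' @param neck Neck position `c(x, y)`.
#' @param axis_dir Mother-bud axis direction.
#' @param config An [imaging_config()].
#' @return Actin cluster area in px.
#' @export
actin_cluster_area_phalloidin <- function(image, neck, axis_dir = c(1, 0),
                                          config = imaging_config()) {
  .need_ebimage()
  nx <- nrow(image); ny <- ncol(image)
  axis_dir <- axis_dir / sqrt(sum(axis_dir^2))
  theta <- atan2(axis_dir[2], axis_dir[1]) + pi / 2  # long axis perpendicular
  ell <- .ellipse_mask(nx, ny, neck[1], neck[2],
                       a = config$phalloidin_axes[1] / 2,
                       b = config$phalloidin_axes[2] / 2, theta = theta)
  if (!any(ell)) stop("neck ellipse is empty", call. = FALSE)
  sm <- as.matrix(EBImage::gblur(EBImage::Image(image), sigma = config$sigma))
  v <- sm[ell]
  thr <- mean(v) + config$k_std * sd(v)
  # guard against featureless reference regions: smoothing ripple on a
  # flat field must not register as signal
  thr <- max(thr, mean(v) * (1 + 1e-9) + 1e-12)
  bin <- matrix(0L, nx, ny)
  bin[sm > thr] <- 1L
  if (!any(bin == 1L)) return(0)
  lab <- as.matrix(EBImage::bwlabel(EBImage::Image(bin)))
  total <- 0
  for (ob in seq_len(max(lab))) {
    pix <- lab == ob
    if (sum(pix & ell) / sum(pix) >= config$phalloidin_overlap)
      total <- total + sum(pix)
  }
  total
}

#' Cell volume from a 2D mask by rotational symmetry
#'
#' Aligns the mask to its major axis and revolves each 1-px slice
#' perpendicular to it: `V = sum pi (width/2)^2 * 1`.
#'
#' @param mask Logical or 0/1 matrix of one connected cell.
#' @return Volume in voxel units (px^3).
#' @export
cell_volume_from_mask <- function(mask) {
  .need_ebimage()
  bin <- matrix(as.integer(mask > 0), nrow(mask), ncol(mask))
  lab <- as.matrix(EBImage::bwlabel(EBImage::Image(bin)))
  if (max(lab) != 1L)
    stop("mask must contain exactly one connected cell (found ",
         max(lab), ")", call. = FALSE)
  idx <- which(bin == 1L, arr.ind = TRUE)
  xy <- sweep(idx, 2, colMeans(idx))
  ev <- eigen(cov(xy), symmetric = TRUE)
  u <- as.numeric(xy %*% ev$vectors[, 1])   # along major axis
  v <- as.numeric(xy %*% ev$vectors[, 2])
  bins <- floor(u - min(u))                 # 1-px slices
  width <- tapply(v, bins, function(z) diff(range(z)) + 1)
  sum(pi * (width / 2)^2)
}
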