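#' Segmentation parameters for thick-filament detection
#'
#' Parameter block for [segment_filaments()]. Defaults assume filament
#' diameters of roughly 10--20 px; scale the kernel sizes with magnification.
#'
#' @param median_kernel_px odd median-filter kernel width (px).
#' @param threshold_method `"otsu"` (default) or `"fixed"`.
#' @param fixed_threshold intensity threshold used when
#'   `threshold_method = "fixed"`.
#' @param closing_radius_px radius of the disc structuring element for
#'   morphological closing (px).
#' @param smooth_sigma_px sigma of the Gaussian smoothing convolution (px).
#' @param canny_low,canny_high hysteresis thresholds on the gradient
#'   magnitude, or `"auto"` for (0.5, 1.5) times the median nonzero gradient
#'   of the smoothed image.
#' @param min_area_nm2,max_area_nm2 area filter rejecting noise specks and
#'   merged blobs (nm^2).
#' @param exclude_border drop filaments whose filled contour touches the
#'   image border.
#' @return A `seg_params` list.
#' @export
seg_params <- function(median_kernel_px = 5, threshold_method = c("otsu", "fixed"),
                       fixed_threshold = 0.5, closing_radius_px = 3,
                       smooth_sigma_px = 1, canny_low = "auto", canny_high = "auto",
                       min_area_nm2 = 50, max_area_nm2 = 2000,
                       exclude_border = FALSE) {
  threshold_method <- match.arg(threshold_method)
  stopifnot(median_kernel_px >= 1, median_kernel_px %% 2 == 1,
            min_area_nm2 < max_area_nm2, closing_radius_px >= 0,
            smooth_sigma_px > 0)
  structure(list(median_kernel_px = median_kernel_px,
                 threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 closing_radius_px = closing_radius_px,
                 smooth_sigma_px = smooth_sigma_px,
                 canny_low = canny_low, canny_high = canny_high,
                 min_area_nm2 = min_area_nm2, max_area_nm2 = max_area_nm2,
                 exclude_border = exclude_border),
            class = "seg_params")
}

shift_mat <- function(m, dx, dy) {
  # shift with zero padding; dx along first index (x), dy along second (y)
  nx <- nrow(m); ny <- ncol(m)
  out <- matrix(0, nx, ny)
  xs <- max(1, 1 + dx):min(nx, nx + dx)
  ys <- max(1, 1 + dy):min(ny, ny + dy)
  out[xs, ys] <- m[xs - dx, ys - dy]
  out
}

#' Canny edge detection
#'
#' Sobel gradients, 4-direction non-maximum suppression and hysteresis
#' linking. Returns a logical edge matrix.
#'
#' @param img numeric matrix.
#' @param low,high hysteresis thresholds on gradient magnitude, or `"auto"`
#'   for (0.5, 1.5) times the median nonzero gradient magnitude.
#' @return logical matrix of edge pixels.
#' @export
canny_edges <- function(img, low = "auto", high = "auto") {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  ky <- t(kx)
  gx <- EBImage::filter2(EBImage::Image(img), kx)
  gy <- EBImage::filter2(EBImage::Image(img), ky)
  gx <- EBImage::imageData(gx); gy <- EBImage::imageData(gy)
  mag <- sqrt(gx^2 + gy^2)
  nz <- mag[mag > 1e-12]
  if (!length(nz)) return(matrix(FALSE, nrow(img), ncol(img)))
  m <- median(nz)
  if (identical(low, "auto")) low <- 0.5 * m
  if (identical(high, "auto")) high <- 1.5 * m

  # quantize gradient direction to 0/45/90/135 degrees
  ang <- atan2(gy, gx)
  sector <- (round(ang / (pi / 4)) %% 4)
  off <- list(`0` = c(1, 0), `1` = c(1, 1), `2` = c(0, 1), `3` = c(-1, 1))
  nms <- matrix(FALSE, nrow(img), ncol(img))
  for (s in 0:3) {
    d <- off[[as.character(s)]]
    nb1 <- shift_mat(mag, d[1], d[2])
    nb2 <- shift_mat(mag, -d[1], -d[2])
    sel <- sector == s & mag >= nb1 & mag >= nb2
    nms <- nms | sel
  }
  weak <- nms & mag > low
  strong <- nms & mag > high
  if (!any(strong)) return(matrix(FALSE, nrow(img), ncol(img)))
  lab <- EBImage::bwlabel(EBImage::Image(weak * 1))
  lab <- EBImage::imageData(lab)
  keep <- unique(lab[strong])
  keep <- keep[keep > 0]
  matrix(lab %in% keep, nrow(img), ncol(img)) & weak
}

#' Segment thick myosin filaments in a cross-sectional micrograph
#'
#' Operator chain: median filter, binarization (Otsu or fixed threshold),
#' morphological closing, Gaussian convolution smoothing, Canny edge
#' detection, filling of closed edge contours, connected-component labeling,
#' area filtering and optional border exclusion. Per-filament area is the
#' count of thresholded pixels within each filled contour times
#' `nm_per_pixel^2`.
#'
#' @param m a `micrograph` (list with `image`, `nm_per_pixel`, `id`), e.g.
#'   from [gen_em_micrograph()] or [read_micrograph()].
#' @param p a [seg_params()] block.
#' @return A `filament_set`: data.frame with columns `label`, `cx_nm`,
#'   `cy_nm`, `area_nm2`, `border`, with attributes `nm_per_pixel`,
#'   `micrograph_id` and `empty` (TRUE when nothing survived filtering).
#' @export
segment_filaments <- function(m, p = seg_params()) {
  img <- m$image
  if (!length(img)) stop("empty image")
  if (any(!is.finite(img))) stop("non-finite pixel intensities")
  npp <- m$nm_per_pixel
  stopifnot(npp > 0)
  img <- pmin(pmax(img, 0), 1)
  if (diff(range(img)) < 1e-12) {             # uniform image: nothing to segment
    out <- data.frame(label = integer(0), cx_nm = numeric(0), cy_nm = numeric(0),
                      area_nm2 = numeric(0), border = logical(0))
    attr(out, "nm_per_pixel") <- npp
    attr(out, "micrograph_id") <- m$id
    attr(out, "image_size_nm") <- dim(img) * npp
    attr(out, "empty") <- TRUE
    class(out) <- c("filament_set", "data.frame")
    warning("no filaments detected after filtering")
    return(out)
  }

  x <- EBImage::Image(img)
  if (p$median_kernel_px > 1)
    x <- EBImage::medianFilter(x, (p$median_kernel_px - 1) / 2)
  thr <- if (p$threshold_method == "otsu") EBImage::otsu(x) else p$fixed_threshold
  bin <- x > thr
  if (p$closing_radius_px > 0)
    bin <- EBImage::closing(bin, EBImage::makeBrush(2 * p$closing_radius_px + 1, "disc"))
  mask <- EBImage::imageData(bin) > 0

  # zero-pad so blobs clipped by the frame still yield closed edge contours;
  # their truncated areas are flagged via `border` but their centres remain
  # available as spacing neighbours
  pad <- ceiling(3 * p$smooth_sigma_px) + 2
  nx0 <- nrow(mask); ny0 <- ncol(mask)
  mpad <- matrix(FALSE, nx0 + 2 * pad, ny0 + 2 * pad)
  mpad[pad + seq_len(nx0), pad + seq_len(ny0)] <- mask

  bw <- EBImage::makeBrush(2 * ceiling(3 * p$smooth_sigma_px) + 1, "gaussian",
                           sigma = p$smooth_sigma_px)
  smooth <- EBImage::imageData(EBImage::filter2(EBImage::Image(mpad * 1), bw))

  edges <- canny_edges(smooth, p$canny_low, p$canny_high)
  filled <- EBImage::fillHull(EBImage::Image(edges * 1))
  lab <- EBImage::imageData(EBImage::bwlabel(filled))
  lab <- lab[pad + seq_len(nx0), pad + seq_len(ny0)]

  empty_set <- function() {
    out <- data.frame(label = integer(0), cx_nm = numeric(0), cy_nm = numeric(0),
                      area_nm2 = numeric(0), border = logical(0))
    attr(out, "nm_per_pixel") <- npp
    attr(out, "micrograph_id") <- m$id
    attr(out, "empty") <- TRUE
    class(out) <- c("filament_set", "data.frame")
    warning("no filaments detected after filtering")
    out
  }
  nlab <- max(lab)
  if (nlab == 0) return(empty_set())

  # measure each filled contour on the thresholded mask: the mask crosses the
  # threshold at the filament boundary, so its pixel count is unbiased, while
  # the filled contour includes the edge ring itself
  sel <- lab > 0 & mask
  labs_in <- lab[sel]
  nx <- nrow(lab); ny <- ncol(lab)
  idx <- which(sel)
  ix <- ((idx - 1) %% nx) + 1
  iy <- ((idx - 1) %/% nx) + 1
  area_px <- tabulate(labs_in, nbins = nlab)
  sx <- rowsum_by(ix, labs_in, nlab)
  sy <- rowsum_by(iy, labs_in, nlab)

  # border contact judged on the filled contour
  border_labs <- unique(c(lab[1, ], lab[nx, ], lab[, 1], lab[, ny]))
  border_labs <- border_labs[border_labs > 0]

  keep <- which(area_px > 0)
  if (!length(keep)) return(empty_set())
  out <- data.frame(label = keep,
                    cx_nm = (sx[keep] / area_px[keep] - 0.5) * npp,
                    cy_nm = (sy[keep] / area_px[keep] - 0.5) * npp,
                    area_nm2 = area_px[keep] * npp^2,
                    border = keep %in% border_labs)
  out <- out[out$area_nm2 >= p$min_area_nm2 & out$area_nm2 <= p$max_area_nm2, ,
             drop = FALSE]
  if (p$exclude_border) out <- out[!out$border, , drop = FALSE]
  if (!nrow(out)) return(empty_set())
  out$label <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "nm_per_pixel") <- npp
  attr(out, "micrograph_id") <- m$id
  attr(out, "image_size_nm") <- c(nx * npp, ny * npp)
  attr(out, "empty") <- FALSE
  class(out) <- c("filament_set", "data.frame")
  out
}

rowsum_by <- function(x, g, n) {
  out <- numeric(n)
  s <- rowsum(x, g)
  out[as.integer(rownames(s))] <- s
  out
}

#' Interfilament distance and cross-sectional-area morphometry
#'
#' For each eligible focal filament, the mean Euclidean distance from its
#' centre of mass to its six nearest neighbours is computed; the reported
#' interfilament distance is the across-filament mean of these values minus
#' the equivalent-circle diameter \eqn{2\sqrt{\bar A / \pi}}, where
#' \eqn{\bar A} is the mean filament area of the set (or an externally
#' supplied, e.g. pooled per-genotype, mean diameter). Border-touching
#' filaments are excluded as focal filaments (their areas are truncated) but
#' still count as neighbours. A filament is additionally ineligible as a
#' focal filament when its distance to the image edge is smaller than its
#' own k-th-neighbour distance: in that case part of its true neighbourhood
#' may lie outside the analyzed frame, which would otherwise bias the mean
#' neighbour distance upward near the frame edge.
#'
#' @param fs a `filament_set` from [segment_filaments()] (or a data.frame
#'   with `cx_nm`, `cy_nm`, `area_nm2`, `border`, `label`; the image extent
#'   is taken from the `image_size_nm` attribute, falling back to the
#'   bounding box of the centres).
#' @param equivalent_diameter `"from_set"` (default: computed from the mean
#'   area of non-border filaments) or a numeric diameter in nm.
#' @param k number of nearest neighbours (6 for a hexagonal lattice).
#' @return A `morphometry_result` list: `mean_csa`,
#'   `mean_interfilament_distance`, `mean_center_distance`, `n_filaments`,
#'   `n_focal`, `equivalent_diameter_used`, `negative_distance` flag, and the
#'   per-focal-filament mean neighbour distances (`per_filament_nn`).
#' @export
interfilament_distance <- function(fs, equivalent_diameter = "from_set", k = 6) {
  n <- nrow(fs)
  if (n < k + 1)
    stop("need at least ", k + 1, " filaments (each focal filament needs ",
         k, " neighbours)")
  pts <- cbind(fs$cx_nm, fs$cy_nm)
  dmat <- as.matrix(stats::dist(pts))
  knn <- function(i) {
    d <- dmat[i, -i]
    labs <- fs$label[-i]
    ord <- order(d, labs)           # stable tie-break by label
    d[ord[seq_len(k)]]
  }
  kth <- vapply(seq_len(n), function(i) max(knn(i)), numeric(1))
  sz <- attr(fs, "image_size_nm")
  if (is.null(sz)) {
    bb <- c(min(pts[, 1]), max(pts[, 1]), min(pts[, 2]), max(pts[, 2]))
  } else {
    bb <- c(0, sz[1], 0, sz[2])
  }
  edge_dist <- pmin(pts[, 1] - bb[1], bb[2] - pts[, 1],
                    pts[, 2] - bb[3], bb[4] - pts[, 2])
  eligible <- (!fs$border) & edge_dist >= kth
  focal <- if (any(eligible)) which(eligible) else
    if (any(!fs$border)) which(!fs$border) else seq_len(n)
  per_focal <- vapply(focal, function(i) mean(knn(i)), numeric(1))

  areas <- fs$area_nm2[if (any(!fs$border)) !fs$border else TRUE]
  mean_csa <- mean(areas)
  eq_d <- if (identical(equivalent_diameter, "from_set"))
    2 * sqrt(mean_csa / pi) else as.numeric(equivalent_diameter)
  center_d <- mean(per_focal)
  ifd <- center_d - eq_d
  structure(list(mean_csa = mean_csa,
                 mean_interfilament_distance = ifd,
                 mean_center_distance = center_d,
                 n_filaments = n, n_focal = length(focal),
                 equivalent_diameter_used = eq_d,
                 negative_distance = ifd < 0,
                 per_filament_nn = per_focal),
            class = "morphometry_result")
}

#' Estimate the dominant lattice spacing by Fourier analysis
#'
#' Radially averaged power spectrum of the 2-D discrete Fourier transform of
#' the (mean-subtracted) micrograph; the dominant spacing is the reciprocal
#' of the peak spatial frequency. For a hexagonal filament lattice with
#' centre spacing \eqn{d} the first diffraction ring sits at the row
#' (plane) spacing \eqn{d\sqrt{3}/2}, so the hexagonal lattice constant
#' implied by the peak is also returned.
#'
#' @param m a `micrograph` list (`image`, `nm_per_pixel`).
#' @param spacing_range search window for the spacing (nm),
#'   default `c(10, 100)`.
#' @param peak_snr minimum ratio of peak power to the median in-window power
#'   for the peak to be considered defined.
#' @return list with `spacing_nm` (1 / peak frequency), `lattice_d_nm`
#'   (`spacing_nm * 2 / sqrt(3)`), `peak_freq` (1/nm), and `defined`
#'   (FALSE when no peak rises above background, in which case the spacings
#'   are `NA`).
#' @export
estimate_spacing_fft <- function(m, spacing_range = c(10, 100), peak_snr = 10) {
  img <- m$image
  npp <- m$nm_per_pixel
  nx <- nrow(img); ny <- ncol(img)
  P <- Mod(fft(img - mean(img)))^2
  fx <- ((seq_len(nx) - 1) %% nx)
  fx <- ifelse(fx > nx / 2, fx - nx, fx) / (nx * npp)
  fy <- ((seq_len(ny) - 1) %% ny)
  fy <- ifelse(fy > ny / 2, fy - ny, fy) / (ny * npp)
  fr <- sqrt(outer(fx^2, fy^2, "+"))
  f_lo <- 1 / spacing_range[2]; f_hi <- 1 / spacing_range[1]
  sel <- fr >= f_lo & fr <= f_hi
  if (!any(sel)) stop("spacing_range outside the resolvable frequency window")
  # radial binning at the fundamental frequency resolution
  df <- 1 / (max(nx, ny) * npp)
  bins <- round(fr[sel] / df)
  pow <- tapply(P[sel], bins, mean)
  freq <- as.numeric(names(pow)) * df
  bg <- median(pow)
  i_pk <- which.max(pow)
  if (pow[i_pk] < peak_snr * bg)
    return(list(spacing_nm = NA_real_, lattice_d_nm = NA_real_,
                peak_freq = NA_real_, defined = FALSE))
  list(spacing_nm = 1 / freq[i_pk],
       lattice_d_nm = (1 / freq[i_pk]) * 2 / sqrt(3),
       peak_freq = freq[i_pk], defined = TRUE)
}

#' Shoelace area of a polygon
#'
#' Absolute area of a simple polygon given its ordered vertices; used for
#' manually delineated organelle (e.g. mitochondrial) outlines.
#'
#' @param vertices two-column matrix or data.frame of ordered vertex
#'   coordinates (nm); at least three non-collinear points.
#' @return area in nm^2.
#' @export
polygon_area <- function(vertices) {
  v <- as.matrix(vertices)
  if (nrow(v) < 3) stop("a polygon needs at least 3 vertices")
  x <- v[, 1]; y <- v[, 2]
  a <- 0.5 * abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y))
  scale2 <- max(diff(range(x)), diff(range(y)))^2
  if (a <= 1e-12 * max(scale2, 1)) stop("vertices are collinear (zero area)")
  a
}

#' Percent occurrence of a per-animal phenotype
#'
#' Bookkeeping for presence/absence phenotypes scored per animal (e.g.
#' Z-disc streaming in electron micrographs): 100 * positives / total.
#'
#' @param per_animal_flags named logical vector (or list) of per-animal
#'   presence calls.
#' @param digits rounding, default nearest integer.
#' @return percent occurrence (numeric scalar).
#' @export
region_occurrence_summary <- function(per_animal_flags, digits = 0) {
  flags <- unlist(per_animal_flags)
  if (!length(flags)) stop("empty per-animal map")
  stopifnot(is.logical(flags))
  round(100 * mean(flags), digits)
}

#' Seeded sampling of analysis regions within a micrograph
#'
#' Implements the sampling protocol of quantifying a fixed number of randomly
#' selected regions per micrograph that together include a minimum number of
#' filaments. The image frame is divided into a grid of candidate windows;
#' `n_regions` distinct windows are drawn with the seed, and filaments are
#' assigned by centroid.
#'
#' @param fs a `filament_set`.
#' @param image_size_nm numeric `c(width, height)` of the source image (nm).
#' @param n_regions number of regions to draw (default 3).
#' @param grid grid subdivision per axis (default 2, i.e. 4 candidate
#'   windows).
#' @param min_filaments minimum total filaments required across the sampled
#'   regions (default 100); a warning is issued below it.
#' @param seed integer seed.
#' @return the subset of `fs` falling in the sampled regions, with a
#'   `region_id` column; attribute `regions` holds the window rectangles.
#' @export
sample_regions <- function(fs, image_size_nm, n_regions = 3, grid = 2,
                           min_filaments = 100, seed = 1) {
  stopifnot(n_regions >= 1, grid >= 1, n_regions <= grid^2)
  wx <- image_size_nm[1] / grid; wy <- image_size_nm[2] / grid
  cells <- expand.grid(ix = seq_len(grid), iy = seq_len(grid))
  pick <- withr::with_seed(seed, sample(nrow(cells), n_regions))
  out <- NULL
  regions <- data.frame(region_id = seq_len(n_regions),
                        x0 = (cells$ix[pick] - 1) * wx, x1 = cells$ix[pick] * wx,
                        y0 = (cells$iy[pick] - 1) * wy, y1 = cells$iy[pick] * wy)
  for (r in seq_len(n_regions)) {
    inr <- fs$cx_nm >= regions$x0[r] & fs$cx_nm < regions$x1[r] &
      fs$cy_nm >= regions$y0[r] & fs$cy_nm < regions$y1[r]
    sub <- fs[inr, , drop = FALSE]
    if (nrow(sub)) sub$region_id <- r
    out <- rbind(out, sub)
  }
  if (is.null(out) || nrow(out) < min_filaments)
    warning("sampled regions contain fewer than ", min_filaments, " filaments")
  attr(out, "nm_per_pixel") <- attr(fs, "nm_per_pixel")
  attr(out, "micrograph_id") <- attr(fs, "micrograph_id")
  attr(out, "regions") <- regions
  class(out) <- c("filament_set", "data.frame")
  out
}
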