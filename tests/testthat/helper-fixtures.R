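# fixtures built in code, shared across test files

# seven hexagonal sites: one centre + its six first-shell neighbours
hex7_centers <- function(d = 40, origin = c(80, 80)) {
  ang <- (0:5) * pi / 3
  rbind(origin,
        cbind(origin[1] + d * cos(ang), origin[2] + d * sin(ang)))
}

# micrograph with a single centred disk, built without the lattice generator
single_disk_micrograph <- function(r_nm = 9, nm_per_pixel = 1, size_px = 64,
                                   bg = 0.3, fg = 0.7) {
  img <- matrix(bg, size_px, size_px)
  cx <- size_px / 2 * nm_per_pixel
  px <- (seq_len(size_px) - 0.5) * nm_per_pixel
  inside <- outer((px - cx)^2, (px - cx)^2, "+") <= r_nm^2
  img[inside] <- fg
  list(image = img, nm_per_pixel = nm_per_pixel, id = "single_disk",
       true_area = sum(inside) * nm_per_pixel^2)
}

# brute-force mean k-NN centre distance with the same focal-eligibility rule
# as interfilament_distance: non-border filaments whose distance to the frame
# edge is at least their own k-th neighbour distance
brute_force_knn <- function(fs, image_size_nm, k = 6) {
  pts <- cbind(fs$cx_nm, fs$cy_nm)
  n <- nrow(pts)
  per <- kth <- numeric(n)
  for (i in seq_len(n)) {
    d <- sqrt((pts[, 1] - pts[i, 1])^2 + (pts[, 2] - pts[i, 2])^2)[-i]
    labs <- fs$label[-i]
    ord <- order(d, labs)
    per[i] <- mean(d[ord[1:k]])
    kth[i] <- d[ord[k]]
  }
  edge <- pmin(pts[, 1], image_size_nm[1] - pts[, 1],
               pts[, 2], image_size_nm[2] - pts[, 2])
  focal <- which(!fs$border & edge >= kth)
  list(focal = focal, per_focal = per[focal], mean = mean(per[focal]))
}
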