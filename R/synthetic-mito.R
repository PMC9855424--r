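# Synthetic mitochondrial network images and paired ROS channels.

#' Generate a toy mitochondrial network image from a skeleton layout
#'
#' Rasterizes a user-specified skeleton (list of line segments in 0-based
#' pixel coordinates), dilates it to a tube of the requested thickness,
#' applies a Gaussian blur and adds noise -- a controllable stand-in for
#' a MitoTracker channel. Ground truth (individuals, networks, branch
#' counts and lengths) is computed analytically from the layout graph:
#' segments sharing endpoints are joined; a segment endpoint touching
#' another segment's interior splits it (T-junction). Segment pairs
#' crossing interior-to-interior are rejected because rasterization would
#' merge components the layout keeps distinct, making the truth
#' ambiguous.
#'
#' @param layout list of segments, each `c(x0, y0, x1, y1)` in 0-based
#'   pixel coordinates.
#' @param size image `c(n_row, n_col)`; default fits the layout with a
#'   margin.
#' @param thickness_px odd integer tube diameter in pixels (1 = bare
#'   skeleton).
#' @param blur_sigma_px Gaussian blur SD in pixels (0 = none).
#' @param noise_sigma additive Gaussian noise SD (intensity units).
#' @param fg,bg foreground (tube) and background intensity levels.
#' @param seed integer RNG seed.
#' @return numeric matrix with a `synthetic_spec` attribute; `truth`
#'   holds `n_individuals`, `n_networks`, `branches_per_network`,
#'   `n_branches`, `total_branch_length`, `mean_branch_length`, and the
#'   rasterized skeleton mask (`skeleton_mask`).
#' @export
make_mito_image <- function(layout, size = NULL, thickness_px = 3,
                            blur_sigma_px = 0, noise_sigma = 0,
                            fg = 200, bg = 10, seed = 0) {
  if (!length(layout)) stop("empty layout: no segments to draw",
                            call. = FALSE)
  segs <- do.call(rbind, lapply(layout, function(s) {
    if (length(s) != 4L || any(!is.finite(s))) {
      stop("each segment must be c(x0, y0, x1, y1)", call. = FALSE)
    }
    as.numeric(s)
  }))
  margin <- ceiling(thickness_px / 2) + ceiling(3 * blur_sigma_px) + 2
  if (is.null(size)) {
    size <- c(max(segs[, c(2, 4)]) + margin + 1,
              max(segs[, c(1, 3)]) + margin + 1)
  }
  nr <- as.integer(size[1]); nc <- as.integer(size[2])
  if (any(segs[, c(1, 3)] < margin - 1) || any(segs[, c(2, 4)] < margin - 1)) {
    # allow tight layouts but never off-image tubes
    if (any(segs[, c(1, 3)] < 0) || any(segs[, c(2, 4)] < 0) ||
        any(segs[, c(1, 3)] > nc - 1) || any(segs[, c(2, 4)] > nr - 1)) {
      stop("segment endpoints fall outside the image", call. = FALSE)
    }
  }
  check_layout_crossings(segs)
  truth <- layout_truth(segs)
  # rasterize: dense sampling along each segment
  mask <- matrix(FALSE, nr, nc)
  for (r in seq_len(nrow(segs))) {
    len <- sqrt((segs[r, 3] - segs[r, 1])^2 + (segs[r, 4] - segs[r, 2])^2)
    tt <- seq(0, 1, length.out = max(2L, ceiling(len * 4) + 1L))
    xs <- round(segs[r, 1] + tt * (segs[r, 3] - segs[r, 1]))
    ys <- round(segs[r, 2] + tt * (segs[r, 4] - segs[r, 2]))
    mask[cbind(ys + 1L, xs + 1L)] <- TRUE
  }
  tube <- mask
  if (thickness_px > 1) {
    brush <- EBImage::makeBrush(odd_size(thickness_px), shape = "disc")
    tube <- EBImage::dilate(mask * 1, brush) > 0
  }
  img <- bg + (fg - bg) * (tube * 1)
  if (blur_sigma_px > 0) img <- as.matrix(EBImage::gblur(img, blur_sigma_px))
  img <- with_seed(seed, {
    if (noise_sigma > 0) img + stats::rnorm(length(img), 0, noise_sigma)
    else img
  })
  img <- matrix(img, nr, nc)
  params <- list(thickness_px = thickness_px, blur_sigma_px = blur_sigma_px,
                 noise_sigma = noise_sigma, fg = fg, bg = bg,
                 n_segments = nrow(segs))
  truth$skeleton_mask <- mask
  truth$tube_area_px <- sum(tube)
  attr(img, "synthetic_spec") <-
    synthetic_spec(seed, "mito_image", params, truth)
  img
}

odd_size <- function(k) if (k %% 2 == 1) k else k + 1L

# Reject interior-interior crossings and collinear overlaps.
check_layout_crossings <- function(segs) {
  n <- nrow(segs)
  if (n < 2L) return(invisible())
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
    p <- segs[a, 1:2]; r <- segs[a, 3:4] - p
    q <- segs[b, 1:2]; s <- segs[b, 3:4] - q
    cr <- r[1] * s[2] - r[2] * s[1]
    qp <- q - p
    if (abs(cr) < 1e-9) {
      # parallel: reject collinear overlap
      if (abs(qp[1] * r[2] - qp[2] * r[1]) < 1e-9) {
        t0 <- sum(qp * r) / sum(r * r)
        t1 <- t0 + sum(s * r) / sum(r * r)
        if (max(min(t0, t1), 0) < min(max(t0, t1), 1) - 1e-9) {
          stop("overlapping collinear segments make the layout truth ambiguous",
               call. = FALSE)
        }
      }
      next
    }
    t <- (qp[1] * s[2] - qp[2] * s[1]) / cr
    u <- (qp[1] * r[2] - qp[2] * r[1]) / cr
    eps <- 1e-6
    if (t > eps && t < 1 - eps && u > eps && u < 1 - eps) {
      stop("segments cross interior-to-interior; truth would be ambiguous",
           call. = FALSE)
    }
  }
  invisible()
}

# Analytic skeleton statistics from the layout graph.
layout_truth <- function(segs) {
  # split segments at T-junction touch points (other endpoints on interior)
  pts <- rbind(segs[, 1:2, drop = FALSE], segs[, 3:4, drop = FALSE])
  edges <- list()
  for (r in seq_len(nrow(segs))) {
    p <- segs[r, 1:2]; q <- segs[r, 3:4]
    d <- q - p; len2 <- sum(d * d)
    tt <- c(0, 1)
    for (i in seq_len(nrow(pts))) {
      t0 <- sum((pts[i, ] - p) * d) / len2
      if (t0 > 1e-9 && t0 < 1 - 1e-9) {
        proj <- p + t0 * d
        if (sqrt(sum((pts[i, ] - proj)^2)) < 0.5) tt <- c(tt, t0)
      }
    }
    tt <- sort(unique(round(tt, 9)))
    for (k in seq_len(length(tt) - 1L)) {
      edges[[length(edges) + 1L]] <- rbind(p + tt[k] * d, p + tt[k + 1L] * d)
    }
  }
  key <- function(pt) paste(round(pt[1], 6), round(pt[2], 6))
  vkeys <- unique(unlist(lapply(edges, function(e) c(key(e[1, ]),
                                                     key(e[2, ])))))
  g <- igraph::make_empty_graph(n = length(vkeys), directed = FALSE)
  igraph::V(g)$name <- vkeys
  el <- do.call(rbind, lapply(edges, function(e) c(key(e[1, ]), key(e[2, ]))))
  wts <- vapply(edges, function(e) sqrt(sum((e[2, ] - e[1, ])^2)), numeric(1))
  g <- igraph::add_edges(g, t(el))
  igraph::E(g)$weight <- wts
  comp <- igraph::components(g)
  deg <- igraph::degree(g)
  n_ind <- 0L; n_net <- 0L; bpn <- integer(0)
  for (ci in seq_len(comp$no)) {
    vs <- which(comp$membership == ci)
    sub_edges <- which(apply(igraph::as_edgelist(g, names = FALSE), 1,
                             function(e) comp$membership[e[1]] == ci))
    if (any(deg[vs] >= 3)) {
      n_net <- n_net + 1L
      bpn <- c(bpn, length(sub_edges))
    } else {
      n_ind <- n_ind + 1L
    }
  }
  list(n_individuals = n_ind, n_networks = n_net,
       branches_per_network = bpn,
       n_branches = length(edges),
       total_branch_length = sum(wts),
       mean_branch_length = mean(wts))
}

#' Generate a paired MitoTracker/MitoSOX (or any two-channel ROS) image set
#'
#' Inside the mask the tracker channel has mean `tracker_level` and the
#' superoxide channel mean `sox_level` (plus optional noise); the truth
#' records the intensity ratio `sox_level / tracker_level`.
#'
#' @param mask logical matrix (nonempty) defining the mitochondrial /
#'   cell region.
#' @param tracker_level,sox_level in-mask mean intensities
#'   (`tracker_level` > 0).
#' @param noise_sigma additive Gaussian noise SD (both channels).
#' @param seed integer RNG seed.
#' @return list with matrices `tracker` and `sox` plus the `mask`;
#'   `synthetic_spec` attribute records `ratio = sox_level /
#'   tracker_level`.
#' @export
make_ros_pair <- function(mask, tracker_level, sox_level, noise_sigma = 0,
                          seed = 0) {
  if (!is.matrix(mask)) stop("`mask` must be a matrix", call. = FALSE)
  mask <- mask != 0
  if (!any(mask)) stop("`mask` is empty", call. = FALSE)
  assert_scalar_num(tracker_level, "tracker_level", positive = TRUE)
  assert_scalar_num(sox_level, "sox_level", nonneg = TRUE)
  with_seed(seed, {
    mk <- function(level) {
      img <- matrix(0, nrow(mask), ncol(mask))
      img[mask] <- level
      if (noise_sigma > 0) img <- img + stats::rnorm(length(img), 0,
                                                     noise_sigma)
      img
    }
    out <- list(tracker = mk(tracker_level), sox = mk(sox_level),
                mask = mask)
    params <- list(tracker_level = tracker_level, sox_level = sox_level,
                   noise_sigma = noise_sigma)
    truth <- list(ratio = sox_level / tracker_level,
                  tracker_level = tracker_level, sox_level = sox_level,
                  n_pixels = sum(mask))
    attr(out, "synthetic_spec") <-
      synthetic_spec(seed, "ros_pair", params, truth)
    out
  })
}
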