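# Mitochondrial network morphometry: segmentation, topological
# skeletonization, and skeleton statistics in the MiNA convention
# (individuals, networks, branches per network, branch lengths,
# footprint).

#' Segment mitochondria from a single-channel image
#'
#' Applies a 3x3 median filter followed by Otsu (default) or a fixed
#' threshold; connected components smaller than `min_size_px` pixels are
#' removed.
#'
#' @param image numeric matrix.
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold intensity threshold when `method = "fixed"` (applied
#'   to the filtered image).
#' @param min_size_px minimum component size kept (default 4).
#' @return logical mask matrix with attribute `no_signal = TRUE` when
#'   nothing survives thresholding.
#' @export
segment_mitochondria <- function(image, method = c("otsu", "fixed"),
                                 threshold = NULL, min_size_px = 4) {
  method <- match.arg(method)
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("`image` must be a numeric matrix", call. = FALSE)
  }
  rng <- range(image)
  if (diff(rng) == 0) {
    m <- matrix(FALSE, nrow(image), ncol(image))
    attr(m, "no_signal") <- TRUE
    return(m)
  }
  norm <- (image - rng[1]) / diff(rng)
  med <- as.matrix(EBImage::medianFilter(norm, size = 1)) # 3x3 window
  thr <- if (method == "otsu") {
    EBImage::otsu(EBImage::Image(med), range = c(0, 1))
  } else {
    if (is.null(threshold)) stop("fixed method needs `threshold`",
                                 call. = FALSE)
    (threshold - rng[1]) / diff(rng)
  }
  mask <- med > thr
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_size_px)
  mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  if (!any(mask)) attr(mask, "no_signal") <- TRUE
  mask
}

# 8-connected component labelling (BFS; images here are small).
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  idx <- which(mask)
  for (s in idx) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue)) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (p - 1L) %% nr + 1L
      cl <- (p - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- cl + dc
        if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc) {
          q <- (cc - 1L) * nr + rr
          if (mask[q] && lab[q] == 0L) {
            lab[q] <- cur
            queue <- c(queue, q)
          }
        }
      }
    }
  }
  lab
}

shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Topologically skeletonize a binary mask (Zhang-Suen thinning)
#'
#' Iteratively peels boundary pixels while preserving 8-connectivity,
#' reducing each component to a one-pixel-wide centerline.
#'
#' @param mask logical matrix.
#' @return logical matrix of skeleton pixels.
#' @export
skeletonize <- function(mask) {
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      # neighbors in the Zhang-Suen order P2..P9 = N, NE, E, SE, S, SW, W, NW
      # matrix rows grow downward: N = row - 1
      p2 <- shift_mat(m, 1, 0)   # value of the pixel above (shift down)
      p3 <- shift_mat(m, 1, -1)
      p4 <- shift_mat(m, 0, -1)
      p5 <- shift_mat(m, -1, -1)
      p6 <- shift_mat(m, -1, 0)
      p7 <- shift_mat(m, -1, 1)
      p8 <- shift_mat(m, 0, 1)
      p9 <- shift_mat(m, 1, 1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seqs <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
      a <- 0L
      for (i in 1:8) a <- a + (seqs[[i]] == 0L & seqs[[i + 1L]] == 1L)
      cond <- m == 1L & b >= 2L & b <= 6L & a == 1L
      cond <- if (step == 1) {
        cond & (p2 * p4 * p6 == 0L) & (p4 * p6 * p8 == 0L)
      } else {
        cond & (p2 * p4 * p8 == 0L) & (p2 * p6 * p8 == 0L)
      }
      if (any(cond)) {
        m[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m == 1L
}

# 8-neighbor count of each pixel of `skel` (integer matrix result).
neighbor_counts <- function(skel) {
  m <- matrix(as.integer(skel), nrow(skel), ncol(skel))
  acc <- matrix(0L, nrow(m), ncol(m))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    acc <- acc + shift_mat(m, dr, dc)
  }
  acc
}

# Classify skeleton pixels by 8-neighbor count.
classify_skeleton <- function(skel) {
  nb <- neighbor_counts(skel)
  cls <- matrix("", nrow(skel), ncol(skel))
  cls[skel & nb == 0] <- "isolated"
  cls[skel & nb == 1] <- "endpoint"
  cls[skel & nb == 2] <- "slab"
  cls[skel & nb >= 3] <- "junction"
  cls
}

#' Skeleton-based mitochondrial network statistics
#'
#' Skeletonizes the mask and classifies skeleton pixels by 8-neighbor
#' count: endpoints (1 neighbor), slab (2) and junction pixels (>= 3).
#' Junction pixels that are 8-adjacent are merged into a single junction
#' node before branch counting so that pixel-level junction clusters do
#' not inflate counts. Connected skeleton components without a junction
#' are *individuals* (punctate or rod mitochondria); components with at
#' least one junction are *networks*. Branches are maximal slab paths
#' between endpoint/junction nodes; lengths sum Euclidean steps (1 for
#' orthogonal, sqrt(2) for diagonal moves).
#'
#' @param mask logical matrix (binary segmentation), or the output of
#'   [segment_mitochondria()].
#' @param pixel_um optional pixel size; when given, lengths are in
#'   micrometers and the footprint in square micrometers, otherwise
#'   pixel units.
#' @return a `mito_stats` list: `n_individuals`, `n_networks`,
#'   `mean_branches_per_network`, `n_branches`, `mean_branch_length`,
#'   `total_branch_length`, `footprint`, `n_junctions`, `units`,
#'   `empty` flag.
#' @export
skeleton_stats <- function(mask, pixel_um = NULL) {
  if (!is.matrix(mask)) stop("`mask` must be a matrix", call. = FALSE)
  mask <- mask != 0
  scale <- if (is.null(pixel_um)) 1 else pixel_um
  units <- if (is.null(pixel_um)) "px" else "um"
  if (!any(mask)) {
    return(structure(list(n_individuals = 0L, n_networks = 0L,
                          mean_branches_per_network = NA_real_,
                          n_branches = 0L, mean_branch_length = NA_real_,
                          total_branch_length = 0,
                          footprint = 0, n_junctions = 0L,
                          units = units, empty = TRUE),
                     class = "mito_stats"))
  }
  skel <- skeletonize(mask)
  g <- skeleton_graph(skel)
  comp <- igraph::components(g$graph)
  n_ind <- 0L; n_net <- 0L
  branches <- list()
  bpn <- integer(0)
  for (ci in seq_len(comp$no)) {
    vids <- which(comp$membership == ci)
    has_junction <- any(g$v_kind[vids] == "junction")
    br <- trace_branches(g, vids)
    if (has_junction) {
      n_net <- n_net + 1L
      bpn <- c(bpn, length(br))
    } else {
      n_ind <- n_ind + 1L
    }
    branches <- c(branches, br)
  }
  lens <- unlist(branches) * scale
  if (is.null(lens)) lens <- numeric(0)
  structure(list(
    n_individuals = n_ind, n_networks = n_net,
    mean_branches_per_network = if (n_net) mean(bpn) else NA_real_,
    n_branches = length(lens),
    mean_branch_length = if (length(lens)) mean(lens) else NA_real_,
    total_branch_length = sum(lens),
    footprint = sum(mask) * scale^2,
    n_junctions = sum(g$v_kind == "junction"),
    units = units, empty = FALSE), class = "mito_stats")
}

#' @export
print.mito_stats <- function(x, ...) {
  if (isTRUE(x$empty)) {
    cat("Mitochondrial stats: empty mask (no signal)\n")
    return(invisible(x))
  }
  cat(sprintf(paste0("Mitochondrial stats: %d individuals, %d networks",
                     " (%s branches/network)\n"),
              x$n_individuals, x$n_networks,
              format(x$mean_branches_per_network, digits = 3)))
  cat(sprintf("  %d branches, mean length %s %s, total %s %s, footprint %s %s^2\n",
              x$n_branches, format(x$mean_branch_length, digits = 4),
              x$units, format(x$total_branch_length, digits = 4), x$units,
              format(x$footprint, digits = 4), x$units))
  invisible(x)
}

# Build a node-level graph of the skeleton: junction pixel clusters are
# contracted to single nodes; endpoints, isolated pixels and slab pixels
# are their own vertices. Edges connect 8-adjacent pixels (weight 1 or
# sqrt 2); edges internal to a junction cluster are dropped.
skeleton_graph <- function(skel) {
  nr <- nrow(skel)
  cls <- classify_skeleton(skel)
  pix <- which(skel)
  if (!length(pix)) stop("empty skeleton")
  kind <- cls[pix]
  # merge 8-adjacent junction pixels into clusters
  jmask <- matrix(FALSE, nr, ncol(skel))
  jmask[pix[kind == "junction"]] <- TRUE
  jlab <- label_components(jmask)
  node_of <- integer(length(pix))          # vertex id per pixel
  names(node_of) <- pix
  v_kind <- character(0)
  v_pix <- list()                           # pixels per vertex
  nj <- max(jlab)
  if (nj > 0) {
    for (j in seq_len(nj)) {
      v_kind <- c(v_kind, "junction")
      v_pix[[j]] <- which(jlab == j)
    }
  }
  nxt <- nj
  for (i in seq_along(pix)) {
    p <- pix[i]
    if (jmask[p]) {
      node_of[i] <- jlab[p]
    } else {
      nxt <- nxt + 1L
      node_of[i] <- nxt
      v_kind <- c(v_kind, kind[i])
      v_pix[[nxt]] <- p
    }
  }
  # pixel adjacency -> vertex edges
  idx_of <- integer(nr * ncol(skel))
  idx_of[pix] <- seq_along(pix)
  from <- integer(0); to <- integer(0); w <- numeric(0)
  nc <- ncol(skel)
  for (i in seq_along(pix)) {
    p <- pix[i]
    r <- (p - 1L) %% nr + 1L
    cl <- (p - 1L) %/% nr + 1L
    for (dd in list(c(0, 1), c(1, 1), c(1, 0), c(1, -1))) { # forward half
      rr <- r + dd[1]; cc <- cl + dd[2]
      if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
      q <- (cc - 1L) * nr + rr
      if (!skel[q]) next
      vi <- node_of[i]; vj <- node_of[idx_of[q]]
      if (vi == vj) next                   # internal to a junction cluster
      from <- c(from, vi); to <- c(to, vj)
      w <- c(w, sqrt(sum(dd^2)))
    }
  }
  g <- igraph::make_empty_graph(n = length(v_kind), directed = FALSE)
  if (length(from)) {
    g <- igraph::add_edges(g, rbind(from, to))
    igraph::E(g)$weight <- w
  }
  list(graph = g, v_kind = v_kind, v_pix = v_pix,
       pixels_id = seq_along(pix), node_of = node_of,
       is_junction = jmask[pix])
}

# Branch lengths within one component (vertex ids `vids`): maximal paths
# between node vertices (junction clusters / endpoints / isolated), plus
# pure cycles. Degree-2 slab vertices are interior path points.
trace_branches <- function(g, vids) {
  gr <- g$graph
  sub <- igraph::induced_subgraph(gr, vids)
  deg <- igraph::degree(sub)
  vkind <- g$v_kind[vids]
  is_node <- vkind %in% c("junction", "endpoint", "isolated") | deg != 2
  el <- igraph::as_edgelist(sub, names = FALSE)
  ew <- igraph::E(sub)$weight
  ne <- nrow(el)
  if (ne == 0L) return(if (length(vids) == 1L) list(0) else list())
  used <- rep(FALSE, ne)
  # adjacency with edge ids
  adj <- lapply(seq_along(vids), function(i) integer(0))
  for (e in seq_len(ne)) {
    adj[[el[e, 1]]] <- c(adj[[el[e, 1]]], e)
    adj[[el[e, 2]]] <- c(adj[[el[e, 2]]], e)
  }
  other <- function(e, v) if (el[e, 1] == v) el[e, 2] else el[e, 1]
  branches <- list()
  for (v in which(is_node)) {
    for (e0 in adj[[v]]) {
      if (used[e0]) next
      len <- ew[e0]; used[e0] <- TRUE
      cur <- other(e0, v)
      prev_e <- e0
      while (!is_node[cur]) {
        nxt <- setdiff(adj[[cur]], prev_e)
        nxt <- nxt[!used[nxt]]
        if (!length(nxt)) break
        e1 <- nxt[1]
        len <- len + ew[e1]
        used[e1] <- TRUE
        cur <- other(e1, cur)
        prev_e <- e1
      }
      branches[[length(branches) + 1L]] <- len
    }
  }
  # pure cycles (no node vertices at all): one branch per cycle
  if (!any(is_node) && any(!used)) {
    branches[[length(branches) + 1L]] <- sum(ew[!used])
  }
  branches
}
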