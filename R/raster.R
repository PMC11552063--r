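# Low-level raster helpers shared by the segmentation, landmark and metric
# code. Everything operates on plain [row, col] matrices; EBImage is used
# where it already provides the primitive (distance transform, resize, blur).

# result[r, c] = m[r + dr, c + dc], zero-padded outside the canvas
.shift <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  r1 <- max(1L, 1L - dr); r2 <- min(nr, nr - dr)
  c1 <- max(1L, 1L - dc); c2 <- min(nc, nc - dc)
  if (r1 > r2 || c1 > c2) return(out)
  out[r1:r2, c1:c2] <- m[(r1 + dr):(r2 + dr), (c1 + dc):(c2 + dc)]
  out
}

.as_binary <- function(m) {
  stopifnot(is.matrix(m))
  (m > 0) * 1L
}

# 8-neighbour offsets in Zhang-Suen order P2..P9 (N, NE, E, SE, S, SW, W, NW)
.N8 <- list(c(-1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L),
            c(1L, 0L), c(1L, -1L), c(0L, -1L), c(-1L, -1L))

.neighbor_stack <- function(b) lapply(.N8, function(o) .shift(b, o[1], o[2]))

# number of foreground 8-neighbours of every pixel
count_neighbors8 <- function(mask) {
  b <- .as_binary(mask)
  Reduce(`+`, .neighbor_stack(b))
}

# crossing number: distinct 8-neighbourhood branches at each pixel (number
# of 0->1 transitions around the circular neighbour sequence). Robust
# junction/endpoint criterion for skeletons: staircase corners have 2
# branches and are not junctions, unlike the raw neighbour count.
count_branches8 <- function(mask) {
  b <- .as_binary(mask)
  nb <- .neighbor_stack(b)
  A <- matrix(0L, nrow(b), ncol(b))
  for (k in 1:8) {
    nxt <- if (k == 8) 1 else k + 1
    A <- A + (nb[[k]] == 0L & nb[[nxt]] == 1L)
  }
  A
}

#' Label 8-connected components
#'
#' Connected-component labelling under 8-connectivity (diagonal neighbours
#' belong to the same component), the convention used throughout the package
#' because thinned vessels are 8-connected curves.
#'
#' @param mask binary matrix (non-zero = foreground).
#' @return integer matrix of the same shape; 0 = background, components
#'   numbered from 1 in first-pixel (column-major) order.
#' @export
label_components8 <- function(mask) {
  b <- .as_binary(mask)
  nr <- nrow(b); nc <- ncol(b)
  lab <- matrix(0L, nr, nc)
  idx <- which(b > 0L)
  if (length(idx) == 0L) return(lab)
  node <- integer(nr * nc)
  node[idx] <- seq_along(idx)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  from <- integer(0); to <- integer(0)
  for (off in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- rows + off[1]; c2 <- cols + off[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    j <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- b[j] > 0L
    from <- c(from, node[idx[ok]][hit])
    to <- c(to, node[j][hit])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(from)) g <- igraph::add_edges(g, rbind(from, to))
  memb <- igraph::components(g)$membership
  # renumber components by first occurrence so labelling is deterministic
  first <- match(unique(memb), memb)
  order_id <- integer(max(memb))
  order_id[memb[sort(first)]] <- seq_along(first)
  lab[idx] <- order_id[memb]
  lab
}

#' Skeletonize a binary mask (Zhang-Suen thinning)
#'
#' Iterative morphological thinning to a 1-pixel-wide, 8-connected,
#' topology-preserving skeleton. Used both as the medial axis for caliber
#' estimation and as the curve set for vessel segment decomposition.
#' Implemented sparsely: each pass only indexes the surviving foreground
#' pixels, so large mostly-empty masks thin quickly.
#'
#' @param mask binary matrix.
#' @return binary integer matrix of the same shape.
#' @export
skeletonize <- function(mask) {
  m0 <- .as_binary(mask)
  if (!any(m0 > 0L)) return(m0)
  nr <- nrow(m0) + 2L; nc <- ncol(m0) + 2L
  b <- matrix(0L, nr, nc)
  b[2:(nr - 1L), 2:(nc - 1L)] <- m0
  # linear-index offsets of P2..P9 (N, NE, E, SE, S, SW, W, NW)
  off <- c(-1L, nr - 1L, nr, nr + 1L, 1L, 1L - nr, -nr, -nr - 1L)
  fg <- which(b == 1L)
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      n <- length(fg)
      if (n == 0L) break
      nb <- matrix(0L, n, 8L)
      for (k in 1:8) nb[, k] <- b[fg + off[k]]
      B <- rowSums(nb)
      A <- integer(n)
      for (k in 1:8) {
        nxt <- if (k == 8L) 1L else k + 1L
        A <- A + (nb[, k] == 0L & nb[, nxt] == 1L)
      }
      cond <- if (pass == 1L) {
        nb[, 1] * nb[, 3] * nb[, 5] == 0L & nb[, 3] * nb[, 5] * nb[, 7] == 0L
      } else {
        nb[, 1] * nb[, 3] * nb[, 7] == 0L & nb[, 1] * nb[, 5] * nb[, 7] == 0L
      }
      del <- B >= 2L & B <= 6L & A == 1L & cond
      if (any(del)) {
        b[fg[del]] <- 0L
        fg <- fg[!del]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- b[2:(nr - 1L), 2:(nc - 1L), drop = FALSE]
  storage.mode(out) <- "integer"
  out
}

# Euclidean distance transform: distance from each foreground pixel to the
# nearest background pixel center (EBImage::distmap).
.dist_transform <- function(mask) {
  b <- .as_binary(mask)
  if (!any(b > 0L)) return(matrix(0, nrow(b), ncol(b)))
  d <- EBImage::distmap(b, metric = "euclidean")
  matrix(as.numeric(d), nrow(b), ncol(b))
}

# Per-pixel caliber estimate at skeleton points: the distance transform
# measures center-to-center distance so the vessel width is 2*EDT - 1; when
# the true medial axis falls between two pixel rows/cols (even rasterized
# widths) the EDT plateaus one half-pixel low, detected via a non-skeleton
# 4-neighbour attaining the same EDT value, and corrected by +1.
.width_map <- function(mask, skeleton) {
  dt <- .dist_transform(mask)
  w <- 2 * dt - 1
  b <- .as_binary(mask)
  s <- .as_binary(skeleton)
  plateau <- matrix(FALSE, nrow(b), ncol(b))
  for (off in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    nd <- .shift(dt, off[1], off[2], fill = -1)
    nbmask <- .shift(b, off[1], off[2])
    nbskel <- .shift(s, off[1], off[2])
    plateau <- plateau | (nbmask == 1L & nbskel == 0L & abs(nd - dt) < 1e-9)
  }
  w + (plateau & s == 1L)
}

# Order the pixels of a simple 8-connected path. `pts` is a 2-column matrix
# of (row, col). Returns the same rows reordered end to end.
.trace_path <- function(pts) {
  n <- nrow(pts)
  if (n <= 2) return(pts)
  key <- paste(pts[, 1], pts[, 2])
  lookup <- new.env(hash = TRUE, size = n)
  for (i in seq_len(n)) assign(key[i], i, envir = lookup)
  adj <- vector("list", n)
  deg <- integer(n)
  for (i in seq_len(n)) {
    for (o in .N8) {
      k2 <- paste(pts[i, 1] + o[1], pts[i, 2] + o[2])
      j <- mget(k2, envir = lookup, ifnotfound = list(NULL))[[1]]
      if (!is.null(j)) {
        adj[[i]] <- c(adj[[i]], j)
        deg[i] <- deg[i] + 1L
      }
    }
  }
  start <- which(deg == 1L)
  start <- if (length(start)) min(start) else 1L
  ord <- integer(n)
  visited <- logical(n)
  cur <- start
  for (step in seq_len(n)) {
    ord[step] <- cur
    visited[cur] <- TRUE
    nxt <- adj[[cur]][!visited[adj[[cur]]]]
    if (!length(nxt)) {
      if (step < n) { # disconnected remainder (rare, e.g. touching spur)
        ord <- ord[seq_len(step)]
        break
      }
      break
    }
    cur <- nxt[1]
  }
  pts[ord, , drop = FALSE]
}

# arc length of an ordered 8-connected path (1 per axial step, sqrt(2)
# per diagonal step)
.path_arc_length <- function(pts) {
  if (nrow(pts) < 2) return(0)
  dr <- abs(diff(pts[, 1])); dc <- abs(diff(pts[, 2]))
  sum(ifelse(dr + dc == 2, sqrt(2), 1))
}

.path_chord_length <- function(pts) {
  n <- nrow(pts)
  if (n < 2) return(0)
  sqrt(sum((pts[n, ] - pts[1, ])^2))
}

# matrix <-> EBImage::Image with the package's [row, col] convention
.as_eb <- function(m) EBImage::Image(t(m))
.from_eb <- function(im) {
  a <- as.array(im)
  if (length(dim(a)) == 3) a <- a[, , 1]
  t(a)
}

# draw a disc-brush stroke: all pixels whose center is within width/2 of the
# densely sampled polyline `xy` (2-col matrix of continuous (row, col),
# 0-based). `butt = TRUE` limits to the perpendicular band (no end caps),
# used for calibration fixtures with exactly known rasterized caliber.
# Work is windowed per polyline segment so long curves stay cheap.
.stroke_mask <- function(xy, width, nrow_px, ncol_px, butt = FALSE) {
  if (width < 1) stop("vessel width must be >= 1 px")
  mask <- matrix(FALSE, nrow_px, ncol_px)
  half <- width / 2
  pad <- half + 1.5
  xy <- .sparsify_polyline(xy)
  n <- nrow(xy)
  for (i in seq_len(max(1L, n - 1L))) {
    p <- xy[i, ]
    q <- xy[min(i + 1L, n), ]
    r_lo <- max(1L, floor(min(p[1], q[1]) - pad) + 1L)
    r_hi <- min(nrow_px, ceiling(max(p[1], q[1]) + pad) + 1L)
    c_lo <- max(1L, floor(min(p[2], q[2]) - pad) + 1L)
    c_hi <- min(ncol_px, ceiling(max(p[2], q[2]) + pad) + 1L)
    if (r_lo > r_hi || c_lo > c_hi) next
    gr <- matrix((r_lo:r_hi) - 1, r_hi - r_lo + 1L, c_hi - c_lo + 1L)
    gc <- matrix((c_lo:c_hi) - 1, r_hi - r_lo + 1L, c_hi - c_lo + 1L,
                 byrow = TRUE)
    v <- q - p
    len2 <- sum(v^2)
    wr <- gr - p[1]; wc <- gc - p[2]
    if (len2 < 1e-12) {
      d2 <- wr^2 + wc^2
      inside <- d2 <= half^2 + 1e-9
    } else {
      tt <- (wr * v[1] + wc * v[2]) / len2
      tcl <- pmin(pmax(tt, 0), 1)
      d2 <- (wr - tcl * v[1])^2 + (wc - tcl * v[2])^2
      inside <- d2 <= half^2 + 1e-9
      if (butt) inside <- inside & tt >= 0 & tt <= 1
    }
    mask[r_lo:r_hi, c_lo:c_hi] <- mask[r_lo:r_hi, c_lo:c_hi] | inside
  }
  mask * 1L
}

# reduce a densely sampled polyline to ~2 px vertex spacing (the curves are
# smooth at that scale, so the chordal error is far below a pixel)
.sparsify_polyline <- function(xy, spacing = 2) {
  n <- nrow(xy)
  if (n <= 3) return(xy)
  arc <- c(0, cumsum(sqrt(rowSums(diff(xy)^2))))
  if (arc[n] <= spacing) return(xy[c(1L, n), , drop = FALSE])
  keep <- !duplicated(floor(arc / spacing))
  keep[n] <- TRUE
  xy[keep, , drop = FALSE]
}

# squared-distance field helpers used by zones and the scene generator:
# matrix of Euclidean distance of each pixel center (0-based) from (y0, x0)
.radius_field <- function(nrow_px, ncol_px, y0, x0) {
  ry <- ((seq_len(nrow_px) - 1) - y0)^2
  cx <- ((seq_len(ncol_px) - 1) - x0)^2
  sqrt(outer(ry, cx, `+`))
}

.ellipse_mask <- function(nrow_px, ncol_px, y0, x0, semi_y, semi_x) {
  ry <- ((seq_len(nrow_px) - 1) - y0)^2 / semi_y^2
  cx <- ((seq_len(ncol_px) - 1) - x0)^2 / semi_x^2
  (outer(ry, cx, `+`) <= 1) * 1L
}
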