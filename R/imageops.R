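# Low-level raster utilities shared by the simulator, the nuclei module and
# the filopodia detector.  All functions operate on plain numeric/logical
# matrices indexed [y, x] (see package doc for conventions).

# Shift a matrix by (dy, dx), filling vacated cells with `fill`.
shift_mat <- function(m, dy, dx, fill = 0) {
  ny <- nrow(m); nx <- ncol(m)
  out <- matrix(fill, ny, nx)
  ys <- max(1, 1 + dy):min(ny, ny + dy)
  xs <- max(1, 1 + dx):min(nx, nx + dx)
  if (length(ys) == 0L || length(xs) == 0L) return(out)
  out[ys, xs] <- m[ys - dy, xs - dx, drop = FALSE]
  out
}

gauss_kernel1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

# Separable Gaussian blur with renormalised (replicate-free) edges.
# Implemented by shift-and-add so that large slices stay cheap.
gauss_blur2d <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- gauss_kernel1d(sigma)
  r <- (length(k) - 1L) / 2L
  ny <- nrow(img); nx <- ncol(img)
  # 1D edge normalisation vectors (kernel mass actually inside the image)
  norm1 <- function(n) {
    v <- numeric(n)
    for (o in -r:r) {
      idx <- max(1, 1 + o):min(n, n + o)
      v[idx] <- v[idx] + k[o + r + 1L]
    }
    v
  }
  tmp <- matrix(0, ny, nx)
  for (o in -r:r) tmp <- tmp + k[o + r + 1L] * shift_mat(img, 0L, o)
  tmp <- sweep(tmp, 2L, norm1(nx), "/")
  out <- matrix(0, ny, nx)
  for (o in -r:r) out <- out + k[o + r + 1L] * shift_mat(tmp, o, 0L)
  sweep(out, 1L, norm1(ny), "/")
}

# Multiscale Hessian ridge ("tubeness") enhancement for bright curvilinear
# structures: at each scale, minus the most negative eigenvalue of the
# scale-normalised Hessian, clipped at zero; maximum over scales.
tubeness_map <- function(img, sigmas = c(1, 2, 3)) {
  best <- matrix(0, nrow(img), ncol(img))
  for (s in sigmas) {
    g <- gauss_blur2d(img, s)
    dxx <- shift_mat(g, 0L, 1L) + shift_mat(g, 0L, -1L) - 2 * g
    dyy <- shift_mat(g, 1L, 0L) + shift_mat(g, -1L, 0L) - 2 * g
    dxy <- (shift_mat(g, 1L, 1L) + shift_mat(g, -1L, -1L) -
            shift_mat(g, 1L, -1L) - shift_mat(g, -1L, 1L)) / 4
    tr <- dxx + dyy
    dt <- sqrt(pmax((dxx - dyy)^2 + 4 * dxy^2, 0))
    lam2 <- (tr - dt) / 2          # most negative eigenvalue
    best <- pmax(best, s^2 * pmax(-lam2, 0))
  }
  # finite differences are invalid against the zero-filled border
  best[c(1:2, nrow(best) - 1:0), ] <- 0
  best[, c(1:2, ncol(best) - 1:0)] <- 0
  best
}

# Robust z-score of a map against its global background (median / MAD).
robust_zscore <- function(m) {
  med <- median(m)
  s <- mad(m, center = med)
  if (s <= 0) s <- sd(m)
  if (!is.finite(s) || s <= 0) s <- 1
  (m - med) / s
}

# Otsu threshold on raw values (histogram-based, 256 bins).
otsu_threshold <- function(v, nbins = 256L) {
  if (anyNA(v)) v <- v[is.finite(v)]
  # the histogram of a large subsample gives the same threshold
  if (length(v) > 2e6) v <- v[seq(1L, length(v), by = length(v) %/% 2e6)]
  rng <- range(v)
  if (diff(rng) <= 0) return(rng[1])
  h <- tabulate(pmin(nbins, 1L + floor((v - rng[1]) / diff(rng) * nbins)),
                nbins)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(nbins) - 0.5) / nbins * diff(rng)
  w1 <- cumsum(p)
  mu1 <- cumsum(p * mids)
  mu_t <- mu1[nbins]
  sigma_b <- (mu_t * w1 - mu1)^2 / (w1 * (1 - w1))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

# ---- skeletons -------------------------------------------------------------

neighbour_stack <- function(m) {
  # 8 shifted copies in Zhang-Suen order P2..P9 (N, NE, E, SE, S, SW, W, NW),
  # with y increasing downward.
  list(p2 = shift_mat(m, 1L, 0L),  p3 = shift_mat(m, 1L, -1L),
       p4 = shift_mat(m, 0L, -1L), p5 = shift_mat(m, -1L, -1L),
       p6 = shift_mat(m, -1L, 0L), p7 = shift_mat(m, -1L, 1L),
       p8 = shift_mat(m, 0L, 1L),  p9 = shift_mat(m, 1L, 1L))
}

# Zhang-Suen thinning to a 1-px-wide 8-connected skeleton.
thin_mask <- function(mask) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      nb <- neighbour_stack(m)
      b <- nb$p2 + nb$p3 + nb$p4 + nb$p5 + nb$p6 + nb$p7 + nb$p8 + nb$p9
      seqs <- list(nb$p2, nb$p3, nb$p4, nb$p5, nb$p6, nb$p7, nb$p8, nb$p9,
                   nb$p2)
      a <- matrix(0, nrow(m), ncol(m))
      for (i in 1:8) a <- a + (seqs[[i]] == 0) * (seqs[[i + 1L]] == 1)
      if (sub == 1L) {
        c1 <- nb$p2 * nb$p4 * nb$p6
        c2 <- nb$p4 * nb$p6 * nb$p8
      } else {
        c1 <- nb$p2 * nb$p4 * nb$p8
        c2 <- nb$p2 * nb$p6 * nb$p8
      }
      del <- m == 1 & b >= 2 & b <= 6 & a == 1 & c1 == 0 & c2 == 0
      if (any(del)) {
        m[del] <- 0
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m == 1
}

skeleton_neighbour_count <- function(sk) {
  nb <- neighbour_stack(sk * 1)
  Reduce(`+`, nb)
}

# 8-connected components of a logical mask (via EBImage; diagonal links are
# restored by merging labels that touch diagonally).
label8 <- function(mask) {
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask)))
  n <- max(lab)
  if (n <= 1L) return(lab)
  parent <- seq_len(n)
  findp <- function(i) { i <- as.integer(i); while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (sh in list(c(1L, 1L), c(1L, -1L))) {
    a <- lab
    b <- shift_mat(lab, sh[1], sh[2])
    idx <- which(a > 0 & b > 0 & a != b)
    if (length(idx)) {
      prs <- unique(cbind(a[idx], b[idx]))
      for (r in seq_len(nrow(prs))) {
        ra <- findp(prs[r, 1]); rb <- findp(prs[r, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  roots <- vapply(seq_len(n), findp, 1L)
  newid <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- newid[lab[lab > 0]]
  out
}

# Adjacency list of an 8-connected pixel set ((y, x) matrix).
pixel_adjacency <- function(pix) {
  n <- nrow(pix)
  lookup <- seq_len(n)
  names(lookup) <- paste(pix[, 1], pix[, 2])
  offs <- expand.grid(dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dy == 0 & offs$dx == 0), ]
  lapply(seq_len(n), function(i) {
    nb <- lookup[paste(pix[i, 1] + offs$dy, pix[i, 2] + offs$dx)]
    as.integer(nb[!is.na(nb)])
  })
}

# Longest geodesic path through an 8-connected pixel set: BFS from an
# arbitrary pixel to the farthest one, then BFS again recording parents.
# Robust to thinning artefacts (corner nubs, 2x2 blocks); off-path pixels
# are dropped.  Returns the ordered (y, x) matrix.
order_path <- function(pix) {
  n <- nrow(pix)
  if (n <= 2L) return(pix)
  adj <- pixel_adjacency(pix)
  bfs <- function(start) {
    dist <- rep(NA_integer_, n)
    parent <- rep(NA_integer_, n)
    dist[start] <- 0L
    queue <- start
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      for (nb in adj[[cur]]) {
        if (is.na(dist[nb])) {
          dist[nb] <- dist[cur] + 1L
          parent[nb] <- cur
          queue <- c(queue, nb)
        }
      }
    }
    list(dist = dist, parent = parent)
  }
  b1 <- bfs(1L)
  u <- which.max(b1$dist)
  b2 <- bfs(u)
  v <- which.max(b2$dist)
  path <- v
  while (!is.na(b2$parent[path[1]])) path <- c(b2$parent[path[1]], path)
  pix[path, , drop = FALSE]
}

# Prune spurs shorter than `min_spur` pixels, then split remaining branched
# skeletons at junction pixels into simple paths.  Returns a list of ordered
# (y, x) path matrices (paths with >= 2 pixels).
skeleton_paths <- function(sk, min_spur = 3L) {
  sk <- sk & TRUE
  repeat {
    cnt <- skeleton_neighbour_count(sk)
    if (!any(sk & cnt >= 3)) break      # no junctions: nothing to prune
    ends <- which(sk & cnt == 1, arr.ind = TRUE)
    removed <- FALSE
    for (e in seq_len(nrow(ends))) {
      path <- walk_from(sk, ends[e, ], cnt, max_steps = min_spur)
      if (!is.null(path) && nrow(path) <= min_spur) {
        sk[path] <- FALSE
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  cnt <- skeleton_neighbour_count(sk)
  junc <- sk & cnt >= 4          # genuine crossings; corner nubs have 3
  core <- sk & !junc
  lab <- label8(core)
  n <- max(lab)
  out <- list()
  for (i in seq_len(n)) {
    pix <- which(lab == i, arr.ind = TRUE)
    if (nrow(pix) < 2L) next
    out[[length(out) + 1L]] <- unname(order_path(pix))
  }
  out
}

# Walk along a skeleton from an endpoint until a junction (neighbour count
# >= 3) or for max_steps pixels; returns the visited (y, x) pixels
# (junction excluded).
walk_from <- function(sk, start, cnt, max_steps = Inf) {
  offs <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  cur <- as.integer(start)
  visited <- matrix(cur, 1, 2)
  prev <- c(NA_integer_, NA_integer_)
  steps <- 0L
  repeat {
    steps <- steps + 1L
    if (steps > max_steps) return(visited)
    cand <- sweep(offs, 2L, cur, `+`)
    ok <- cand[, 1] >= 1 & cand[, 1] <= nrow(sk) &
          cand[, 2] >= 1 & cand[, 2] <= ncol(sk)
    cand <- cand[ok, , drop = FALSE]
    on <- sk[cand]
    cand <- cand[on, , drop = FALSE]
    if (nrow(cand) && !is.na(prev[1])) {
      keep <- !(cand[, 1] == prev[1] & cand[, 2] == prev[2])
      cand <- cand[keep, , drop = FALSE]
    }
    keep <- rep(TRUE, nrow(cand))
    for (r in seq_len(nrow(cand)))
      if (any(visited[, 1] == cand[r, 1] & visited[, 2] == cand[r, 2]))
        keep[r] <- FALSE
    cand <- cand[keep, , drop = FALSE]
    if (nrow(cand) == 0L) return(visited)
    if (cnt[cand[1, 1], cand[1, 2]] >= 3) return(visited)
    prev <- cur
    cur <- cand[1, ]
    visited <- rbind(visited, cur)
  }
}

# Sequential robust extraction of straight line segments from a weighted
# pixel cloud (deterministic: candidate directions come from an ordered
# subset of point pairs, refined by weighted PCA).  Filopodia are straight
# filaments, so each detection corresponds to one fitted segment; crossing
# or merged filaments are recovered as separate segments.
fit_line_segments <- function(pts, w, high = NULL, band = 1.5, gap_px = 4,
                              max_lines = 6L, min_pts = 4L,
                              consume_band = 4.5, min_high = 3L) {
  out <- list()
  if (is.null(high)) high <- rep(TRUE, nrow(pts))
  active <- seq_len(nrow(pts))
  for (iter in seq_len(max_lines)) {
    if (length(active) < min_pts) break
    P <- pts[active, , drop = FALSE]
    W <- w[active]
    ord <- order(-W)
    K <- min(12L, nrow(P))
    sub <- P[ord[unique(round(seq(1, length(ord), length.out = K)))],
             , drop = FALSE]
    best <- NULL
    for (i in seq_len(nrow(sub) - 1L)) {
      for (j in (i + 1L):nrow(sub)) {
        d <- sub[j, ] - sub[i, ]
        nd <- sqrt(sum(d^2))
        if (nd < 3) next
        d <- d / nd
        r <- abs((P[, 1] - sub[i, 1]) * d[2] - (P[, 2] - sub[i, 2]) * d[1])
        inl <- r <= band
        sc <- sum(W[inl])
        if (is.null(best) || sc > best$sc + 1e-12)
          best <- list(p0 = sub[i, ], d = d, inl = inl, sc = sc)
      }
    }
    if (is.null(best) || sum(best$inl) < min_pts) break
    # refine by weighted PCA on the inliers
    Pi <- P[best$inl, , drop = FALSE]
    Wi <- W[best$inl]
    ctr <- colSums(Pi * Wi) / sum(Wi)
    Pc <- sweep(Pi, 2L, ctr)
    cv <- crossprod(Pc * sqrt(Wi)) / sum(Wi)
    eg <- eigen(cv, symmetric = TRUE)
    d <- eg$vectors[, 1]
    r <- abs((P[, 1] - ctr[1]) * d[2] - (P[, 2] - ctr[2]) * d[1])
    inl <- which(r <= band)
    if (length(inl) < min_pts) { active <- active[-which(best$inl)]; next }
    t <- (P[inl, 1] - ctr[1]) * d[1] + (P[inl, 2] - ctr[2]) * d[2]
    ot <- order(t)
    ts <- t[ot]
    splits <- c(0L, which(diff(ts) > gap_px), length(ts))
    runs <- cbind(splits[-length(splits)] + 1L, splits[-1L])
    mass <- vapply(seq_len(nrow(runs)), function(k)
      sum(W[inl][ot][runs[k, 1]:runs[k, 2]]), 0)
    rr <- runs[which.max(mass), ]
    run_sel <- ot[rr[1]:rr[2]]
    tmin <- ts[rr[1]]; tmax <- ts[rr[2]]
    # consume the whole support band of the accepted segment, so flank
    # pixels cannot seed a duplicate parallel line
    rall <- abs((P[, 1] - ctr[1]) * d[2] - (P[, 2] - ctr[2]) * d[1])
    tall <- (P[, 1] - ctr[1]) * d[1] + (P[, 2] - ctr[2]) * d[2]
    consumed <- active[rall <= consume_band &
                       tall >= tmin - 1 & tall <= tmax + 1]
    n_high <- sum(high[active[inl[run_sel]]] &
                  abs(t[run_sel] - (tmin + tmax) / 2) <=
                    (tmax - tmin) / 2)
    active <- setdiff(active, c(consumed, active[inl[run_sel]]))
    if (tmax - tmin < 2) next
    # a genuine filament carries its own high-score core; flank or noise
    # lines do not
    if (n_high < min_high) next
    out[[length(out) + 1L]] <- list(ctr = ctr, dir = d,
                                    t0 = tmin, t1 = tmax,
                                    n = length(run_sel))
  }
  out
}

# Bilinear interpolation of a matrix at fractional (y, x) positions.
bilinear_at <- function(m, y, x) {
  y <- pmin(pmax(y, 1), nrow(m)); x <- pmin(pmax(x, 1), ncol(m))
  y0 <- pmin(floor(y), nrow(m) - 1L); x0 <- pmin(floor(x), ncol(m) - 1L)
  fy <- y - y0; fx <- x - x0
  m[cbind(y0, x0)] * (1 - fy) * (1 - fx) +
    m[cbind(y0 + 1, x0)] * fy * (1 - fx) +
    m[cbind(y0, x0 + 1)] * (1 - fy) * fx +
    m[cbind(y0 + 1, x0 + 1)] * fy * fx
}

# ---- geometry helpers ------------------------------------------------------

# Chain-code length of an ordered closed contour with Kulpa weights
# (0.948 straight, 1.340 diagonal): near-unbiased digital perimeter.
kulpa_perimeter <- function(contour) {
  if (nrow(contour) < 2L) return(0)
  nxt <- rbind(contour[-1, , drop = FALSE], contour[1, , drop = FALSE])
  d <- abs(nxt - contour)
  straight <- sum(d[, 1] + d[, 2] == 1)
  diag <- sum(d[, 1] == 1 & d[, 2] == 1)
  0.948 * straight + 1.340 * diag
}

# Even-odd rasterisation of a polygon (x, y in micrometres) onto the pixel
# grid; returns a logical matrix.  Pixel centres at (i - 0.5) * pixel_size.
rasterize_polygon <- function(poly, ny, nx, pixel_size) {
  px <- (seq_len(nx) - 0.5) * pixel_size
  py <- (seq_len(ny) - 0.5) * pixel_size
  out <- matrix(FALSE, ny, nx)
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  xi <- which(px >= xr[1] - pixel_size & px <= xr[2] + pixel_size)
  yi <- which(py >= yr[1] - pixel_size & py <= yr[2] + pixel_size)
  if (!length(xi) || !length(yi)) return(out)
  gx <- rep(px[xi], each = length(yi))
  gy <- rep(py[yi], times = length(xi))
  inside <- rep(FALSE, length(gx))
  n <- nrow(poly)
  j <- n
  for (i in seq_len(n)) {
    xi1 <- poly[i, 1]; yi1 <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi1 > gy) != (yj > gy)) &
      (gx < (xj - xi1) * (gy - yi1) / (yj - yi1) + xi1)
    inside <- xor(inside, crosses)
    j <- i
  }
  out[yi, xi] <- matrix(inside, length(yi), length(xi))
  out
}

# Add an anti-aliased Gaussian-profile ridge along segment p0 -> p1 (pixel
# coordinates, c(y, x)) to an image; amp at the centreline.
draw_segment <- function(img, p0, p1, width_px, amp) {
  r <- ceiling(3 * width_px) + 1L
  ylim <- pmax(1L, floor(min(p0[1], p1[1])) - r):
          pmin(nrow(img), ceiling(max(p0[1], p1[1])) + r)
  xlim <- pmax(1L, floor(min(p0[2], p1[2])) - r):
          pmin(ncol(img), ceiling(max(p0[2], p1[2])) + r)
  if (!length(ylim) || !length(xlim)) return(img)
  gy <- matrix(ylim, length(ylim), length(xlim))
  gx <- matrix(xlim, length(ylim), length(xlim), byrow = TRUE)
  v <- p1 - p0
  len2 <- sum(v^2)
  if (len2 == 0) {
    d2 <- (gy - p0[1])^2 + (gx - p0[2])^2
  } else {
    t <- ((gy - p0[1]) * v[1] + (gx - p0[2]) * v[2]) / len2
    t <- pmin(pmax(t, 0), 1)
    d2 <- (gy - (p0[1] + t * v[1]))^2 + (gx - (p0[2] + t * v[2]))^2
  }
  img[ylim, xlim] <- img[ylim, xlim] + amp * exp(-d2 / (2 * width_px^2))
  img
}

filled_ellipse <- function(ny, nx, cy, cx, ry, rx, theta = 0) {
  gy <- matrix(seq_len(ny), ny, nx)
  gx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  dy <- gy - cy; dx <- gx - cx
  u <- dx * cos(theta) + dy * sin(theta)
  w <- -dx * sin(theta) + dy * cos(theta)
  (u / rx)^2 + (w / ry)^2 <= 1
}

# ---- 3D helpers ------------------------------------------------------------

# Connected components of a 3D logical array: 8-connected within slice,
# face-connected across slices.  Returns an integer array of labels.
label3d <- function(mask) {
  dm <- dim(mask)
  nz <- dm[3]
  labs <- vector("list", nz)
  offs <- integer(nz)
  total <- 0L
  for (k in seq_len(nz)) {
    l <- label8(mask[, , k])
    offs[k] <- total
    total <- total + max(l)
    labs[[k]] <- l
  }
  if (total == 0L) return(array(0L, dm))
  parent <- seq_len(total)
  findp <- function(i) { i <- as.integer(i); while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nz - 1L)) {
    a <- labs[[k]]; b <- labs[[k + 1L]]
    idx <- which(a > 0 & b > 0)
    if (length(idx)) {
      enc <- unique((a[idx] + offs[k]) * (total + 1) +
                    (b[idx] + offs[k + 1L]))
      prs <- cbind(enc %/% (total + 1), enc %% (total + 1))
      for (r in seq_len(nrow(prs))) {
        ra <- findp(prs[r, 1]); rb <- findp(prs[r, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  roots <- vapply(seq_len(total), findp, 1L)
  newid <- match(roots, sort(unique(roots)))
  out <- array(0L, dm)
  for (k in seq_len(nz)) {
    l <- labs[[k]]
    sel <- l > 0
    lk <- out[, , k]
    lk[sel] <- newid[l[sel] + offs[k]]
    out[, , k] <- lk
  }
  out
}

# Exact L1 (city-block) distance to the complement of a 3D mask, by iterated
# one-dimensional sweeps along each axis.
l1_distmap3d <- function(mask) {
  dm <- dim(mask)
  big <- sum(dm)
  d <- array(ifelse(mask, big, 0), dm)
  for (ax in 1:3) {
    n <- dm[ax]
    for (i in 2:n) {
      if (ax == 1) d[i, , ] <- pmin(d[i, , ], d[i - 1L, , ] + 1)
      if (ax == 2) d[, i, ] <- pmin(d[, i, ], d[, i - 1L, ] + 1)
      if (ax == 3) d[, , i] <- pmin(d[, , i], d[, , i - 1L] + 1)
    }
    for (i in (n - 1L):1) {
      if (ax == 1) d[i, , ] <- pmin(d[i, , ], d[i + 1L, , ] + 1)
      if (ax == 2) d[, i, ] <- pmin(d[, i, ], d[, i + 1L, ] + 1)
      if (ax == 3) d[, , i] <- pmin(d[, , i], d[, , i + 1L] + 1)
    }
  }
  d
}
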