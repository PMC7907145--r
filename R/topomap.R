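# Topographic imaging: scattered per-channel values -> 32 x 32 grids via
# Delaunay triangulation + Clough-Tocher piecewise-cubic interpolation, and
# assembly of per-band grids into 3-channel images.
#
# The interpolation scheme is the classic (reduced) Hsieh-Clough-Tocher
# macro-element: each Delaunay triangle is split at its centroid into three
# cubic Bezier patches; vertex values and estimated gradients fix the outer
# control net, the condition that the cross-edge normal derivative varies
# linearly along each outer edge fixes the interior edge points, and C1
# coupling across the internal edges fixes the centre.  Vertex gradients are
# least-squares plane fits over the Delaunay neighbours, so the whole map
# from electrode values to grid is linear and exact for affine fields.

# ---- Delaunay (Bowyer-Watson) ----------------------------------------------

circumcircle <- function(p1, p2, p3) {
  ax <- p1[1]; ay <- p1[2]; bx <- p2[1]; by <- p2[2]; cx <- p3[1]; cy <- p3[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-300) return(NULL)
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  c(ux, uy, (ux - ax)^2 + (uy - ay)^2)  # centre + squared radius
}

# Incremental Bowyer-Watson triangulation.  A deterministic sub-nanometre
# jitter (relative 1e-9) breaks exact co-circularity of symmetric montages;
# its effect on interpolated values is far below the 1e-6 tolerances used
# throughout.
delaunay <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 3) stop_input("need at least 3 points for a triangulation")
  scale <- max(apply(points, 2, function(v) diff(range(v))), 1e-12)
  jit <- function(i, d) {
    h <- (i * 2654435761 + d * 97003) %% 4294967296
    (h / 4294967296 - 0.5) * 2e-9 * scale
  }
  pts <- points
  for (i in seq_len(n)) {
    pts[i, 1] <- pts[i, 1] + jit(i, 1)
    pts[i, 2] <- pts[i, 2] + jit(i, 2)
  }
  cx <- mean(range(pts[, 1])); cy <- mean(range(pts[, 2]))
  big <- 20 * scale
  sup <- rbind(c(cx - 2 * big, cy - big), c(cx + 2 * big, cy - big), c(cx, cy + 2 * big))
  allp <- rbind(pts, sup)
  tris <- list(c(n + 1L, n + 2L, n + 3L))
  ccs <- list(circumcircle(sup[1, ], sup[2, ], sup[3, ]))
  eps <- 1e-11 * scale^2
  for (i in seq_len(n)) {
    p <- allp[i, ]
    bad <- logical(length(tris))
    for (t in seq_along(tris)) {
      cc <- ccs[[t]]
      bad[t] <- (p[1] - cc[1])^2 + (p[2] - cc[2])^2 < cc[3] - eps
    }
    if (!any(bad)) stop_input("triangulation failed: point in no circumcircle")
    edges <- do.call(rbind, lapply(which(bad), function(t) {
      v <- tris[[t]]
      rbind(sort(c(v[1], v[2])), sort(c(v[2], v[3])), sort(c(v[3], v[1])))
    }))
    key <- paste(edges[, 1], edges[, 2])
    boundary <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]
    tris <- tris[!bad]; ccs <- ccs[!bad]
    for (e in seq_len(nrow(boundary))) {
      v <- c(boundary[e, ], i)
      cc <- circumcircle(allp[v[1], ], allp[v[2], ], allp[v[3], ])
      if (is.null(cc)) next  # degenerate sliver with a duplicate point
      tris[[length(tris) + 1L]] <- v
      ccs[[length(ccs) + 1L]] <- cc
    }
  }
  keep <- vapply(tris, function(v) all(v <= n), logical(1))
  tri <- do.call(rbind, tris[keep])
  if (is.null(tri) || nrow(tri) == 0)
    stop_input("degenerate electrode cloud (all points collinear?)")
  # enforce counter-clockwise orientation
  for (t in seq_len(nrow(tri))) {
    v <- tri[t, ]
    a <- pts[v[1], ]; b <- pts[v[2], ]; cpt <- pts[v[3], ]
    if ((b[1] - a[1]) * (cpt[2] - a[2]) - (b[2] - a[2]) * (cpt[1] - a[1]) < 0)
      tri[t, ] <- v[c(1, 3, 2)]
  }
  list(points = pts, triangles = tri)
}

# ---- Clough-Tocher machinery ------------------------------------------------

# least-squares plane-fit gradient operators: gx, gy are n x n matrices with
# grad_x(f) = Gx %*% f etc.; exact for affine fields.
ct_gradient_ops <- function(dt) {
  n <- nrow(dt$points)
  nb <- vector("list", n)
  for (t in seq_len(nrow(dt$triangles))) {
    v <- dt$triangles[t, ]
    nb[[v[1]]] <- c(nb[[v[1]]], v[2], v[3])
    nb[[v[2]]] <- c(nb[[v[2]]], v[1], v[3])
    nb[[v[3]]] <- c(nb[[v[3]]], v[1], v[2])
  }
  gx <- matrix(0, n, n); gy <- matrix(0, n, n)
  for (v in seq_len(n)) {
    ks <- unique(nb[[v]])
    dp <- sweep(dt$points[ks, , drop = FALSE], 2, dt$points[v, ])
    A <- crossprod(dp)
    if (abs(det(A)) < 1e-14 * (sum(diag(A)) / 2)^2 + 1e-300)
      A <- A + diag(1e-12 * (sum(diag(A)) + 1e-300), 2)
    # gradient = A^{-1} t(dp) (f[ks] - f[v]): accumulate as linear operator
    M <- solve(A, t(dp))              # 2 x k
    gx[v, ks] <- gx[v, ks] + M[1, ]
    gx[v, v] <- gx[v, v] - sum(M[1, ])
    gy[v, ks] <- gy[v, ks] + M[2, ]
    gy[v, v] <- gy[v, v] - sum(M[2, ])
  }
  list(gx = gx, gy = gy)
}

# barycentric coordinates of points wrt triangle (a, b, c); rows of `p`
bary_coords <- function(p, a, b, c) {
  d <- (b[2] - c[2]) * (a[1] - c[1]) + (c[1] - b[1]) * (a[2] - c[2])
  l1 <- ((b[2] - c[2]) * (p[, 1] - c[1]) + (c[1] - b[1]) * (p[, 2] - c[2])) / d
  l2 <- ((c[2] - a[2]) * (p[, 1] - c[1]) + (a[1] - c[1]) * (p[, 2] - c[2])) / d
  cbind(l1, l2, 1 - l1 - l2)
}

# Precompute the evaluation structure for a fixed set of query points:
# for each query point its macro triangle, micro patch and barycentric
# coordinates (wrt the micro triangle).
ct_locate <- function(dt, q) {
  nq <- nrow(q)
  tri_id <- rep(NA_integer_, nq)
  bary_macro <- matrix(NA_real_, nq, 3)
  remaining <- seq_len(nq)
  for (t in seq_len(nrow(dt$triangles))) {
    if (!length(remaining)) break
    v <- dt$triangles[t, ]
    l <- bary_coords(q[remaining, , drop = FALSE],
                     dt$points[v[1], ], dt$points[v[2], ], dt$points[v[3], ])
    inside <- l[, 1] >= -1e-7 & l[, 2] >= -1e-7 & l[, 3] >= -1e-7
    hit <- remaining[inside]
    tri_id[hit] <- t
    bary_macro[hit, ] <- l[inside, , drop = FALSE]
    remaining <- remaining[!inside]
  }
  inside <- !is.na(tri_id)
  # micro patch: split at centroid; patch k contains points whose macro
  # barycentric coordinate k is the smallest (centroid has coords 1/3 each)
  patch <- max.col(-bary_macro[inside, , drop = FALSE], ties.method = "first")
  # barycentric wrt the micro triangle (outer_i, outer_j, centroid):
  # if macro coords are (l1, l2, l3) and patch opposite vertex k, then
  # w (centroid weight) = 3*lk, and u, v are li - lk, lj - lk for the two
  # outer vertices i, j of the patch.
  lm <- bary_macro[inside, , drop = FALSE]
  uvw <- matrix(NA_real_, nrow(lm), 3)
  outer_idx <- rbind(c(2, 3), c(3, 1), c(1, 2))  # patch k spans these verts
  for (k in 1:3) {
    rows <- patch == k
    if (!any(rows)) next
    i <- outer_idx[k, 1]; j <- outer_idx[k, 2]
    w <- 3 * lm[rows, k]
    uvw[rows, ] <- cbind(lm[rows, i] - lm[rows, k], lm[rows, j] - lm[rows, k], w)
  }
  list(inside = inside, tri_id = tri_id[inside], patch = patch, uvw = uvw)
}

# 10 Bernstein monomials of a cubic patch at (u, v, w), ordered
# b300 b030 b003 b210 b120 b201 b021 b111 b102 b012
ct_bernstein <- function(uvw) {
  u <- uvw[, 1]; v <- uvw[, 2]; w <- uvw[, 3]
  cbind(u^3, v^3, w^3, 3 * u^2 * v, 3 * u * v^2, 3 * u^2 * w, 3 * v^2 * w,
        6 * u * v * w, 3 * u * w^2, 3 * v * w^2)
}

# per-patch control points for data values f and gradients (gx, gy);
# returns a (3 * ntri) x 10 matrix, rows indexed by (tri - 1) * 3 + patch
ct_control_points <- function(dt, f, gx, gy) {
  ntri <- nrow(dt$triangles)
  cp <- matrix(0, 3 * ntri, 10)
  P <- dt$points
  for (t in seq_len(ntri)) {
    v <- dt$triangles[t, ]
    p0 <- (P[v[1], ] + P[v[2], ] + P[v[3], ]) / 3
    fv <- f[v]; g <- rbind(c(gx[v[1]], gy[v[1]]), c(gx[v[2]], gy[v[2]]),
                           c(gx[v[3]], gy[v[3]]))
    b111 <- numeric(3)
    ecp <- vector("list", 3)
    outer_idx <- rbind(c(2, 3), c(3, 1), c(1, 2))
    for (k in 1:3) {
      i <- outer_idx[k, 1]; j <- outer_idx[k, 2]
      A <- P[v[i], ]; B <- P[v[j], ]
      b300 <- fv[i]; b030 <- fv[j]
      b210 <- fv[i] + sum(g[i, ] * (B - A)) / 3
      b120 <- fv[j] + sum(g[j, ] * (A - B)) / 3
      b201 <- fv[i] + sum(g[i, ] * (p0 - A)) / 3
      b021 <- fv[j] + sum(g[j, ] * (p0 - B)) / 3
      # cross-edge direction: barycentric direction of the Cartesian normal
      ev <- B - A
      nv <- c(-ev[2], ev[1])
      M <- rbind(c(A[1], B[1], p0[1]), c(A[2], B[2], p0[2]), c(1, 1, 1))
      d <- solve(M, c(nv, 0))
      end0 <- d[1] * b300 + d[2] * b210 + d[3] * b201
      end1 <- d[1] * b120 + d[2] * b030 + d[3] * b021
      b111[k] <- ((end0 + end1) / 2 - d[1] * b210 - d[2] * b120) / d[3]
      ecp[[k]] <- c(b300 = b300, b030 = b030, b210 = b210, b120 = b120,
                    b201 = b201, b021 = b021)
    }
    # interior edge points: q_a at macro vertex a couples the two patches
    # having a as an outer vertex (patches: 1 spans (2,3), 2 spans (3,1),
    # 3 spans (1,2)); vertex 1 belongs to patches 2 and 3, etc.
    q <- numeric(3)
    vert_patches <- rbind(c(2, 3), c(3, 1), c(1, 2))  # patches touching vert a
    for (a in 1:3) {
      pa <- vert_patches[a, ]
      q[a] <- (b111[pa[1]] + b111[pa[2]] +
                 fv[a] + sum(g[a, ] * (p0 - P[v[a], ])) / 3) / 3
    }
    centre <- mean(q)
    for (k in 1:3) {
      i <- outer_idx[k, 1]; j <- outer_idx[k, 2]
      e <- ecp[[k]]
      cp[(t - 1) * 3 + k, ] <- c(e["b300"], e["b030"], centre, e["b210"],
                                 e["b120"], e["b201"], e["b021"], b111[k],
                                 q[i], q[j])
    }
  }
  cp
}

# ---- public interpolation API ----------------------------------------------

.topo_cache <- new.env(parent = emptyenv())

# build (and cache) the full evaluation structure for a set of electrode
# positions and a grid
topo_setup <- function(positions2d, grid_size = 32L, margin = 0.05) {
  key <- paste(grid_size, margin, paste(signif(as.numeric(positions2d), 10), collapse = ","))
  hit <- .topo_cache[[key]]
  if (!is.null(hit)) return(hit)
  positions2d <- as.matrix(positions2d)
  if (nrow(positions2d) < 4) stop_input("need at least 4 electrodes")
  dt <- delaunay(positions2d)
  grads <- ct_gradient_ops(dt)
  xr <- range(positions2d[, 1]); yr <- range(positions2d[, 2])
  xr <- xr + c(-1, 1) * margin * diff(xr)
  yr <- yr + c(-1, 1) * margin * diff(yr)
  gx <- seq(xr[1], xr[2], length.out = grid_size)
  gy <- seq(yr[1], yr[2], length.out = grid_size)
  q <- cbind(rep(gx, each = grid_size), rep(gy, grid_size))  # row-major (x, y)
  loc <- ct_locate(dt, q)
  bern <- ct_bernstein(loc$uvw)
  row_id <- (loc$tri_id - 1L) * 3L + loc$patch
  st <- list(dt = dt, grads = grads, grid_size = grid_size,
             grid_x = gx, grid_y = gy, inside = loc$inside,
             row_id = row_id, bern = bern)
  .topo_cache[[key]] <- st
  st
}

topo_eval <- function(st, values) {
  gxv <- drop(st$grads$gx %*% values)
  gyv <- drop(st$grads$gy %*% values)
  cp <- ct_control_points(st$dt, values, gxv, gyv)
  out <- numeric(st$grid_size^2)
  out[st$inside] <- rowSums(st$bern * cp[st$row_id, , drop = FALSE])
  # grid[i, j] with i = y index (row), j = x index (column)
  matrix(out, st$grid_size, st$grid_size)
}

#' Interpolate scattered electrode values onto a square grid
#'
#' Piecewise-cubic Clough-Tocher interpolation over the Delaunay
#' triangulation of the electrode positions, evaluated on a regular
#' `grid_size` x `grid_size` mesh spanning the electrode bounding box with a
#' 5% margin.  Pixels outside the convex hull are set to 0.  The scheme
#' passes through the data values and reproduces affine fields exactly.
#'
#' @param positions2d n x 2 matrix of projected electrode positions.
#' @param values one value per electrode.
#' @param grid_size mesh side length (default 32).
#' @return `grid_size` x `grid_size` numeric matrix (rows = y, columns = x).
#' @export
interpolate_grid <- function(positions2d, values, grid_size = 32L) {
  positions2d <- as.matrix(positions2d)
  if (length(values) != nrow(positions2d))
    stop_input("one value per electrode required")
  st <- topo_setup(positions2d, grid_size)
  topo_eval(st, as.numeric(values))
}

#' Linear operator from electrode values to grid pixels
#'
#' Because gradient estimation and Clough-Tocher evaluation are both linear
#' in the data, the full interpolation is `grid = W %*% values`; this builds
#' the `grid_size^2 x n` matrix `W` once so that bulk image generation is a
#' single matrix product.
#'
#' @inheritParams interpolate_grid
#' @return list with `W` (pixels x electrodes) and `inside` (logical mask).
#' @export
topo_operator <- function(positions2d, grid_size = 32L) {
  positions2d <- as.matrix(positions2d)
  key <- paste("op", grid_size, paste(signif(as.numeric(positions2d), 10), collapse = ","))
  hit <- .topo_cache[[key]]
  if (!is.null(hit)) return(hit)
  n <- nrow(positions2d)
  st <- topo_setup(positions2d, grid_size)
  W <- matrix(0, grid_size^2, n)
  for (i in seq_len(n)) {
    e <- numeric(n); e[i] <- 1
    W[, i] <- as.numeric(topo_eval(st, e))
  }
  op <- list(W = W, inside = matrix(st$inside, grid_size, grid_size),
             grid_size = grid_size)
  .topo_cache[[key]] <- op
  op
}

# ---- normalisation and image assembly --------------------------------------

#' Fit a per-band min-max normalizer
#'
#' Per-band affine map to `[0, 1]` fitted on (training) grids; a degenerate
#' band (min == max) maps to all-0 by convention.  Apply with
#' [assemble_rgb()]; values outside the fitted range clip to `[0, 1]`.
#'
#' @param band_values list (length = bands) of numeric data (grids or values)
#'   from the fitting split.
#' @return a `band_normalizer`.
#' @export
fit_normalizer <- function(band_values) {
  rng <- lapply(band_values, range)
  structure(list(min = vapply(rng, `[`, 0, 1), max = vapply(rng, `[`, 0, 2)),
            class = "band_normalizer")
}

#' @rdname fit_normalizer
#' @export
identity_normalizer <- function(n_bands = 3L) {
  structure(list(min = rep(0, n_bands), max = rep(1, n_bands)),
            class = "band_normalizer")
}

apply_normalizer <- function(normalizer, values, band) {
  lo <- normalizer$min[band]; hi <- normalizer$max[band]
  if (hi <= lo) return(values * 0)
  pmin(1, pmax(0, (values - lo) / (hi - lo)))
}

#' Stack three band grids into one RGB topographic image
#'
#' Channel order is theta -> R, alpha -> G, beta -> B; each band is
#' normalized to `[0, 1]` by the fitted per-band affine map, with clipping.
#'
#' @param band_grids list of three equal-shape grids (theta, alpha, beta).
#' @param normalizer a `band_normalizer` from [fit_normalizer()].
#' @param window_index stored frame index.
#' @return a `topo_image`: 32 x 32 x 3 array with `window_index` attribute.
#' @export
assemble_rgb <- function(band_grids, normalizer, window_index = 0L) {
  stopifnot(inherits(normalizer, "band_normalizer"), length(band_grids) == 3)
  d <- dim(band_grids[[1]])
  for (g in band_grids) if (!identical(dim(g), d)) stop_input("grid shape mismatch")
  px <- array(0, dim = c(d, 3))
  for (b in 1:3) px[, , b] <- apply_normalizer(normalizer, band_grids[[b]], b)
  structure(px, window_index = window_index, class = "topo_image")
}

#' Topographic image sequence for one trial
#'
#' One RGB image per feature frame, order preserved.
#'
#' @param frames list of `feature_frame`s (one trial, channel rows in
#'   montage order).
#' @param montage a projected `eeg_montage` (see [aep_project()]).
#' @param normalizer a `band_normalizer`.
#' @param grid_size mesh side (default 32).
#' @param label optional class label carried along.
#' @return an `image_sequence`: list of `topo_image`s plus label.
#' @export
make_sequence <- function(frames, montage, normalizer, grid_size = 32L,
                          label = NA_integer_) {
  stopifnot(inherits(montage, "eeg_montage"))
  if (is.null(montage$pos2d)) stop_input("montage not projected; call aep_project() first")
  op <- topo_operator(montage$pos2d, grid_size)
  imgs <- lapply(frames, function(fr) {
    if (nrow(fr$values) != length(montage$labels))
      stop_input("channel count of feature frame does not match montage")
    grids <- lapply(1:3, function(b)
      matrix(op$W %*% fr$values[, b], grid_size, grid_size))
    assemble_rgb(grids, normalizer, fr$window_index)
  })
  structure(list(frames = imgs, label = label), class = "image_sequence")
}
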