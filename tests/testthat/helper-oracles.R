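# Independent brute-force oracles the implementation is checked against.
# These deliberately share no code with the package internals.

# per-pixel confusion counting by explicit loop
oracle_confusion <- function(pred, truth) {
  p <- as.numeric(pred); t <- as.numeric(truth)
  tp <- fp <- fn <- tn <- 0
  for (i in seq_along(p)) {
    if (p[i] == 1 && t[i] == 1) tp <- tp + 1
    else if (p[i] == 1 && t[i] == 0) fp <- fp + 1
    else if (p[i] == 0 && t[i] == 1) fn <- fn + 1
    else tn <- tn + 1
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

oracle_seg_metrics <- function(pred, truth) {
  cc <- oracle_confusion(pred, truth)
  rat <- function(num, den) if (den == 0) 1 else num / den
  iou_fg <- rat(cc$tp, cc$tp + cc$fp + cc$fn)
  iou_bg <- rat(cc$tn, cc$tn + cc$fp + cc$fn)
  list(precision = rat(cc$tp, cc$tp + cc$fp),
       recall = rat(cc$tp, cc$tp + cc$fn),
       iou = iou_fg, miou = (iou_fg + iou_bg) / 2,
       mpa = (rat(cc$tp, cc$tp + cc$fn) + rat(cc$tn, cc$tn + cc$fp)) / 2,
       pixel_accuracy = rat(cc$tp + cc$tn, cc$tp + cc$fp + cc$fn + cc$tn))
}

# exhaustive search over all 255 candidate thresholds, recomputing the
# between-class variance from the raw pixel split each time
oracle_otsu <- function(image) {
  px <- as.integer(round(as.numeric(image)))
  n <- length(px)
  best <- -Inf; bt <- NA_integer_
  for (t in 0:254) {
    lo <- px[px <= t]; hi <- px[px > t]
    if (length(lo) == 0 || length(hi) == 0) next
    v <- (length(lo) / n) * (length(hi) / n) * (mean(lo) - mean(hi))^2
    if (v > best) { best <- v; bt <- t }
  }
  bt
}

# O(n^2) density-connectivity BFS with the same closed-ball core rule and
# ascending-index expansion order as the clustering contract
oracle_dbscan <- function(pts, eps, min_pts) {
  n <- nrow(pts)
  D <- as.matrix(stats::dist(pts)) <= eps
  nbrs <- lapply(seq_len(n), function(i) which(D[i, ]))
  labels <- integer(n); visited <- logical(n); ncl <- 0
  for (i in seq_len(n)) {
    if (visited[i]) next
    visited[i] <- TRUE
    if (length(nbrs[[i]]) < min_pts) next
    ncl <- ncl + 1
    labels[i] <- ncl
    queue <- nbrs[[i]]
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      if (labels[j] == 0) labels[j] <- ncl
      if (visited[j]) next
      visited[j] <- TRUE
      if (length(nbrs[[j]]) >= min_pts) queue <- c(queue, nbrs[[j]])
    }
  }
  labels
}

# direct Welch formulas
oracle_welch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

oracle_r2 <- function(x, y) {
  n <- length(x)
  cxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  cxy^2 / (var(x) * var(y))
}

# triangulated parametric ellipsoid surface area (vectorized over the
# latitude-longitude quad grid, two triangles per quad)
oracle_ellipsoid_mesh_area <- function(a, b, c, nu = 400, nv = 800) {
  th <- seq(0, pi, length.out = nu)
  ph <- seq(0, 2 * pi, length.out = nv)
  px <- a * outer(sin(th), cos(ph))
  py <- b * outer(sin(th), sin(ph))
  pz <- c * outer(cos(th), rep(1, nv))
  i <- seq_len(nu - 1); j <- seq_len(nv - 1)
  corner <- function(m, di, dj) m[i + di, j + dj]
  tri_area <- function(ax, ay, az, bx, by, bz) {
    cx <- ay * bz - az * by
    cy <- az * bx - ax * bz
    cz <- ax * by - ay * bx
    0.5 * sqrt(cx^2 + cy^2 + cz^2)
  }
  # quad corners: 1=(i,j) 2=(i+1,j) 3=(i+1,j+1) 4=(i,j+1)
  t1 <- tri_area(corner(px, 1, 0) - corner(px, 0, 0),
                 corner(py, 1, 0) - corner(py, 0, 0),
                 corner(pz, 1, 0) - corner(pz, 0, 0),
                 corner(px, 1, 1) - corner(px, 0, 0),
                 corner(py, 1, 1) - corner(py, 0, 0),
                 corner(pz, 1, 1) - corner(pz, 0, 0))
  t2 <- tri_area(corner(px, 1, 1) - corner(px, 0, 0),
                 corner(py, 1, 1) - corner(py, 0, 0),
                 corner(pz, 1, 1) - corner(pz, 0, 0),
                 corner(px, 0, 1) - corner(px, 0, 0),
                 corner(py, 0, 1) - corner(py, 0, 0),
                 corner(pz, 0, 1) - corner(pz, 0, 0))
  sum(t1) + sum(t2)
}
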