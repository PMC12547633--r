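# Minimal planar polygon geometry on lon/lat degrees.
# Rings are n x 2 matrices (lon, lat), not closed; vertices in any order.

# even-odd ray casting; points on an edge may fall either side, callers
# combine with vertex/edge tests so cell membership is robust
point_in_ring <- function(px, py, ring) {
  n <- nrow(ring)
  xs <- ring[, 1]; ys <- ring[, 2]
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- xs[i]; yi <- ys[i]; xj <- xs[j]; yj <- ys[j]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

seg_orient <- function(ax, ay, bx, by, cx, cy) {
  v <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  ifelse(abs(v) < 1e-12, 0, sign(v))
}

on_segment <- function(ax, ay, bx, by, px, py) {
  px >= pmin(ax, bx) - 1e-12 & px <= pmax(ax, bx) + 1e-12 &
    py >= pmin(ay, by) - 1e-12 & py <= pmax(ay, by) + 1e-12
}

segments_intersect <- function(a1, a2, b1, b2) {
  o1 <- seg_orient(a1[1], a1[2], a2[1], a2[2], b1[1], b1[2])
  o2 <- seg_orient(a1[1], a1[2], a2[1], a2[2], b2[1], b2[2])
  o3 <- seg_orient(b1[1], b1[2], b2[1], b2[2], a1[1], a1[2])
  o4 <- seg_orient(b1[1], b1[2], b2[1], b2[2], a2[1], a2[2])
  if (o1 != o2 && o3 != o4) return(TRUE)
  if (o1 == 0 && on_segment(a1[1], a1[2], a2[1], a2[2], b1[1], b1[2])) return(TRUE)
  if (o2 == 0 && on_segment(a1[1], a1[2], a2[1], a2[2], b2[1], b2[2])) return(TRUE)
  if (o3 == 0 && on_segment(b1[1], b1[2], b2[1], b2[2], a1[1], a1[2])) return(TRUE)
  if (o4 == 0 && on_segment(b1[1], b1[2], b2[1], b2[2], a2[1], a2[2])) return(TRUE)
  FALSE
}

ring_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

ring_self_intersects <- function(ring) {
  n <- nrow(ring)
  if (n < 4) return(FALSE)
  idx <- rbind(cbind(seq_len(n), c(2:n, 1)))
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next  # adjacent through closure
      if (segments_intersect(ring[idx[i, 1], ], ring[idx[i, 2], ],
                             ring[idx[j, 1], ], ring[idx[j, 2], ]))
        return(TRUE)
    }
  }
  FALSE
}

# does the ring intersect the axis-aligned cell [xmin,xmax] x [ymin,ymax]?
ring_intersects_cell <- function(ring, xmin, xmax, ymin, ymax) {
  # any vertex inside the cell
  if (any(ring[, 1] >= xmin & ring[, 1] <= xmax &
          ring[, 2] >= ymin & ring[, 2] <= ymax)) return(TRUE)
  # any cell corner inside the ring (cell fully inside polygon included)
  cx <- c(xmin, xmax, xmax, xmin); cy <- c(ymin, ymin, ymax, ymax)
  if (any(point_in_ring(cx, cy, ring))) return(TRUE)
  # any edge crossing
  n <- nrow(ring)
  cell <- cbind(cx, cy)
  for (i in seq_len(n)) {
    a1 <- ring[i, ]; a2 <- ring[if (i == n) 1 else i + 1, ]
    # quick reject: edge bbox disjoint from cell
    if (max(a1[1], a2[1]) < xmin || min(a1[1], a2[1]) > xmax ||
        max(a1[2], a2[2]) < ymin || min(a1[2], a2[2]) > ymax) next
    for (j in 1:4) {
      b1 <- cell[j, ]; b2 <- cell[if (j == 4) 1 else j + 1, ]
      if (segments_intersect(a1, a2, b1, b2)) return(TRUE)
    }
  }
  FALSE
}

rect_ring <- function(xmin, xmax, ymin, ymax) {
  cbind(lon = c(xmin, xmax, xmax, xmin), lat = c(ymin, ymin, ymax, ymax))
}
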