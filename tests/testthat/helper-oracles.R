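# Brute-force oracles: naive exhaustive-window implementations, written
# independently of the package internals, used to pin down every filter's
# exact semantics on small rasters.

clampIdx <- function(i, n) pmin(pmax(i, 1L), n)

diskOffsets <- function(radius) {
  ir <- floor(radius + 0.5)
  g <- expand.grid(dy = -ir:ir, dx = -ir:ir)
  g[g$dx^2 + g$dy^2 <= (radius + 0.5)^2, ]
}

oracle_rank <- function(m, radius, type = c("min", "max", "median")) {
  type <- match.arg(type)
  off <- diskOffsets(radius)
  H <- nrow(m); W <- ncol(m)
  out <- m
  for (i in 1:H) for (j in 1:W) {
    v <- m[cbind(clampIdx(i + off$dy, H), clampIdx(j + off$dx, W))]
    out[i, j] <- switch(type, min = min(v), max = max(v),
                        median = stats::median(v))
  }
  out
}

oracle_remove_outliers <- function(m, radius, threshold, bright) {
  med <- oracle_rank(m, radius, "median")
  dev <- if (bright) m - med else med - m
  ifelse(dev > threshold, med, m)
}

oracle_conv2 <- function(m, k) {
  H <- nrow(m); W <- ncol(m)
  rh <- (nrow(k) - 1) / 2; rw <- (ncol(k) - 1) / 2
  out <- m
  for (i in 1:H) for (j in 1:W) {
    s <- 0
    for (a in seq_len(nrow(k))) for (b in seq_len(ncol(k)))
      s <- s + k[a, b] * m[clampIdx(i + a - 1 - rh, H),
                           clampIdx(j + b - 1 - rw, W)]
    out[i, j] <- s
  }
  out
}

# grayscale opening with a ball-height structuring element, by exhaustive
# min/max over the element
oracle_ball_open <- function(m, radius) {
  ir <- ceiling(radius)
  g <- expand.grid(dy = -ir:ir, dx = -ir:ir)
  g <- g[g$dx^2 + g$dy^2 <= radius^2, ]
  g$h <- sqrt(radius^2 - g$dx^2 - g$dy^2)
  H <- nrow(m); W <- ncol(m)
  ero <- m; opn <- m
  for (i in 1:H) for (j in 1:W)
    ero[i, j] <- min(m[cbind(clampIdx(i + g$dy, H),
                             clampIdx(j + g$dx, W))] - g$h)
  for (i in 1:H) for (j in 1:W)
    opn[i, j] <- max(ero[cbind(clampIdx(i + g$dy, H),
                               clampIdx(j + g$dx, W))] + g$h)
  opn
}

oracle_morph3x3 <- function(m, type = c("max", "min")) {
  type <- match.arg(type)
  H <- nrow(m); W <- ncol(m)
  out <- m
  for (i in 1:H) for (j in 1:W) {
    v <- m[clampIdx((i - 1):(i + 1), H), clampIdx((j - 1):(j + 1), W)]
    out[i, j] <- if (type == "max") max(v) else min(v)
  }
  out
}

# connected-component count by union-find
oracle_label_count <- function(m, connectivity = 8) {
  H <- nrow(m); W <- ncol(m)
  parent <- seq_len(H * W)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  union <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  nb <- if (connectivity == 8)
    expand.grid(dy = -1:1, dx = -1:1)[-5, ]
  else data.frame(dy = c(-1, 1, 0, 0), dx = c(0, 0, -1, 1))
  for (i in 1:H) for (j in 1:W) {
    if (m[i, j] == 0) next
    for (t in seq_len(nrow(nb))) {
      ii <- i + nb$dy[t]; jj <- j + nb$dx[t]
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W && m[ii, jj] != 0)
        union((j - 1) * H + i, (jj - 1) * H + ii)
    }
  }
  roots <- vapply(which(m != 0), function(p) find(p), numeric(1))
  length(unique(roots))
}

# hole filling by flood fill of the background from the border (4-conn)
oracle_fill <- function(m) {
  H <- nrow(m); W <- ncol(m)
  reach <- matrix(FALSE, H, W)
  stack <- list()
  for (i in 1:H) for (j in 1:W)
    if ((i == 1 || i == H || j == 1 || j == W) && m[i, j] == 0)
      stack[[length(stack) + 1]] <- c(i, j)
  for (p in stack) reach[p[1], p[2]] <- TRUE
  while (length(stack)) {
    p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      ii <- p[1] + d[1]; jj <- p[2] + d[2]
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W &&
          m[ii, jj] == 0 && !reach[ii, jj]) {
        reach[ii, jj] <- TRUE
        stack[[length(stack) + 1]] <- c(ii, jj)
      }
    }
  }
  out <- m
  out[m == 0 & !reach] <- 1
  out
}

# exact Euclidean distance map by all-pairs search
oracle_edt <- function(m) {
  H <- nrow(m); W <- ncol(m)
  bg <- which(m == 0, arr.ind = TRUE)
  out <- matrix(0, H, W)
  if (nrow(bg) == 0) return(matrix(Inf, H, W))
  for (i in 1:H) for (j in 1:W)
    if (m[i, j] != 0)
      out[i, j] <- sqrt(min((bg[, 1] - i)^2 + (bg[, 2] - j)^2))
  out
}

oracle_isodata <- function(v) {
  v <- as.vector(v)
  t <- mean(v)
  repeat {
    lo <- v[v <= t]; hi <- v[v > t]
    if (!length(hi) || !length(lo)) return(t)
    t2 <- (mean(lo) + mean(hi)) / 2
    if (abs(t2 - t) < 1e-7) return(t2)
    t <- t2
  }
}

randRaster <- function(h = 16, w = 16, maxv = 255) {
  Raster(matrix(round(stats::runif(h * w, 0, maxv)), h, w),
         maxValue = maxv)
}

randMask <- function(h = 16, w = 16, p = 0.4) {
  BinaryMask(matrix(stats::rbinom(h * w, 1, p), h, w))
}

diskMatrix <- function(h, w, cy, cx, r) {
  g <- expand.grid(i = 1:h, j = 1:w)
  matrix(as.numeric((g$i - cy)^2 + (g$j - cx)^2 <= r^2), h, w)
}
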