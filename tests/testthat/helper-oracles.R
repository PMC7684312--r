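# Independent brute-force enumerators for the texture matrices. These walk
# voxels one at a time with explicit loops and share no code with the
# package's vectorized implementations.

# Wrap an integer array (NA outside the mask) as a DiscreteVolume.
makeDiscrete <- function(arr, L = max(arr, na.rm = TRUE)) {
  new("DiscreteVolume", levels = array(as.integer(arr), dim(arr)),
      nLevels = as.integer(L), spacing = c(1, 1, 1), meta = list())
}

oracleDisplacement <- function(angle, d) {
  switch(angle, angle0 = c(0, d), angle90 = c(d, 0), angle45 = c(d, d),
         angle135 = c(d, -d))
}

# Symmetric co-occurrence counts by explicit voxel loops.
oracleGLCM <- function(lev, L, angle, offset) {
  d <- dim(lev)
  disp <- oracleDisplacement(angle, offset)
  M <- matrix(0, L, L)
  for (k in seq_len(d[3])) for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    i2 <- i + disp[1]; j2 <- j + disp[2]
    if (i2 < 1 || i2 > d[1] || j2 < 1 || j2 > d[2]) next
    a <- lev[i, j, k]; b <- lev[i2, j2, k]
    if (is.na(a) || is.na(b)) next
    M[a, b] <- M[a, b] + 1
    M[b, a] <- M[b, a] + 1
  }
  M
}

# Run counts by stepping along each line voxel-by-voxel.
oracleRLM <- function(lev, L, angle) {
  d <- dim(lev)
  maxLen <- max(d[1], d[2])
  R <- matrix(0, L, maxLen)
  step <- oracleDisplacement(angle, 1)
  starts <- list()
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    pi <- i - step[1]; pj <- j - step[2]
    if (pi < 1 || pi > d[1] || pj < 1 || pj > d[2])
      starts[[length(starts) + 1]] <- c(i, j)
  }
  for (k in seq_len(d[3])) for (st in starts) {
    i <- st[1]; j <- st[2]
    cur <- NA; len <- 0
    while (i >= 1 && i <= d[1] && j >= 1 && j <= d[2]) {
      v <- lev[i, j, k]
      if (!is.na(v) && !is.na(cur) && v == cur) {
        len <- len + 1
      } else {
        if (!is.na(cur)) R[cur, len] <- R[cur, len] + 1
        cur <- v; len <- if (is.na(v)) 0 else 1
      }
      i <- i + step[1]; j <- j + step[2]
    }
    if (!is.na(cur)) R[cur, len] <- R[cur, len] + 1
  }
  R
}

# 26-connected equal-level zones by breadth-first flood fill.
oracleZones <- function(lev) {
  d <- dim(lev)
  seen <- array(FALSE, d)
  zones <- list()
  idx <- which(!is.na(lev))
  for (start in idx) {
    if (seen[start]) next
    v <- lev[start]
    queue <- start
    seen[start] <- TRUE
    size <- 0
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      size <- size + 1
      pos <- arrayInd(cur, d)
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        p <- pos + c(dx, dy, dz)
        if (any(p < 1) || any(p > d)) next
        lin <- p[1] + (p[2] - 1) * d[1] + (p[3] - 1) * d[1] * d[2]
        if (!seen[lin] && !is.na(lev[lin]) && lev[lin] == v) {
          seen[lin] <- TRUE
          queue <- c(queue, lin)
        }
      }
    }
    zones[[length(zones) + 1]] <- c(level = v, size = size)
  }
  df <- as.data.frame(do.call(rbind, zones))
  df[order(df$level, df$size), , drop = FALSE]
}

# Random discretized test volume with a random mask.
randomDiscreteVolume <- function(dims = c(6, 6, 3), L = 4, maskProb = 0.85) {
  arr <- array(sample.int(L, prod(dims), replace = TRUE), dims)
  m <- array(stats::runif(prod(dims)) < maskProb, dims)
  arr[!m] <- NA_integer_
  makeDiscrete(arr, L)
}
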