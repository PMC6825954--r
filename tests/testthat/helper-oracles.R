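# Brute-force oracles, deliberately written as direct set arithmetic /
# scalar queues so they share no code path with the package's vectorized
# shift-based implementations.

diamond_offs <- function(r) {
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g[abs(g$dr) + abs(g$dc) <= r, , drop = FALSE]
}

oracle_erode <- function(mask, r) {
  offs <- diamond_offs(r)
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j]) next
    keep <- TRUE
    for (k in seq_len(nrow(offs))) {
      ii <- i + offs$dr[k]; jj <- j + offs$dc[k]
      if (ii < 1 || ii > nr || jj < 1 || jj > nc || !mask[ii, jj]) {
        keep <- FALSE; break
      }
    }
    out[i, j] <- keep
  }
  out
}

oracle_dilate <- function(mask, r) {
  offs <- diamond_offs(r)
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    for (k in seq_len(nrow(offs))) {
      ii <- i + offs$dr[k]; jj <- j + offs$dc[k]
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc && mask[ii, jj]) {
        out[i, j] <- TRUE; break
      }
    }
  }
  out
}

oracle_open <- function(mask, r) oracle_dilate(oracle_erode(mask, r), r)

# flood fill from the border over background (4-connectivity, scalar queue)
oracle_fill <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  reach <- matrix(FALSE, nr, nc)
  onborder <- row(mask) %in% c(1L, nr) | col(mask) %in% c(1L, nc)
  stack <- which(!mask & onborder)
  reach[stack] <- TRUE
  while (length(stack)) {
    p <- stack[length(stack)]; stack <- stack[-length(stack)]
    i <- ((p - 1L) %% nr) + 1L; j <- ((p - 1L) %/% nr) + 1L
    for (o in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
      ii <- i + o[1]; jj <- j + o[2]
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
          !mask[ii, jj] && !reach[ii, jj]) {
        reach[ii, jj] <- TRUE
        stack <- c(stack, (jj - 1L) * nr + ii)
      }
    }
  }
  mask | (!mask & !reach)
}

# 8-connected components via scalar BFS; returns the largest, ties broken
# by the earliest first pixel in row-major order
oracle_largest <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nbr <- list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L),
              c(1L, 1L), c(1L, -1L), c(-1L, 1L), c(-1L, -1L))
  comp <- 0L; sizes <- integer(0); firsts <- integer(0)
  for (j0 in seq_len(nc)) for (i0 in seq_len(nr)) {
    if (!mask[i0, j0] || lab[i0, j0] > 0L) next
    comp <- comp + 1L
    stack <- (j0 - 1L) * nr + i0
    lab[i0, j0] <- comp
    sz <- 0L; first_rm <- .Machine$integer.max
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- ((p - 1L) %% nr) + 1L; j <- ((p - 1L) %/% nr) + 1L
      sz <- sz + 1L
      first_rm <- min(first_rm, (i - 1L) * nc + j)
      for (o in nbr) {
        ii <- i + o[1]; jj <- j + o[2]
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
            mask[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- comp
          stack <- c(stack, (jj - 1L) * nr + ii)
        }
      }
    }
    sizes[comp] <- sz; firsts[comp] <- first_rm
  }
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) best <- best[which.min(firsts[best])]
  lab == best
}

# direct covariance-formula Pearson with the t-based two-sided p value
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  r <- sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), n - 2))
}

random_mask <- function(seed, max_side = 64L) {
  set.seed(seed)
  nr <- sample(16:max_side, 1L); nc <- sample(16:max_side, 1L)
  matrix(stats::runif(nr * nc) < 0.45, nr, nc)
}
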