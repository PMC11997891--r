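# Independent brute-force oracles used by the property tests. These are
# deliberately naive implementations kept separate from the package's own
# code paths.

# O(m^3) rubber-band baseline: a line through any two points that leaves no
# point below it is a supporting line of the lower convex hull; the baseline
# at each grid point is the highest supporting line covering its abscissa.
oracle_rubberband <- function(axis, values, tol = 1e-9) {
  m <- length(values)
  base <- rep(-Inf, m)
  for (i in 1:(m - 1)) {
    for (j in (i + 1):m) {
      slope <- (values[j] - values[i]) / (axis[j] - axis[i])
      line <- values[i] + slope * (axis - axis[i])
      if (all(values - line >= -tol)) {
        cover <- axis >= axis[i] & axis <= axis[j]
        base[cover] <- pmax(base[cover], line[cover])
      }
    }
  }
  base[1] <- values[1]
  base[m] <- values[m]
  base
}

# windowed modal label, ties keep the center; background (0) never votes
# and is never replaced
oracle_majority <- function(mask, window) {
  H <- nrow(mask); W <- ncol(mask); r <- window %/% 2
  out <- mask
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (mask[i, j] == 0) next
    nb <- mask[max(1, i - r):min(H, i + r), max(1, j - r):min(W, j + r)]
    nb <- nb[nb > 0]
    tab <- table(nb)
    best <- max(tab)
    winners <- as.integer(names(tab)[tab == best])
    out[i, j] <- if (mask[i, j] %in% winners) mask[i, j] else
      winners[which.max(tab[as.character(winners)])]
  }
  out
}

# pairwise Mann-Whitney AUC with half credit for ties
oracle_mw_auc <- function(counts, truth) {
  h <- counts[truth == "healthy"]
  p <- counts[truth == "pathological"]
  s <- 0
  for (a in p) for (b in h) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(h) * length(p))
}

# brute-force interior test: pixel kept iff all 8 neighbours inside mask
oracle_interior <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(FALSE, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (!mask[i, j]) next
    ok <- i > 1 && i < H && j > 1 && j < W
    if (ok) ok <- all(mask[(i - 1):(i + 1), (j - 1):(j + 1)])
    out[i, j] <- ok
  }
  out
}
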