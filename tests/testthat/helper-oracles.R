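# Brute-force oracle implementations: direct loops over pixels and points,
# written independently of the production code paths.

naive_vd <- function(mask, zone_mask) {
  n <- 0L; v <- 0L
  for (j in seq_len(ncol(mask))) for (i in seq_len(nrow(mask))) {
    if (zone_mask[i, j]) {
      n <- n + 1L
      if (mask[i, j]) v <- v + 1L
    }
  }
  if (n == 0) return(NA_real_)
  v / n
}

naive_vdi <- function(mask, skeleton, zone_mask) {
  v <- 0L; s <- 0L
  for (j in seq_len(ncol(mask))) for (i in seq_len(nrow(mask))) {
    if (zone_mask[i, j]) {
      if (mask[i, j]) v <- v + 1L
      if (skeleton[i, j]) s <- s + 1L
    }
  }
  if (s == 0) return(NA_real_)
  v / s
}

naive_vlf <- function(skeleton, zone_mask) {
  n <- 0L; s <- 0L
  for (j in seq_len(ncol(skeleton))) for (i in seq_len(nrow(skeleton))) {
    if (zone_mask[i, j]) {
      n <- n + 1L
      if (skeleton[i, j]) s <- s + 1L
    }
  }
  if (n == 0) return(NA_real_)
  s / n
}

naive_fd <- function(skeleton, zone_mask = NULL, eps = NULL) {
  sk <- skeleton != 0
  if (!is.null(zone_mask)) sk <- sk & zone_mask
  if (is.null(eps)) {
    emax <- min(dim(sk)) / 4
    eps <- 2^(1:30); eps <- eps[eps <= emax]
  }
  pts <- which(sk, arr.ind = TRUE)
  if (nrow(pts) == 0) return(NA_real_)
  org <- c(min(pts[, 1]), min(pts[, 2]))
  if (!is.null(zone_mask)) {
    zp <- which(zone_mask, arr.ind = TRUE)
    if (nrow(zp) > 0) org <- c(min(zp[, 1]), min(zp[, 2]))
  }
  counts <- numeric(length(eps))
  for (k in seq_along(eps)) {
    e <- eps[k]
    keys <- character(nrow(pts))
    for (i in seq_len(nrow(pts)))
      keys[i] <- paste((pts[i, 1] - org[1]) %/% e, (pts[i, 2] - org[2]) %/% e)
    counts[k] <- length(unique(keys))
  }
  keep <- counts >= 2
  if (sum(keep) < 2) return(NA_real_)
  lx <- log(eps[keep]); ly <- log(counts[keep])
  mx <- mean(lx); my <- mean(ly)
  -(sum((lx - mx) * (ly - my)) / sum((lx - mx)^2))
}

naive_lc <- function(p) {
  total <- 0
  for (i in seq_len(nrow(p) - 1))
    total <- total + sqrt((p[i, 1] - p[i + 1, 1])^2 +
                            (p[i, 2] - p[i + 1, 2])^2)
  as.numeric(total)
}

naive_lx <- function(p) {
  n <- nrow(p)
  as.numeric(sqrt((p[n, 1] - p[1, 1])^2 + (p[n, 2] - p[1, 2])^2))
}

naive_mdac <- function(p, step = 5) {
  n <- nrow(p)
  if (n < 2 * step + 1) return(NA_real_)
  total <- 0
  for (k in (step + 1):(n - step)) {
    v1 <- p[k, ] - p[k - step, ]
    v2 <- p[k + step, ] - p[k, ]
    cosang <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
    total <- total + acos(min(1, max(-1, cosang)))
  }
  as.numeric(total / (n - 2 * step))
}

# Direct count of pixel centers within w/2 of a segment (mm coords).
naive_ribbon_count <- function(p0, p1, width_mm, shape, pitch) {
  cnt <- 0L
  hw <- width_mm / 2
  for (j in seq_len(shape[2])) for (i in seq_len(shape[1])) {
    x <- (j - 0.5 - shape[2] / 2) * pitch
    y <- (shape[1] / 2 - (i - 0.5)) * pitch
    d <- p1 - p0
    len2 <- sum(d^2)
    t <- if (len2 > 0) max(0, min(1, sum((c(x, y) - p0) * d) / len2)) else 0
    q <- p0 + t * d
    if (sum((c(x, y) - q)^2) <= hw^2) cnt <- cnt + 1L
  }
  cnt
}

# Kruskal-Wallis H with tie correction, from first principles.
naive_kruskal_h <- function(groups) {
  y <- unlist(groups)
  N <- length(y)
  r <- rank(y)
  idx <- rep(seq_along(groups), vapply(groups, length, 1L))
  h <- 12 / (N * (N + 1)) *
    sum(tapply(r, idx, function(v) length(v) * mean(v)^2)) - 3 * (N + 1)
  ties <- table(y)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}
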