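# Brute-force oracles, deliberately independent of the package's
# vectorized implementations, plus small fixture generators.

# per-pixel three-inequality loop
oracle_in_range <- function(hsv, range) {
  out <- matrix(FALSE, nrow(hsv), ncol(hsv))
  for (i in seq_len(nrow(hsv))) {
    for (j in seq_len(ncol(hsv))) {
      px <- hsv[i, j, ]
      out[i, j] <- all(px >= range$lower) && all(px <= range$upper)
    }
  }
  out
}

# per-pixel logical-or loop over a list of masks
oracle_union_count <- function(masks) {
  n <- 0L
  for (i in seq_len(nrow(masks[[1]]))) {
    for (j in seq_len(ncol(masks[[1]]))) {
      if (any(vapply(masks, function(m) unclass(m)[i, j] == 255L, TRUE)))
        n <- n + 1L
    }
  }
  n
}

# BFS flood fill, 8-connectivity; returns sizes of all components
oracle_component_sizes <- function(mask) {
  seen <- matrix(FALSE, nrow(mask), ncol(mask))
  sizes <- integer(0)
  for (si in seq_len(nrow(mask))) {
    for (sj in seq_len(ncol(mask))) {
      if (!mask[si, sj] || seen[si, sj]) next
      queue <- list(c(si, sj)); seen[si, sj] <- TRUE; n <- 0L
      while (length(queue) > 0) {
        p <- queue[[1]]; queue <- queue[-1]; n <- n + 1L
        for (di in -1:1) for (dj in -1:1) {
          if (di == 0 && dj == 0) next
          qi <- p[1] + di; qj <- p[2] + dj
          if (qi >= 1 && qi <= nrow(mask) && qj >= 1 && qj <= ncol(mask) &&
              mask[qi, qj] && !seen[qi, qj]) {
            seen[qi, qj] <- TRUE
            queue[[length(queue) + 1L]] <- c(qi, qj)
          }
        }
      }
      sizes <- c(sizes, n)
    }
  }
  sizes
}

# closed-form OLS via the normal equations
oracle_ols <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  c(slope = slope, intercept = intercept)
}

random_hsv_image <- function(h, w) {
  hsv_image(array(c(sample(0:179, h * w, TRUE),
                    sample(0:255, h * w, TRUE),
                    sample(0:255, h * w, TRUE)), c(h, w, 3)))
}

random_mask <- function(h, w, p = 0.5) {
  binary_mask(matrix(ifelse(stats::runif(h * w) < p, 255, 0), h, w))
}

uniform_rgb <- function(r, g, b, h = 4, w = 4) {
  px <- array(0, c(h, w, 3))
  px[, , 1] <- r; px[, , 2] <- g; px[, , 3] <- b
  rgb_image(px)
}
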