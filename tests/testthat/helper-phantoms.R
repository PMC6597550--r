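# Shared phantom fixtures, all generated in code at test time.

# Small, quick phantom with moderate airspace.
quick_config <- function(shape = c(60L, 80L, 80L), noise_sd = 10, ...) {
  phantom_config(shape = shape,
                 target_profile = list(edge = 5, plateau = 25,
                                       rise_length_um = 40),
                 stoma_sites = list(abaxial = 3L),
                 noise_sd = noise_sd, ...)
}

# Sparse phantom: pocket chains stay below the cavity volume threshold so
# sub-stomatal cavities are the only large near-epidermis components.
sparse_config <- function(n_stomata = 5L, cavity_fraction = 1, ...) {
  phantom_config(shape = c(60L, 120L, 120L),
                 target_profile = list(edge = 0.5, plateau = 4,
                                       rise_length_um = 40),
                 pocket_radius_um = c(3, 6),
                 stoma_sites = list(abaxial = n_stomata),
                 cavity_fraction = cavity_fraction, noise_sd = 0, ...)
}

# Masks straight from truth labels (the voxel-count oracle side).
truth_masks <- function(truth) {
  vs <- truth$voxel_size
  list(leaf = binary_mask(truth$labels != 0L, "leaf", vs),
       tissue = binary_mask(truth$labels != 0L & truth$labels != 4L, "tissue", vs),
       airspace = binary_mask(truth$labels == 4L, "airspace", vs))
}

# A digital ball mask centred in a cube of tissue.
ball_masks <- function(r, n = 2L * r + 11L, voxel_size = 1,
                       centre = rep((n + 1) / 2, 3)) {
  ax <- seq_len(n)
  dz <- (ax - centre[1])^2
  dy <- (ax - centre[2])^2
  dx <- (ax - centre[3])^2
  d2 <- outer(outer(dz, dy, `+`), dx, `+`)
  air <- d2 <= r^2
  list(air = binary_mask(air, "airspace", voxel_size),
       tissue = binary_mask(!air, "tissue", voxel_size))
}

# Random bimodal 256-bin histogram for threshold oracle tests.
random_bimodal_hist <- function() {
  m1 <- sample(30:90, 1)
  m2 <- sample(150:220, 1)
  s1 <- runif(1, 4, 15); s2 <- runif(1, 4, 15)
  n1 <- sample(2000:20000, 1); n2 <- sample(2000:20000, 1)
  v <- c(pmin(255, pmax(0, round(rnorm(n1, m1, s1)))),
         pmin(255, pmax(0, round(rnorm(n2, m2, s2)))))
  tabulate(v + 1L, 256L)
}

# Brute-force IsoData oracle: smallest t satisfying the fixed-point
# condition, scanning all 255 candidates.
isodata_oracle <- function(counts) {
  v <- 0:255
  for (t in 0:254) {
    lo <- counts[1:(t + 1)]
    hi <- counts[(t + 2):256]
    if (sum(lo) == 0 || sum(hi) == 0) next
    mu_lo <- sum(lo * v[1:(t + 1)]) / sum(lo)
    mu_hi <- sum(hi * v[(t + 2):256]) / sum(hi)
    if (t == floor((mu_lo + mu_hi) / 2 + 0.5)) return(t)
  }
  NA_integer_
}

# Independent minimum-threshold oracle: literal smoothing loop written
# separately from the implementation.
minimum_oracle <- function(counts, max_iter = 10000L) {
  s <- as.numeric(counts)
  smooth1 <- function(x) {
    n <- length(x)
    sapply(seq_len(n), function(i) {
      l <- if (i == 1) x[2] else x[i - 1]
      r <- if (i == n) x[n - 1] else x[i + 1]
      (l + x[i] + r) / 3
    })
  }
  maxima <- function(x) {
    r <- rle(x); k <- length(r$values)
    st <- cumsum(r$lengths) - r$lengths + 1L
    idx <- integer(0)
    for (i in seq_len(k)) {
      if ((i == 1 || r$values[i - 1] < r$values[i]) &&
          (i == k || r$values[i + 1] < r$values[i]) && r$values[i] > 0)
        idx <- c(idx, st[i])
    }
    idx
  }
  for (it in seq_len(max_iter)) {
    mx <- maxima(s)
    if (length(mx) == 2L) {
      betw <- (mx[1] + 1L):(mx[2] - 1L)
      return(betw[which.min(s[betw])] - 1L)
    }
    if (length(mx) < 2L) return(NA_integer_)
    s <- smooth1(s)
  }
  NA_integer_
}
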