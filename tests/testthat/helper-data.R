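# Shared fixtures, all generated in code.

# two-Gaussian classification task
gauss2_task <- function(n_per = 100, d = 2, sep = 3, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * d, -sep), n_per, d),
             matrix(rnorm(n_per * d, sep), n_per, d))
  list(x = x, y = rep(c("a", "b"), each = n_per))
}

# small synthetic image dataset over shape-distinct genera
tiny_image_dataset <- function(per_class = 6, noise = 0, seed = 1,
                               genera = c("Aggregicoccus", "Corallococcus",
                                          "Labilithrix")) {
  generate_dataset(generator_profile("balanced", genera = genera,
                                     per_class = per_class, noise = noise,
                                     seed = seed))
}

# dataset with the published per-genus class sizes but trivial images;
# cheap fixture for subset-filtering arithmetic
profile_counts_dataset <- function() {
  counts <- myxodb_class_sizes()
  genus <- rep(names(counts), counts)
  images <- replicate(length(genus), matrix(0, 2, 2), simplify = FALSE)
  labeled_dataset(images, genus, classes = names(counts))
}

# binary foreground mask of a rendered image at the midpoint threshold
foreground_mask <- function(gray) {
  gray > (min(gray) + max(gray)) / 2
}

# Zhang-Suen thinning: independent skeletonisation oracle for the
# renderer tests (operates on a logical mask)
zhang_suen_thin <- function(mask) {
  m <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- as.integer(mask)
  neighbours <- function(m, r, c) {
    c(m[r - 1, c], m[r - 1, c + 1], m[r, c + 1], m[r + 1, c + 1],
      m[r + 1, c], m[r + 1, c - 1], m[r, c - 1], m[r - 1, c - 1])
  }
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      del <- NULL
      on_px <- which(m == 1L, arr.ind = TRUE)
      on_px <- on_px[on_px[, 1] > 1 & on_px[, 1] < nrow(m) &
                       on_px[, 2] > 1 & on_px[, 2] < ncol(m), , drop = FALSE]
      for (i in seq_len(nrow(on_px))) {
        r <- on_px[i, 1]; c <- on_px[i, 2]
        p <- neighbours(m, r, c)
        B <- sum(p)
        if (B < 2 || B > 6) next
        A <- sum(p != c(p[-1], p[1]) & p == 0)
        if (A != 1) next
        if (pass == 1) {
          if (p[1] * p[3] * p[5] != 0 || p[3] * p[5] * p[7] != 0) next
        } else {
          if (p[1] * p[3] * p[7] != 0 || p[1] * p[5] * p[7] != 0) next
        }
        del <- rbind(del, c(r, c))
      }
      if (!is.null(del)) {
        m[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] == 1L
}

# endpoints of a skeleton: on-pixels with exactly one 8-neighbour
count_endpoints <- function(skel) {
  m <- matrix(0L, nrow(skel) + 2L, ncol(skel) + 2L)
  m[2:(nrow(skel) + 1L), 2:(ncol(skel) + 1L)] <- as.integer(skel)
  n <- 0L
  for (r in 2:(nrow(m) - 1L)) for (c in 2:(ncol(m) - 1L)) {
    if (m[r, c] == 1L) {
      nb <- sum(m[(r - 1):(r + 1), (c - 1):(c + 1)]) - 1L
      if (nb == 1L) n <- n + 1L
    }
  }
  n
}

# simple shape descriptors used by the separability audit
shape_features <- function(gray) {
  fg <- foreground_mask(gray)
  area <- mean(fg)
  meanint <- mean(gray)
  # second-moment eccentricity of the foreground
  if (sum(fg) > 1) {
    idx <- which(fg, arr.ind = TRUE)
    cv <- stats::cov(idx)
    ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
    ecc <- sqrt(max(0, 1 - ev[2] / max(ev[1], 1e-12)))
  } else ecc <- 0
  c(mean_intensity = meanint, area = area, eccentricity = ecc)
}
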