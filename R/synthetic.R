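# Synthetic stereomicroscope-like fruiting-body renderer.  The goal is
# not photorealism: each genus gets a morphotype (shape family, relative
# size, texture, stalk/sporangiole flags) distilled from the published
# macro-morphology key, and the renderer emits images whose between-class
# differences are shape and texture — never colour — so that every
# pipeline stage can be exercised without the (undeposited) real image
# collection.

#' Morphotype registry for the 30 genera
#'
#' One renderer specification per genus: a shape family (`sphere`,
#' `sphere_cluster`, `coral_branched`, `tree_stalked`, `bean_oval`,
#' `swarm_only`), a relative size range (fraction of the image side,
#' mapped linearly from the published micrometre ranges; "not
#' distinguishable" sizes default to the global median range), a texture
#' class (`hard`, `soft`, `glassy`, `tough`) controlling contrast and
#' edge sharpness, stalk/sporangiole flags, and a cluster-count range.
#'
#' @return data.frame with 30 rows and columns `genus`, `shape_family`,
#'   `size_lo`, `size_hi`, `texture`, `has_stalk`, `has_sporangioles`,
#'   `cluster_lo`, `cluster_hi`.
#' @export
make_morphotype_registry <- function() {
  # genus, family, um_lo, um_hi (NA = ND), texture, stalk, sporangiole,
  # cluster range
  m <- list(
    list("Aetherobacter",    "bean_oval",      50,   3000, "soft",  FALSE, TRUE,  2L, 4L),
    list("Aggregicoccus",    "sphere",         NA,   NA,   "soft",  FALSE, FALSE, 1L, 1L),
    list("Anaeromyxobacter", "sphere_cluster", NA,   NA,   "soft",  FALSE, TRUE,  1L, 4L),
    list("Angiococcus",      "sphere_cluster", 30,   40,   "soft",  FALSE, TRUE,  2L, 5L),
    list("Archangium",       "coral_branched", 50,   1000, "hard",  FALSE, FALSE, 1L, 1L),
    list("Byssovora",        "sphere_cluster", 220,  560,  "soft",  FALSE, TRUE,  3L, 6L),
    list("Chondromyces",     "tree_stalked",   1000, 1000, "hard",  TRUE,  TRUE,  2L, 4L),
    list("Corallococcus",    "coral_branched", 20,   1000, "hard",  FALSE, FALSE, 1L, 1L),
    list("Cystobacter",      "sphere_cluster", 50,   180,  "hard",  FALSE, TRUE,  1L, 4L),
    list("Enhygromyxa",      "sphere",         100,  150,  "soft",  FALSE, FALSE, 1L, 1L),
    list("Haliangium",       "bean_oval",      15,   150,  "soft",  FALSE, TRUE,  1L, 2L),
    list("Hyalangium",       "sphere",         35,   45,   "glassy", FALSE, TRUE, 1L, 1L),
    list("Jahnella",         "sphere_cluster", 60,   120,  "tough", FALSE, TRUE,  2L, 5L),
    list("Kofleria",         "sphere",         NA,   NA,   "soft",  FALSE, FALSE, 1L, 1L),
    list("Labilithrix",      "swarm_only",     NA,   NA,   "soft",  FALSE, FALSE, 1L, 1L),
    list("Melittangium",     "tree_stalked",   50,   100,  "soft",  TRUE,  TRUE,  2L, 3L),
    list("Minicystis",       "bean_oval",      4,    12,   "soft",  FALSE, TRUE,  1L, 3L),
    list("Myxococcus",       "sphere",         50,   200,  "soft",  TRUE,  FALSE, 1L, 1L),
    list("Nannocystis",      "bean_oval",      6,    110,  "hard",  FALSE, TRUE,  1L, 2L),
    list("Phaselicystis",    "bean_oval",      20,   56,   "tough", FALSE, TRUE,  1L, 2L),
    list("Plesiocystis",     "sphere",         100,  500,  "soft",  FALSE, FALSE, 1L, 1L),
    list("Polyangium",       "sphere_cluster", 50,   400,  "soft",  FALSE, TRUE,  1L, 5L),
    list("Pseudenhygromyxa", "sphere",         50,   800,  "soft",  FALSE, FALSE, 1L, 1L),
    list("Pyxidicoccus",     "sphere_cluster", 30,   80,   "hard",  FALSE, TRUE,  2L, 5L),
    list("Racemicystis",     "sphere_cluster", 200,  800,  "tough", FALSE, TRUE,  2L, 4L),
    list("Sandaracinus",     "sphere",         50,   150,  "soft",  FALSE, FALSE, 1L, 1L),
    list("Sorangium",        "sphere_cluster", 20,   30,   "hard",  FALSE, TRUE,  3L, 6L),
    list("Stigmatella",      "tree_stalked",   300,  350,  "hard",  TRUE,  TRUE,  2L, 4L),
    list("Vitiosangium",     "bean_oval",      20,   200,  "soft",  FALSE, FALSE, 1L, 1L),
    list("Vulgatibacter",    "sphere",         NA,   NA,   "soft",  FALSE, FALSE, 1L, 1L)
  )
  df <- data.frame(
    genus = vapply(m, `[[`, "", 1L),
    shape_family = vapply(m, `[[`, "", 2L),
    um_lo = vapply(m, function(r) as.numeric(r[[3L]]), 0),
    um_hi = vapply(m, function(r) as.numeric(r[[4L]]), 0),
    texture = vapply(m, `[[`, "", 5L),
    has_stalk = vapply(m, `[[`, TRUE, 6L),
    has_sporangioles = vapply(m, `[[`, TRUE, 7L),
    cluster_lo = vapply(m, function(r) as.integer(r[[8L]]), 0L),
    cluster_hi = vapply(m, function(r) as.integer(r[[9L]]), 0L),
    stringsAsFactors = FALSE)
  # ND sizes default to the global median range
  med_lo <- stats::median(df$um_lo, na.rm = TRUE)
  med_hi <- stats::median(df$um_hi, na.rm = TRUE)
  df$um_lo[is.na(df$um_lo)] <- med_lo
  df$um_hi[is.na(df$um_hi)] <- med_hi
  # micrometres -> fraction of image side, linear onto [0.1, 0.9]
  glo <- min(df$um_lo); ghi <- max(df$um_hi)
  to_frac <- function(um) 0.1 + 0.8 * (um - glo) / (ghi - glo)
  df$size_lo <- pmax(0.1, to_frac(df$um_lo))
  df$size_hi <- pmin(0.9, pmax(df$size_lo + 0.02, to_frac(df$um_hi)))
  df[order(df$genus),
     c("genus", "shape_family", "size_lo", "size_hi", "texture",
       "has_stalk", "has_sporangioles", "cluster_lo", "cluster_hi")]
}

texture_params <- function(texture) {
  switch(texture,
         hard = list(level = 0.95, edge = 0.04),
         glassy = list(level = 0.75, edge = 0.05),
         tough = list(level = 0.85, edge = 0.10),
         soft = list(level = 0.80, edge = 0.18),
         stop("unknown texture: ", texture))
}

# soft-edged ellipse field in [0,1]; rg/cg are row/col coordinate grids
draw_ellipse <- function(rg, cg, cy, cx, a, b, angle, edge) {
  xr <- (cg - cx) * cos(angle) + (rg - cy) * sin(angle)
  yr <- -(cg - cx) * sin(angle) + (rg - cy) * cos(angle)
  r <- sqrt((xr / a)^2 + (yr / b)^2)
  pmin(pmax((1 + edge - r) / (2 * edge), 0), 1)
}

# soft-edged thick segment field
draw_segment <- function(rg, cg, p0, p1, thick, edge) {
  v <- p1 - p0
  len2 <- max(sum(v^2), 1e-9)
  t <- ((rg - p0[1]) * v[1] + (cg - p0[2]) * v[2]) / len2
  t <- pmin(pmax(t, 0), 1)
  d <- sqrt((rg - (p0[1] + t * v[1]))^2 + (cg - (p0[2] + t * v[2]))^2)
  pmin(pmax((thick + edge * thick - d) / (2 * edge * thick + 1e-9), 0), 1)
}

#' Render one synthetic fruiting-body image
#'
#' Deterministic given `(spec, seed)`: draws a background with a mild
#' illumination gradient, composites the morphotype's shape primitives
#' (single or clustered ellipses, a branched coral skeleton, a stalked
#' tree with apical blobs, an elongated bean, or swarm streaks for genera
#' without compact fruiting bodies), applies texture-dependent contrast
#' and edge softness, optional sporangiole speckling, and additive
#' Gaussian noise.  Colour is an incidental per-channel tint; class
#' identity survives grayscale conversion.
#'
#' @param spec one row of [make_morphotype_registry()] (data.frame or
#'   list with the same fields).
#' @param side output side in pixels (>= 28).
#' @param noise additive Gaussian noise level on the `[0, 1]` intensity
#'   scale (0 disables).
#' @param seed integer seed.
#' @return `side x side x 3` array in `[0, 255]` (a raw RGB image).
#' @export
render_fruiting_body <- function(spec, side = 64L, noise = 0.05, seed = 1L) {
  spec <- as.list(spec)
  side <- as.integer(side)
  if (side < 28L) stop("side must be >= 28")
  fams <- c("sphere", "sphere_cluster", "coral_branched", "tree_stalked",
            "bean_oval", "swarm_only")
  if (!spec$shape_family %in% fams) {
    stop("unknown shape family: ", spec$shape_family)
  }
  tx <- texture_params(spec$texture)
  with_seed(seed, {
    rg <- matrix(rep(seq_len(side), side), side, side)
    cg <- matrix(rep(seq_len(side), each = side), side, side)
    theta <- stats::runif(1, 0, 2 * pi)
    grad <- stats::runif(1, 0, 0.08)
    bg <- stats::runif(1, 0.18, 0.28) +
      grad * ((cg / side - 0.5) * cos(theta) + (rg / side - 0.5) * sin(theta))
    sz <- stats::runif(1, spec$size_lo, spec$size_hi) * side
    # structured shapes need a minimum pixel extent to draw their parts
    if (spec$shape_family %in% c("tree_stalked", "coral_branched",
                                 "sphere_cluster")) {
      sz <- max(sz, 0.3 * side)
    }
    cy <- side / 2 + stats::runif(1, -0.08, 0.08) * side
    cx <- side / 2 + stats::runif(1, -0.08, 0.08) * side
    F <- matrix(0, side, side)
    fam <- spec$shape_family
    if (fam == "sphere") {
      ratio <- stats::runif(1, 1, 1.1)
      F <- draw_ellipse(rg, cg, cy, cx, sz / 2, sz / (2 * ratio),
                        stats::runif(1, 0, pi), tx$edge)
    } else if (fam == "sphere_cluster") {
      k <- sample(spec$cluster_lo:spec$cluster_hi, 1L)
      r0 <- sz / (1.6 + 0.4 * k)
      for (i in seq_len(k)) {
        ang <- 2 * pi * i / k + stats::runif(1, -0.4, 0.4)
        off <- if (k == 1L) 0 else stats::runif(1, 0.5, 1) * sz / 3
        F <- pmax(F, draw_ellipse(rg, cg, cy + off * sin(ang),
                                  cx + off * cos(ang),
                                  r0 * stats::runif(1, 0.8, 1.2),
                                  r0 * stats::runif(1, 0.8, 1.2),
                                  stats::runif(1, 0, pi), tx$edge))
      }
    } else if (fam == "coral_branched") {
      nb <- sample(3:5, 1L)
      thick <- max(1.2, sz / 14)
      for (i in seq_len(nb)) {
        ang <- 2 * pi * i / nb + stats::runif(1, -0.5, 0.5)
        p0 <- c(cy, cx)
        for (s in 1:3) {
          len <- sz / 2 * stats::runif(1, 0.25, 0.45)
          ang <- ang + stats::runif(1, -0.6, 0.6)
          p1 <- p0 + len * c(sin(ang), cos(ang))
          F <- pmax(F, draw_segment(rg, cg, p0, p1, thick, tx$edge * 4))
          p0 <- p1
        }
      }
    } else if (fam == "tree_stalked") {
      base <- c(min(cy + sz / 2, side - 2), cx)
      top <- c(cy - sz / 6, cx + stats::runif(1, -0.05, 0.05) * side)
      F <- pmax(F, draw_segment(rg, cg, base, top, max(1.2, sz / 16),
                                tx$edge * 4))
      nb <- sample(2:4, 1L)
      for (i in seq_len(nb)) {
        # crown branches fan upwards, tips kept apart so blobs stay distinct
        ang <- -pi / 2 + (i - (nb + 1) / 2) * 1.1 +
          stats::runif(1, -0.1, 0.1)
        tip <- top + sz / 2 * c(sin(ang), cos(ang))
        tip[1] <- min(max(tip[1], 2), side - 1)
        tip[2] <- min(max(tip[2], 2), side - 1)
        F <- pmax(F, draw_segment(rg, cg, top, tip, max(1, sz / 26),
                                  tx$edge * 4))
        F <- pmax(F, draw_ellipse(rg, cg, tip[1], tip[2], sz / 11, sz / 11,
                                  0, tx$edge))
      }
    } else if (fam == "bean_oval") {
      ratio <- stats::runif(1, 1.9, 2.6)
      F <- draw_ellipse(rg, cg, cy, cx, sz / 2, sz / (2 * ratio),
                        stats::runif(1, 0, pi), tx$edge)
    } else if (fam == "swarm_only") {
      # rippled streak texture across the whole field, no compact body
      ang <- stats::runif(1, 0, pi)
      freq <- stats::runif(1, 3, 6) * 2 * pi / side
      phase <- stats::runif(1, 0, 2 * pi)
      u <- cg * cos(ang) + rg * sin(ang)
      v <- -cg * sin(ang) + rg * cos(ang)
      wob <- sin(freq * u + phase + 0.8 * sin(freq * 0.37 * v))
      F <- 0.45 * pmax(wob, 0)^1.5
    }
    if (fam == "tree_stalked" || (isTRUE(spec$has_stalk) &&
                                  fam != "swarm_only")) {
      if (fam != "tree_stalked") {
        base <- c(min(cy + sz / 1.6, side - 1), cx)
        F <- pmax(F, draw_segment(rg, cg, c(cy, cx), base,
                                  max(1, sz / 18), tx$edge * 4))
      }
    }
    if (isTRUE(spec$has_sporangioles) && fam != "swarm_only") {
      speck <- 0.12 * sin(rg * 1.7) * sin(cg * 1.7)
      F <- pmin(pmax(F + speck * (F > 0.5), 0), 1)
    }
    gray <- pmax(bg, tx$level * F)
    if (noise > 0) {
      gray <- gray + stats::rnorm(side * side, 0, noise)
    }
    gray <- pmin(pmax(gray, 0), 1)
    tint <- stats::runif(3, 0.88, 1)
    out <- array(0, c(side, side, 3L))
    for (ch in 1:3) out[, , ch] <- gray * tint[ch] * 255
    out
  })
}

#' Generation profile for a synthetic dataset
#'
#' @param profile `"table2"` (the published 322-image class-size profile
#'   over all 30 genera), `"balanced"` (equal counts over selected
#'   genera) or `"custom"` (explicit `counts`).
#' @param genera genera to include (balanced profile; default 3 genera
#'   covering three distinct shape families: sphere, branched coral and
#'   swarm-only).
#' @param per_class samples per class (balanced profile).
#' @param counts named integer vector (custom profile).
#' @param noise additive noise level on the `[0, 1]` scale.
#' @param side rendered image side in pixels.
#' @param seed master seed for the whole dataset.
#' @return A `generator_profile` object.
#' @export
generator_profile <- function(profile = c("table2", "balanced", "custom"),
                              genera = c("Aggregicoccus", "Corallococcus",
                                         "Labilithrix"),
                              per_class = 60L, counts = NULL,
                              noise = 0.05, side = 64L, seed = 1L) {
  profile <- match.arg(profile)
  counts <- switch(profile,
    table2 = myxodb_class_sizes(),
    balanced = stats::setNames(rep(as.integer(per_class), length(genera)),
                               genera),
    custom = {
      if (is.null(counts) || is.null(names(counts))) {
        stop("custom profile requires a named counts vector")
      }
      counts
    })
  if (sum(counts) < 1) stop("profile yields zero samples")
  structure(list(profile = profile, counts = counts, noise = noise,
                 side = as.integer(side), seed = as.integer(seed)),
            class = "generator_profile")
}

#' Generate a labeled synthetic dataset
#'
#' Renders every image of the profile (deterministically from the master
#' seed), converts to grayscale, normalises to the archive size and then
#' the network input size, and returns a [labeled_dataset()].  When
#' `out_dir` is given the rendered RGB images are also written as a
#' directory-per-class PNG tree (loadable by [load_dataset()]) together
#' with a `manifest.csv` recording every per-image seed.
#'
#' @param profile a [generator_profile()].
#' @param out_dir optional output directory for the PNG tree.
#' @param side network input side (pixels).
#' @param archive_side intermediate normalisation side (pixels).
#' @param stage `"input"` (default) or `"archive"` — see [load_dataset()].
#' @return A `myxo_dataset` (with a `manifest` attribute).
#' @export
generate_dataset <- function(profile, out_dir = NULL, side = 28L,
                             archive_side = 100L,
                             stage = c("input", "archive")) {
  stopifnot(inherits(profile, "generator_profile"))
  stage <- match.arg(stage)
  registry <- make_morphotype_registry()
  counts <- profile$counts[order(names(profile$counts))]
  bad <- setdiff(names(counts), registry$genus)
  if (length(bad)) stop("unknown genera in profile: ",
                        paste(bad, collapse = ", "))
  total <- sum(counts)
  if (total < 1) stop("profile yields zero samples")
  seeds <- with_seed(profile$seed,
                     sample.int(.Machine$integer.max - 1L, total))
  images <- vector("list", total)
  genus <- character(total)
  paths <- rep(NA_character_, total)
  i <- 0L
  for (g in names(counts)) {
    spec <- registry[registry$genus == g, ]
    for (j in seq_len(counts[[g]])) {
      i <- i + 1L
      raw <- render_fruiting_body(spec, side = profile$side,
                                  noise = profile$noise, seed = seeds[i])
      if (!is.null(out_dir)) {
        d <- file.path(out_dir, g)
        dir.create(d, recursive = TRUE, showWarnings = FALSE)
        paths[i] <- file.path(d, sprintf("%s_%03d.png", g, j))
        write_image(raw, paths[i])
      }
      gimg <- resize_gray(to_gray(raw), archive_side)
      if (stage == "input") gimg <- resize_gray(gimg, side)
      images[[i]] <- gimg
      genus[i] <- g
    }
  }
  ds <- labeled_dataset(images, genus, classes = names(counts),
                        paths = paths)
  manifest <- data.frame(path = paths, genus = genus,
                         suborder = ds$suborder, seed = seeds)
  if (!is.null(out_dir)) {
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  attr(ds, "manifest") <- manifest
  ds
}
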