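#' @import stats
#' @import utils
NULL

# Run an expression with a locally seeded RNG, restoring the caller's RNG
# state afterwards so seeded package functions never perturb user code.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

#' Load an image file as an RGB pixel grid
#'
#' Reads a PNG, JPEG or TIFF file and returns its pixels as an
#' `height x width x 3` array of intensities in `[0, 255]` (red, green,
#' blue).  Grayscale files are replicated across the three channels;
#' 16-bit inputs are rescaled to `[0, 255]`; an alpha channel, if present,
#' is dropped.
#'
#' @param path path to a readable PNG/JPEG/TIFF file.
#' @return Numeric array of dimension `c(height, width, 3)`.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("cannot read image '", path, "': ",
                                           conditionMessage(e)))
  px <- EBImage::imageData(img)  # EBImage stores (x = col, y = row[, c])
  if (length(px) == 0L) stop("zero-sized image: ", path)
  if (length(dim(px)) == 2L) {
    px <- array(px, dim = c(dim(px), 1L))
  }
  if (dim(px)[3] >= 3L) {
    px <- px[, , 1:3, drop = FALSE]
  } else {
    px <- array(px[, , 1L], dim = c(dim(px)[1:2], 3L))
  }
  out <- aperm(px, c(2L, 1L, 3L)) * 255
  if (any(!is.finite(out)) || min(out) < 0 || max(out) > 255 + 1e-6) {
    stop("image '", path, "' has intensities outside [0, 255] after decoding")
  }
  out
}

#' Write a grayscale or RGB pixel grid to a PNG file
#'
#' Inverse of [load_image()] for 8-bit data: intensities in `[0, 255]` are
#' rescaled to `[0, 1]` and written as PNG.
#'
#' @param pixels `H x W` matrix or `H x W x 3` array in `[0, 255]`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image <- function(pixels, path) {
  px <- pixels / 255
  if (length(dim(px)) == 3L) {
    img <- EBImage::Image(aperm(px, c(2L, 1L, 3L)), colormode = "Color")
  } else {
    img <- EBImage::Image(t(px), colormode = "Grayscale")
  }
  EBImage::writeImage(img, path, type = "png")
  invisible(path)
}

#' Convert an RGB pixel grid to grayscale
#'
#' Luminance conversion `I_g = 0.2989 R + 0.5870 G + 0.1140 B`, the
#' standard ITU-R 601 luma weighting.  Output intensities are kept as real
#' values (no rounding), so pure white maps to 254.9745.
#'
#' @param img `H x W x 3` array in `[0, 255]` (see [load_image()]), or an
#'   `H x W` matrix which is returned unchanged.
#' @return `H x W` numeric matrix of grayscale intensities.
#' @export
to_gray <- function(img) {
  if (is.matrix(img)) return(img)
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  0.2989 * img[, , 1L] + 0.5870 * img[, , 2L] + 0.1140 * img[, , 3L]
}

#' Resize a grayscale image to a square
#'
#' Bilinear resampling to `side x side` pixels.  Bilinear interpolation is
#' a convex combination of neighbouring pixels, so the output intensity
#' range never exceeds the input range; an image already of the requested
#' size is returned unchanged.
#'
#' @param img `H x W` numeric matrix.
#' @param side target side length in pixels (>= 1).
#' @return `side x side` numeric matrix.
#' @export
resize_gray <- function(img, side) {
  stopifnot(is.matrix(img))
  side <- as.integer(side)
  if (is.na(side) || side < 1L) stop("side must be a positive integer")
  if (nrow(img) == side && ncol(img) == side) return(img)
  out <- EBImage::resize(EBImage::Image(t(img)), w = side, h = side,
                         filter = "bilinear", antialias = FALSE)
  m <- t(EBImage::imageData(out))
  # clamp interpolation round-off to the input range
  pmin(pmax(m, min(img)), max(img))
}

#' Construct a labeled image dataset
#'
#' The package's dataset container: a list of same-sized grayscale images
#' with genus and suborder labels validated against the taxonomy registry.
#'
#' @param images list of numeric matrices, all with identical dimensions.
#' @param genus character vector of genus labels, one per image.
#' @param registry registry data.frame, see [genus_registry()].
#' @param classes class universe (character); defaults to the genera
#'   present in `genus`.  Classes may have zero samples (e.g. an empty
#'   class directory) and are retained for bookkeeping.
#' @param paths optional source file paths (recycled NA otherwise).
#' @return An object of class `myxo_dataset` with fields `images`,
#'   `genus`, `suborder`, `classes`, `registry`, `paths`.
#' @export
labeled_dataset <- function(images, genus, registry = genus_registry(),
                            classes = NULL, paths = NULL) {
  stopifnot(is.list(images), length(images) == length(genus))
  if (length(images)) {
    d <- dim(images[[1L]])
    ok <- vapply(images, function(m) is.matrix(m) && identical(dim(m), d),
                 logical(1))
    if (!all(ok)) stop("all images must be matrices of identical dimensions")
    if (any(vapply(images, function(m) any(!is.finite(m)) || min(m) < 0,
                   logical(1)))) {
      stop("image intensities must be finite and >= 0")
    }
  }
  genus <- as.character(genus)
  if (is.null(classes)) classes <- sort(unique(genus))
  bad <- setdiff(classes, registry$genus)
  if (length(bad)) {
    stop("labels not present in the registry: ", paste(bad, collapse = ", "))
  }
  if (!all(genus %in% classes)) stop("genus labels outside the class universe")
  if (is.null(paths)) paths <- rep(NA_character_, length(images))
  structure(list(images = images, genus = genus,
                 suborder = genus_to_suborder0(genus, registry),
                 classes = classes, registry = registry,
                 paths = paths),
            class = "myxo_dataset")
}

genus_to_suborder0 <- function(genus, registry) {
  registry$suborder[match(genus, registry$genus)]
}

#' @export
print.myxo_dataset <- function(x, ...) {
  d <- if (length(x$images)) paste(dim(x$images[[1L]]), collapse = "x") else "-"
  cat("<myxo_dataset> ", length(x$images), " images (", d, "), ",
      length(x$classes), " classes, ",
      length(unique(x$suborder)), " suborders\n", sep = "")
  invisible(x)
}

#' @export
length.myxo_dataset <- function(x) length(x$images)

#' Subset a labeled dataset by sample index
#' @param x a `myxo_dataset`.
#' @param i integer or logical index over samples.
#' @param ... ignored.
#' @export
`[.myxo_dataset` <- function(x, i, ...) {
  labeled_dataset(x$images[i], x$genus[i], registry = x$registry,
                  classes = x$classes, paths = x$paths[i])
}

#' Load a directory-per-class image dataset
#'
#' Expects `root/<GenusName>/<image files>`.  Every image is loaded,
#' converted to grayscale, normalised to the archive size (default
#' 100 x 100), and — unless `stage = "archive"` — resized again to the
#' network input size (default 28 x 28).  Ordering is deterministic
#' (lexicographic by path).
#'
#' @param root dataset root directory.
#' @param registry taxonomy registry, see [genus_registry()].
#' @param side network input side in pixels.
#' @param archive_side intermediate normalisation side in pixels.
#' @param stage `"input"` (default, `side`-sized images) or `"archive"`
#'   (images kept at `archive_side`, e.g. for crop augmentation).
#' @return A [labeled_dataset()].
#' @export
load_dataset <- function(root, registry = genus_registry(), side = 28L,
                         archive_side = 100L,
                         stage = c("input", "archive")) {
  stage <- match.arg(stage)
  if (!dir.exists(root)) stop("dataset root not found: ", root)
  dirs <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  if (!length(dirs)) stop("no class subdirectories under ", root)
  bad <- setdiff(dirs, registry$genus)
  if (length(bad)) {
    stop("class directories not in the registry: ", paste(bad, collapse = ", "))
  }
  out_side <- if (stage == "archive") archive_side else side
  images <- list(); genus <- character(); paths <- character()
  for (d in dirs) {
    files <- sort(list.files(file.path(root, d),
                             pattern = "\\.(png|jpe?g|tiff?)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (!length(files)) {
      warning("class directory '", d, "' contains no images; ",
              "class retained with zero samples")
      next
    }
    for (f in files) {
      g <- resize_gray(to_gray(load_image(f)), archive_side)
      if (stage == "input") g <- resize_gray(g, side)
      images[[length(images) + 1L]] <- g
      genus <- c(genus, d)
      paths <- c(paths, f)
    }
  }
  labeled_dataset(images, genus, registry = registry, classes = dirs,
                  paths = paths)
}

#' Drop classes with too few samples
#'
#' Removes every class with fewer than `min_n` samples, leaving the
#' surviving samples untouched.  With the published MYXO.DB class-size
#' profile, `min_n = 4` leaves 25 classes (313 images) and `min_n = 8`
#' leaves 22 classes.
#'
#' @param ds a [labeled_dataset()].
#' @param min_n minimum class size to keep (>= 1).
#' @return A filtered `myxo_dataset`.
#' @export
filter_min_class_size <- function(ds, min_n) {
  stopifnot(inherits(ds, "myxo_dataset"), min_n >= 1)
  counts <- table(factor(ds$genus, levels = ds$classes))
  keep_classes <- names(counts)[counts >= min_n]
  if (length(keep_classes) < 2L) {
    stop("fewer than 2 classes remain after filtering at min_n = ", min_n)
  }
  keep <- ds$genus %in% keep_classes
  labeled_dataset(ds$images[keep], ds$genus[keep], registry = ds$registry,
                  classes = keep_classes, paths = ds$paths[keep])
}

#' Augment a dataset by random sub-image cropping
#'
#' Each source image contributes itself plus `crops_per_image` random
#' square sub-windows, every output resized to `side x side`.  Crop side
#' lengths are drawn uniformly between 50% and 100% of the source side and
#' positions uniformly over the valid range; labels are inherited.  Meant
#' to be applied at the archive stage (see [load_dataset()]), mirroring
#' how small fruiting-body collections are expanded before training.
#'
#' @param ds a `myxo_dataset` (any uniform image size >= `side`).
#' @param crops_per_image number of random crops per source image (>= 0).
#' @param seed integer seed; the augmentation is deterministic given it.
#' @param side output side length in pixels.
#' @return A `myxo_dataset` with `(1 + crops_per_image) * length(ds)`
#'   images of size `side x side`.
#' @export
augment_by_cropping <- function(ds, crops_per_image, seed = 1L, side = 28L) {
  stopifnot(inherits(ds, "myxo_dataset"), crops_per_image >= 0)
  if (!length(ds$images)) return(ds)
  src_side <- nrow(ds$images[[1L]])
  with_seed(seed, {
    images <- list(); genus <- character(); paths <- character()
    for (i in seq_along(ds$images)) {
      img <- ds$images[[i]]
      images[[length(images) + 1L]] <- resize_gray(img, side)
      genus <- c(genus, ds$genus[i]); paths <- c(paths, ds$paths[i])
      if (crops_per_image > 0) {
        for (j in seq_len(crops_per_image)) {
          w <- max(side, round(stats::runif(1, 0.5, 1) * src_side))
          w <- min(w, src_side)
          r0 <- sample.int(src_side - w + 1L, 1L)
          c0 <- sample.int(src_side - w + 1L, 1L)
          crop <- img[r0:(r0 + w - 1L), c0:(c0 + w - 1L), drop = FALSE]
          images[[length(images) + 1L]] <- resize_gray(crop, side)
          genus <- c(genus, ds$genus[i]); paths <- c(paths, ds$paths[i])
        }
      }
    }
    labeled_dataset(images, genus, registry = ds$registry,
                    classes = ds$classes, paths = paths)
  })
}

#' Write a dataset manifest as CSV
#'
#' One row per sample: source path, genus, suborder, and an optional split
#' assignment (e.g. a fold id).
#'
#' @param ds a `myxo_dataset`.
#' @param path output CSV path.
#' @param split optional vector (one entry per sample).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(ds, path, split = NULL) {
  df <- data.frame(path = ds$paths, genus = ds$genus, suborder = ds$suborder,
                   split = if (is.null(split)) NA else split)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# Stack dataset images into the network input tensor (h, w, 1, N),
# rescaled from [0,255] to [0,1].
dataset_tensor <- function(ds) {
  stopifnot(length(ds$images) > 0L)
  d <- dim(ds$images[[1L]])
  arr <- array(unlist(ds$images, use.names = FALSE),
               dim = c(d[1L], d[2L], length(ds$images)))
  array(arr / 255, dim = c(d[1L], d[2L], 1L, length(ds$images)))
}
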