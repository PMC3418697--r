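#' @importFrom stats sd rnorm runif quantile
#' @importFrom utils modifyList head tail
NULL

MASK_LABELS <- c("bone", "artery", "detected_hemorrhage",
                 "segmented_hemorrhage", "ground_truth", "generic")

#' Construct a CT slice
#'
#' A `ct_slice` holds one 2-D grayscale image as an integer matrix together
#' with its gray-level domain. By convention, gray level 0 marks background
#' or masked-out pixels (structures such as bone and arteries are removed
#' from the image by setting their pixels to zero), so 0 never codes for
#' valid tissue.
#'
#' @param pixels integer (or whole-number numeric) matrix of gray levels,
#'   indexed `[row, col]` with row 1 at the top.
#' @param gray_depth maximum representable gray level; 255 for 8-bit input,
#'   4095 for 12-bit DICOM-style data.
#' @param spacing optional numeric length-2 vector of mm per pixel
#'   (row, col).
#' @param id character identifier used to guard mask/slice pairings.
#' @return object of class `ct_slice` with elements `pixels`, `height`,
#'   `width`, `gray_depth`, `spacing`, `id`.
#' @export
ct_slice <- function(pixels, gray_depth = 255L, spacing = NULL,
                     id = "slice") {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) stop("slice must be at least 1x1")
  if (any(!is.finite(pixels))) stop("pixel values must be finite")
  if (any(pixels != round(pixels))) stop("gray levels must be integers")
  storage.mode(pixels) <- "integer"
  gray_depth <- as.integer(gray_depth)
  if (gray_depth < 1L) stop("gray_depth must be >= 1")
  if (any(pixels < 0L) || any(pixels > gray_depth)) {
    stop("pixel values must lie in [0, gray_depth]")
  }
  structure(
    list(pixels = pixels, height = nrow(pixels), width = ncol(pixels),
         gray_depth = gray_depth, spacing = spacing, id = as.character(id)),
    class = "ct_slice"
  )
}

#' @export
print.ct_slice <- function(x, ...) {
  cat(sprintf("<ct_slice '%s' %dx%d, gray depth %d, %d non-zero px>\n",
              x$id, x$height, x$width, x$gray_depth, sum(x$pixels > 0L)))
  invisible(x)
}

#' Construct a region mask
#'
#' A `region_mask` is a labeled set of pixels over a named slice, stored as
#' a logical matrix of the slice's dimensions.
#'
#' @param mask logical matrix (`TRUE` = member pixel).
#' @param label one of `"bone"`, `"artery"`, `"detected_hemorrhage"`,
#'   `"segmented_hemorrhage"`, `"ground_truth"`, `"generic"`.
#' @param slice_id id of the slice the mask refers to.
#' @return object of class `region_mask`.
#' @export
region_mask <- function(mask, label = "generic", slice_id = "slice") {
  if (!is.matrix(mask) || !is.logical(mask)) {
    stop("`mask` must be a logical matrix")
  }
  if (any(is.na(mask))) stop("mask may not contain NA")
  label <- match.arg(label, MASK_LABELS)
  structure(list(mask = mask, label = label, slice_id = as.character(slice_id)),
            class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask '%s' on '%s', %dx%d, area %d>\n", x$label,
              x$slice_id, nrow(x$mask), ncol(x$mask), mask_area(x)))
  invisible(x)
}

#' Area (pixel count) of a region mask
#' @param x `region_mask` or logical matrix.
#' @return integer pixel count.
#' @export
mask_area <- function(x) {
  if (inherits(x, "region_mask")) x <- x$mask
  sum(x)
}

as_mask_matrix <- function(x) {
  if (inherits(x, "region_mask")) x$mask else x
}

check_same_slice <- function(a, b) {
  if (inherits(a, "region_mask") && inherits(b, "region_mask") &&
      !identical(a$slice_id, b$slice_id)) {
    stop("masks refer to different slices: '", a$slice_id, "' vs '",
         b$slice_id, "'")
  }
  if (!identical(dim(as_mask_matrix(a)), dim(as_mask_matrix(b)))) {
    stop("mask dimensions differ")
  }
  invisible(TRUE)
}

#' Set algebra on two region masks
#'
#' Computes union, intersection, and symmetric difference of two masks over
#' the same slice, plus their areas. `|union| = |a| + |b| - |intersection|`
#' always holds.
#'
#' @param a,b `region_mask` objects (or logical matrices) over the same
#'   slice.
#' @return list with `union`, `intersection`, `symmetric_difference`
#'   (logical matrices) and `areas` (named integer vector).
#' @export
mask_algebra <- function(a, b) {
  check_same_slice(a, b)
  ma <- as_mask_matrix(a); mb <- as_mask_matrix(b)
  u <- ma | mb
  i <- ma & mb
  s <- xor(ma, mb)
  list(union = u, intersection = i, symmetric_difference = s,
       areas = c(a = sum(ma), b = sum(mb), union = sum(u),
                 intersection = sum(i), symmetric_difference = sum(s)))
}

#' Construct a hemorrhage seed
#'
#' The seed is the initially detected hemorrhage region `C_d` together with
#' its area centroid and the gray-level range `[g_min, g_max]` observed over
#' its pixels; the range bounds the later threshold search.
#'
#' @param mask `region_mask` of the detected hemorrhage (label
#'   `detected_hemorrhage`).
#' @param slice `ct_slice` the mask was detected on.
#' @return object of class `hemorrhage_seed` with `mask`, `centroid`
#'   (row, col), `g_min`, `g_max`, `found = TRUE`; or a `found = FALSE`
#'   sentinel from [no_hemorrhage()].
#' @export
hemorrhage_seed <- function(mask, slice) {
  m <- as_mask_matrix(mask)
  if (!any(m)) stop("cannot build a seed from an empty mask")
  idx <- which(m, arr.ind = TRUE)
  grays <- slice$pixels[m]
  structure(
    list(mask = mask, centroid = c(mean(idx[, 1]), mean(idx[, 2])),
         g_min = min(grays), g_max = max(grays), found = TRUE),
    class = "hemorrhage_seed"
  )
}

#' Explicit "no hemorrhage detected" result
#' @return `hemorrhage_seed` with `found = FALSE`.
#' @export
no_hemorrhage <- function() {
  structure(list(mask = NULL, centroid = NULL, g_min = NA_integer_,
                 g_max = NA_integer_, found = FALSE),
            class = "hemorrhage_seed")
}

#' @export
print.hemorrhage_seed <- function(x, ...) {
  if (!x$found) {
    cat("<hemorrhage_seed: no hemorrhage detected>\n")
  } else {
    cat(sprintf(
      "<hemorrhage_seed: area %d, centroid (%.1f, %.1f), grays [%d, %d]>\n",
      mask_area(x$mask), x$centroid[1], x$centroid[2], x$g_min, x$g_max))
  }
  invisible(x)
}

# logical matrix of pixels with >= 1 non-member 4-neighbor; out-of-bounds
# neighbors count as non-members, so image-edge members are boundary.
boundary_lgl <- function(m) {
  h <- nrow(m); w <- ncol(m)
  up    <- rbind(FALSE, m[-h, , drop = FALSE])
  down  <- rbind(m[-1, , drop = FALSE], FALSE)
  left  <- cbind(FALSE, m[, -w, drop = FALSE])
  right <- cbind(m[, -1, drop = FALSE], FALSE)
  m & !(up & down & left & right)
}

#' Extract the boundary of a region mask
#'
#' Boundary pixels are mask members with at least one non-member in their
#' 4-neighborhood; out-of-bounds neighbors of image-edge pixels count as
#' non-members. This realizes the region boundary on which rule windows and
#' the region grower operate.
#'
#' @param mask non-empty `region_mask` or logical matrix.
#' @return integer matrix with columns `row`, `col`, one boundary pixel per
#'   row, in row-major order.
#' @export
extract_boundary <- function(mask) {
  m <- as_mask_matrix(mask)
  if (!any(m)) stop("cannot extract the boundary of an empty region")
  b <- boundary_lgl(m)
  idx <- which(t(b))  # row-major ordering
  w <- ncol(m)
  cbind(row = (idx - 1L) %/% w + 1L, col = (idx - 1L) %% w + 1L)
}

#' Label connected components
#'
#' 8-connected component labeling of a binary mask, built by merging
#' 4-connected labels across diagonal adjacencies.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return integer matrix of component labels (0 = background), labels
#'   compacted to `1..n`.
#' @export
label_components <- function(mask, connectivity = 8L) {
  m <- as_mask_matrix(mask)
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  lab <- EBImage::bwlabel(m * 1L)
  lab <- matrix(as.integer(round(lab)), nrow(m), ncol(m))
  if (connectivity == 4L || max(lab) <= 1L) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  # diagonal label pairs to merge
  p1 <- cbind(as.vector(lab[-h, -w]), as.vector(lab[-1, -1]))
  p2 <- cbind(as.vector(lab[-h, -1]), as.vector(lab[-1, -w]))
  pairs <- rbind(p1, p2)
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  n <- max(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- relab[lab[lab > 0L]]
  out
}

component_areas <- function(lab) {
  v <- lab[lab > 0L]
  if (!length(v)) return(integer(0))
  tabulate(v)
}

# ---- serialization ----------------------------------------------------------

#' Read a grayscale slice from PNG or TIFF
#'
#' Multi-channel images are collapsed by channel averaging. Values are
#' rescaled from the file's unit range onto `[0, gray_depth]` and rounded.
#'
#' @param path file path ending in `.png`, `.tif`, or `.tiff`.
#' @param gray_depth working gray depth (default 255).
#' @param id slice id; defaults to the file name.
#' @return `ct_slice`.
#' @export
read_slice <- function(path, gray_depth = 255L, id = basename(path)) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, " (PNG and TIFF are supported)")
  )
  if (length(dim(arr)) == 3L) arr <- apply(arr[, , seq_len(min(3L, dim(arr)[3])), drop = FALSE], c(1, 2), mean)
  px <- matrix(as.integer(round(arr * gray_depth)), nrow(arr), ncol(arr))
  ct_slice(px, gray_depth = gray_depth, id = id)
}

#' Write a slice as 8- or 16-bit grayscale PNG
#' @param slice `ct_slice`.
#' @param path output path.
#' @export
write_slice_png <- function(slice, path) {
  png::writePNG(slice$pixels / slice$gray_depth, path,
                dpi = NULL)
  invisible(path)
}

#' Write a region mask as a binary PNG (0 = out, 255 = in)
#' @param mask `region_mask` or logical matrix.
#' @param path output path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(as_mask_matrix(mask) * 1.0, path)
  invisible(path)
}

#' Read a binary PNG mask
#' @param path PNG path written by [write_mask_png()] (any nonzero pixel is
#'   a member).
#' @param label,slice_id metadata for the returned mask.
#' @return `region_mask`.
#' @export
read_mask_png <- function(path, label = "generic", slice_id = "slice") {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1]
  region_mask(arr > 0.5, label = label, slice_id = slice_id)
}

#' Run-length encode a mask (row-major)
#'
#' @param mask `region_mask`.
#' @return list with `height`, `width`, `label`, `slice_id`, and row-major
#'   run `values`/`lengths`, suitable for JSON serialization.
#' @export
mask_to_rle <- function(mask) {
  m <- as_mask_matrix(mask)
  r <- rle(as.integer(t(m)))
  list(height = nrow(m), width = ncol(m),
       label = if (inherits(mask, "region_mask")) mask$label else "generic",
       slice_id = if (inherits(mask, "region_mask")) mask$slice_id else "slice",
       values = r$values, lengths = r$lengths)
}

#' Decode a run-length-encoded mask
#' @param rle list as produced by [mask_to_rle()] (e.g. read back from
#'   JSON).
#' @return `region_mask`.
#' @export
rle_to_mask <- function(rle) {
  v <- inverse.rle(list(values = as.integer(rle$values),
                        lengths = as.integer(rle$lengths)))
  m <- matrix(as.logical(v), nrow = rle$height, ncol = rle$width,
              byrow = TRUE)
  region_mask(m, label = rle$label %||% "generic",
              slice_id = rle$slice_id %||% "slice")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate expr under a temporary RNG seed, restoring the caller's RNG state
with_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
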