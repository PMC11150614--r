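# Dataset plumbing: NetPBM image I/O, DRIVE-style directory layouts
# with the canonical split rules, train/validation splitting, random
# patch sampling, on-the-fly rotation augmentation, image pyramid
# downsampling and probability-map thresholding.
#
# Images travel as H x W (grey) or H x W x 3 (RGB) arrays in [0, 1].
# NetPBM (PGM/PPM, both ASCII and binary) is the supported on-disk
# format: it is self-contained and needs no external image libraries.
# PNG/TIFF/JPEG sources must be converted once, e.g. with ImageMagick
# (`convert x.png x.ppm`) or Python imageio.

#' Read a PGM/PPM image
#'
#' Supports P2/P3 (ASCII) and P5/P6 (binary), 8- or 16-bit.
#'
#' @param path file path
#' @return H x W matrix (grey) or H x W x 3 array (RGB), values in \[0, 1\]
#' @export
read_pnm <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  # tokenise the header manually: magic, width, height, maxval
  pos <- 1L
  n <- length(raw)
  next_token <- function() {
    repeat {
      while (pos <= n && raw[pos] %in% as.raw(c(9L, 10L, 13L, 32L))) pos <<- pos + 1L
      if (pos <= n && raw[pos] == as.raw(35L)) {           # '#' comment
        while (pos <= n && raw[pos] != as.raw(10L)) pos <<- pos + 1L
      } else break
    }
    start <- pos
    while (pos <= n && !raw[pos] %in% as.raw(c(9L, 10L, 13L, 32L))) pos <<- pos + 1L
    rawToChar(raw[start:(pos - 1L)])
  }
  magic <- next_token()
  if (!magic %in% c("P2", "P3", "P5", "P6"))
    input_error(sprintf("unsupported NetPBM magic '%s' in %s", magic, path))
  W <- as.integer(next_token()); H <- as.integer(next_token())
  maxval <- as.integer(next_token())
  nch <- if (magic %in% c("P3", "P6")) 3L else 1L
  nvals <- H * W * nch
  if (magic %in% c("P5", "P6")) {
    pos <- pos + 1L                                        # single whitespace
    if (maxval < 256L) {
      v <- as.integer(raw[pos:(pos + nvals - 1L)])
    } else {
      hi <- as.integer(raw[seq(pos, pos + 2L * nvals - 1L, by = 2L)])
      lo <- as.integer(raw[seq(pos + 1L, pos + 2L * nvals - 1L, by = 2L)])
      v <- hi * 256L + lo
    }
  } else {
    txt <- rawToChar(raw[pos:n])
    txt <- gsub("#[^\n]*", " ", txt)
    v <- as.integer(strsplit(trimws(txt), "[ \t\r\n]+")[[1]])[seq_len(nvals)]
  }
  v <- v / maxval
  if (nch == 1L) {
    matrix(v, H, W, byrow = TRUE)                          # raster order
  } else {
    arr <- array(0, dim = c(H, W, 3L))
    for (cch in 1:3)
      arr[, , cch] <- matrix(v[seq(cch, nvals, by = 3L)], H, W, byrow = TRUE)
    arr
  }
}

#' Write a PGM/PPM image
#'
#' @param img H x W matrix or H x W x 3 array, values in \[0, 1\]
#' @param path output path; grey images become PGM, RGB become PPM
#' @param ascii write the ASCII variants (P2/P3) instead of binary
#' @return `path`, invisibly
#' @export
write_pnm <- function(img, path, ascii = FALSE) {
  v8 <- function(x) round(pmin(pmax(x, 0), 1) * 255)   # keeps dim attributes
  rgb <- length(dim(img)) == 3L
  H <- dim(img)[1]; W <- dim(img)[2]
  if (rgb) {
    px <- v8(img)
    # interleave channels in raster order
    r <- as.vector(t(px[, , 1])); g <- as.vector(t(px[, , 2])); b <- as.vector(t(px[, , 3]))
    vals <- as.integer(rbind(r, g, b))
    magic <- if (ascii) "P3" else "P6"
  } else {
    vals <- as.vector(t(v8(img)))
    magic <- if (ascii) "P2" else "P5"
  }
  con <- file(path, "wb"); on.exit(close(con))
  writeLines(c(magic, paste(W, H), "255"), con, sep = "\n")
  if (ascii) {
    writeLines(paste(vals, collapse = "\n"), con)
  } else {
    writeBin(as.raw(vals), con)
  }
  invisible(path)
}

#' Write an image record to a DRIVE-style layout
#'
#' `root/images/<id>.ppm`, `root/masks/<id>.pgm`, and
#' `root/fov/<id>.pgm` when a FOV mask exists.
#'
#' @param rec an image record (image, mask, fov, id)
#' @param root dataset root directory (created if needed)
#' @param ascii write ASCII NetPBM
#' @return `rec$id`, invisibly
#' @export
write_record <- function(rec, root, ascii = FALSE) {
  for (d in c("images", "masks", if (!is.null(rec$fov)) "fov"))
    dir.create(file.path(root, d), recursive = TRUE, showWarnings = FALSE)
  write_pnm(rec$image, file.path(root, "images", paste0(rec$id, ".ppm")), ascii)
  write_pnm(rec$mask, file.path(root, "masks", paste0(rec$id, ".pgm")), ascii)
  if (!is.null(rec$fov))
    write_pnm(rec$fov, file.path(root, "fov", paste0(rec$id, ".pgm")), ascii)
  invisible(rec$id)
}

#' Dataset specification
#'
#' @param name one of drive, chasedb1, stare, hrf, phantom, custom;
#'   fixes the split rule
#' @param root directory containing `images/`, `masks/` and optionally
#'   `fov/`
#' @param stare_scheme for STARE only: `"half"` (10 train / 10 test) or
#'   `"loo"` (leave-one-out)
#' @param stare_fold 0-based fold index for the leave-one-out scheme
#' @param hrf_downsample_times factor-2 reductions applied to HRF
#'   records (default 2, i.e. 4x total)
#' @return object of class `vn_dataset_spec`
#' @export
dataset_spec <- function(name = c("phantom", "drive", "chasedb1", "stare", "hrf", "custom"),
                         root, stare_scheme = c("half", "loo"), stare_fold = 0L,
                         hrf_downsample_times = 2L) {
  structure(list(name = match.arg(name), root = root,
                 stare_scheme = match.arg(stare_scheme),
                 stare_fold = as.integer(stare_fold),
                 hrf_downsample_times = as.integer(hrf_downsample_times)),
            class = "vn_dataset_spec")
}

#' Load a dataset and assign canonical splits
#'
#' Records are matched by file basename; a missing vessel mask is a
#' hard error naming the id.  Split rules (ids sorted
#' lexicographically): DRIVE first 20 test / last 20 train (the
#' dataset's own numbering); CHASEDB1 last 8 test; STARE either a
#' 10/10 split or leave-one-out by fold; HRF first 15 train, rest
#' test, with each record downsampled `hrf_downsample_times` times;
#' phantom/custom put everything in train (split downstream).
#'
#' @param spec a [dataset_spec()]
#' @return list of image records with `$split` set
#' @export
load_dataset <- function(spec) {
  img_dir <- file.path(spec$root, "images")
  if (!dir.exists(img_dir)) input_error(sprintf("missing %s", img_dir))
  files <- sort(list.files(img_dir, pattern = "\\.(ppm|pgm|pnm)$"))
  ids <- sub("\\.[^.]*$", "", files)
  if (length(ids) == 0L) input_error("no NetPBM images found under images/")
  find_mask <- function(id) {
    for (ext in c(".pgm", ".ppm", ".pnm")) {
      p <- file.path(spec$root, "masks", paste0(id, ext))
      if (file.exists(p)) return(p)
    }
    input_error(sprintf("missing vessel mask for image '%s'", id))
  }
  recs <- lapply(seq_along(ids), function(i) {
    img <- read_pnm(file.path(img_dir, files[i]))
    if (length(dim(img)) == 2L) {                  # grey source: replicate
      img <- array(rep(img, 3L), dim = c(dim(img), 3L))
    }
    msk <- (read_pnm(find_mask(ids[i])) >= 0.5) * 1L
    fovp <- file.path(spec$root, "fov", paste0(ids[i], ".pgm"))
    fov <- if (file.exists(fovp)) (read_pnm(fovp) >= 0.5) * 1L else NULL
    structure(list(image = img, mask = msk, fov = fov, id = ids[i],
                   split = NA_character_), class = "vn_record")
  })
  n <- length(recs)
  split <- rep("train", n)
  if (spec$name == "drive") {
    if (n != 40L) warning(sprintf("DRIVE layout expects 40 images, found %d", n))
    split[seq_len(min(20L, n))] <- "test"
  } else if (spec$name == "chasedb1") {
    split[seq.int(max(1L, n - 7L), n)] <- "test"
  } else if (spec$name == "stare") {
    if (spec$stare_scheme == "half") {
      split[seq.int(n %/% 2 + 1L, n)] <- "test"
    } else {
      split[spec$stare_fold + 1L] <- "test"
    }
  } else if (spec$name == "hrf") {
    split[seq_len(n)] <- c(rep("train", min(15L, n)),
                           rep("test", max(0L, n - 15L)))
    recs <- lapply(recs, downsample_record, times = spec$hrf_downsample_times)
  }
  for (i in seq_len(n)) recs[[i]]$split <- split[i]
  recs
}

#' Split training records into train and validation
#'
#' @param records list of image records
#' @param frac validation fraction (default 0.1); the validation set
#'   size is `round(frac * n)`, floored at one record
#' @param seed integer seed; the partition is a pure function of the
#'   sorted ids and the seed
#' @return list with `train` and `val` record lists
#' @export
split_train_val <- function(records, frac = 0.1, seed = 0L) {
  if (frac <= 0 || frac >= 1) input_error("validation fraction must be in (0, 1)")
  n <- length(records)
  if (n < 2L) input_error("need at least two records to hold out validation")
  ord <- order(vapply(records, function(r) r$id, ""))
  records <- records[ord]
  n_val <- max(1L, as.integer(round(frac * n)))
  val_idx <- with_seed(seed, sample.int(n, n_val))
  list(train = records[setdiff(seq_len(n), val_idx)],
       val = records[val_idx])
}

#' Sample a random square patch
#'
#' The top-left corner is uniform over all positions keeping the patch
#' fully inside the image; image and mask are cropped identically.
#' Uses R's current RNG stream.
#'
#' @param record an image record
#' @param size patch side in pixels (<= both image dims)
#' @return list(image, mask, fov?) cropped patches
#' @export
sample_patch <- function(record, size) {
  H <- dim(record$image)[1]; W <- dim(record$image)[2]
  if (size > H || size > W) input_error("patch size exceeds image dimensions")
  y0 <- sample.int(H - size + 1L, 1L)
  x0 <- sample.int(W - size + 1L, 1L)
  ys <- y0 + seq_len(size) - 1L; xs <- x0 + seq_len(size) - 1L
  list(image = record$image[ys, xs, , drop = FALSE],
       mask = record$mask[ys, xs],
       fov = if (!is.null(record$fov)) record$fov[ys, xs],
       y0 = y0, x0 = x0)
}

# rotate an image (or mask) about its centre by `angle` degrees;
# bilinear for intensities, nearest-neighbour for masks (stays binary).
# Out-of-frame samples replicate the border.
rotate_raster <- function(M, angle, interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  d <- dim(M); H <- d[1]; W <- d[2]
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  th <- angle * pi / 180
  yy <- matrix(seq_len(H), H, W) - cy
  xx <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  # inverse map: source = R(-th) %*% target
  sy <- cy + yy * cos(th) - xx * sin(th)
  sx <- cx + yy * sin(th) + xx * cos(th)
  clampi <- function(v, lo, hi) pmin(pmax(v, lo), hi)
  one_plane <- function(P) {
    if (interp == "nearest") {
      iy <- clampi(round(sy), 1, H); ix <- clampi(round(sx), 1, W)
      matrix(P[cbind(as.vector(iy), as.vector(ix))], H, W)
    } else {
      y0 <- clampi(floor(sy), 1, H); x0 <- clampi(floor(sx), 1, W)
      y1 <- clampi(y0 + 1, 1, H); x1 <- clampi(x0 + 1, 1, W)
      fy <- clampi(sy - y0, 0, 1); fx <- clampi(sx - x0, 0, 1)
      g <- function(iy, ix) matrix(P[cbind(as.vector(iy), as.vector(ix))], H, W)
      (1 - fy) * ((1 - fx) * g(y0, x0) + fx * g(y0, x1)) +
        fy * ((1 - fx) * g(y1, x0) + fx * g(y1, x1))
    }
  }
  if (length(d) == 3L) {
    out <- array(0, dim = d)
    for (cch in seq_len(d[3])) out[, , cch] <- one_plane(M[, , cch])
    out
  } else one_plane(M)
}

#' On-the-fly rotation augmentation
#'
#' Draws an angle uniformly from `[-max_angle, max_angle]` degrees and
#' applies the same geometric transform to image (bilinear) and mask
#' (nearest neighbour, so it stays binary).  Uses R's current RNG.
#'
#' @param image H x W x 3 array
#' @param mask binary H x W matrix
#' @param max_angle rotation range bound in degrees (default 20)
#' @return list(image, mask, angle)
#' @export
augment_rotation <- function(image, mask, max_angle = 20) {
  ang <- stats::runif(1, -max_angle, max_angle)
  list(image = rotate_raster(image, ang, "bilinear"),
       mask = rotate_raster(mask, ang, "nearest"),
       angle = ang)
}

#' Downsample a record by successive factor-2 reductions
#'
#' Each application halves both dimensions (rounding down) by 2 x 2
#' block averaging; masks are re-binarised at 0.5 afterwards.
#'
#' @param record an image record
#' @param times number of halvings (0 = identity)
#' @return the downsampled record
#' @export
downsample_record <- function(record, times = 1L) {
  half_plane <- function(P) {
    H2 <- nrow(P) %/% 2L; W2 <- ncol(P) %/% 2L
    P <- P[seq_len(2L * H2), seq_len(2L * W2), drop = FALSE]
    (P[seq(1, 2 * H2, 2), seq(1, 2 * W2, 2)] +
     P[seq(2, 2 * H2, 2), seq(1, 2 * W2, 2)] +
     P[seq(1, 2 * H2, 2), seq(2, 2 * W2, 2)] +
     P[seq(2, 2 * H2, 2), seq(2, 2 * W2, 2)]) / 4
  }
  for (i in seq_len(times)) {
    img <- record$image
    out <- array(0, dim = c(dim(img)[1] %/% 2L, dim(img)[2] %/% 2L, 3L))
    for (cch in 1:3) out[, , cch] <- half_plane(img[, , cch])
    record$image <- out
    record$mask <- (half_plane(record$mask) >= 0.5) * 1L
    if (!is.null(record$fov)) record$fov <- (half_plane(record$fov) >= 0.5) * 1L
  }
  record
}

#' Threshold a probability map
#'
#' @param p probability matrix
#' @param t threshold; a pixel is vessel iff `p >= t` (inclusive, so
#'   exactly 0.5 maps to vessel at the default threshold)
#' @return binary matrix
#' @export
threshold_map <- function(p, t = 0.5) (p >= t) * 1L
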