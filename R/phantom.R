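# Seeded synthetic fundus phantoms: a disc-shaped field of view on a
# dark background, a branching curvilinear vessel tree darker than the
# background, a smooth illumination gradient and Gaussian sensor noise.
# The rasterised tree is the exact ground-truth mask, so every module
# downstream is testable without external datasets.

#' Phantom specification
#'
#' Fully parameterises one synthetic fundus image; the phantom is a
#' pure function of this object (bitwise reproducible).
#'
#' @param height,width image size in pixels
#' @param fov_radius_frac FOV disc radius as a fraction of
#'   `min(height, width) / 2`
#' @param n_roots number of vessel tree roots on the FOV periphery
#' @param branch_prob per-step probability that a walker spawns a branch
#' @param width_root root vessel width in pixels (>= 1)
#' @param width_decay multiplicative width factor applied to branches
#' @param tortuosity per-step direction jitter (standard deviation,
#'   degrees)
#' @param vessel_contrast intensity drop on vessels, in (0, 1]
#' @param illumination_gradient amplitude of the smooth illumination
#'   ramp (intensity units)
#' @param noise_sd Gaussian sensor noise standard deviation
#' @param seed integer seed
#' @return object of class `vn_phantom_spec`
#' @export
phantom_spec <- function(height = 256L, width = 256L, fov_radius_frac = 0.92,
                         n_roots = 4L, branch_prob = 0.015, width_root = 3.5,
                         width_decay = 0.7, tortuosity = 8,
                         vessel_contrast = 0.35, illumination_gradient = 0.08,
                         noise_sd = 0.03, seed = 1L) {
  spec <- list(height = as.integer(height), width = as.integer(width),
               fov_radius_frac = fov_radius_frac, n_roots = as.integer(n_roots),
               branch_prob = branch_prob, width_root = width_root,
               width_decay = width_decay, tortuosity = tortuosity,
               vessel_contrast = vessel_contrast,
               illumination_gradient = illumination_gradient,
               noise_sd = noise_sd, seed = as.integer(seed))
  stopifnot(spec$height >= 32, spec$width >= 32, spec$fov_radius_frac > 0,
            spec$n_roots >= 1, spec$width_root >= 1,
            spec$width_decay > 0, spec$width_decay <= 1,
            spec$vessel_contrast > 0, spec$vessel_contrast <= 1,
            spec$noise_sd >= 0)
  class(spec) <- "vn_phantom_spec"
  spec
}

# grow the vessel tree as a random recursive walk with branching;
# deterministic given the spec seed.  Returns a data.frame of segments.
grow_vessel_tree <- function(spec) {
  H <- spec$height; W <- spec$width
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  R <- spec$fov_radius_frac * min(H, W) / 2
  step_len <- 2
  segs <- vector("list", 0L)
  with_seed(spec$seed, {
    queue <- lapply(seq_len(spec$n_roots), function(i) {
      th <- stats::runif(1, 0, 2 * pi)
      y0 <- cy + 0.85 * R * sin(th)
      x0 <- cx + 0.85 * R * cos(th)
      # initial heading: inward, jittered
      list(y = y0, x = x0, ang = th + pi + stats::runif(1, -0.5, 0.5),
           w = spec$width_root, depth = 0L)
    })
    n_seg <- 0L
    while (length(queue) > 0L && n_seg < 20000L) {
      wk <- queue[[1L]]; queue <- queue[-1L]
      for (s in seq_len(400L)) {
        wk$ang <- wk$ang + stats::rnorm(1, 0, spec$tortuosity * pi / 180)
        y1 <- wk$y + step_len * sin(wk$ang)
        x1 <- wk$x + step_len * cos(wk$ang)
        w_new <- wk$w * 0.997
        n_seg <- n_seg + 1L
        segs[[n_seg]] <- c(wk$y, wk$x, y1, x1, wk$w)
        wk$y <- y1; wk$x <- x1; wk$w <- w_new
        r2 <- (y1 - cy)^2 + (x1 - cx)^2
        if (r2 > (1.02 * R)^2 || wk$w < 0.8 || n_seg >= 20000L) break
        if (stats::runif(1) < spec$branch_prob && wk$w * spec$width_decay >= 0.8 &&
            wk$depth < 6L) {
          side <- sample(c(-1, 1), 1)
          queue[[length(queue) + 1L]] <- list(
            y = y1, x = x1,
            ang = wk$ang + side * stats::runif(1, 20, 50) * pi / 180,
            w = wk$w * spec$width_decay, depth = wk$depth + 1L)
        }
      }
    }
  })
  m <- do.call(rbind, segs)
  colnames(m) <- c("y0", "x0", "y1", "x1", "w")
  as.data.frame(m)
}

# rasterise segments as dilated centrelines; width_factor scales every
# segment width (used for constricted follow-up phantoms).  Shrinking
# the factor can only remove pixels, never add them.
rasterize_tree <- function(segs, H, W, width_factor = 1) {
  mask <- matrix(FALSE, H, W)
  # sample points along each segment at 0.5 px spacing
  ns <- nrow(segs)
  ly <- vector("list", ns); lx <- vector("list", ns); lr <- vector("list", ns)
  for (i in seq_len(ns)) {
    len <- sqrt((segs$y1[i] - segs$y0[i])^2 + (segs$x1[i] - segs$x0[i])^2)
    nt <- max(2L, as.integer(ceiling(len / 0.5)) + 1L)
    tt <- seq(0, 1, length.out = nt)
    ly[[i]] <- segs$y0[i] + tt * (segs$y1[i] - segs$y0[i])
    lx[[i]] <- segs$x0[i] + tt * (segs$x1[i] - segs$x0[i])
    lr[[i]] <- rep(segs$w[i] * width_factor / 2, nt)
  }
  pts_y <- unlist(ly, use.names = FALSE)
  pts_x <- unlist(lx, use.names = FALSE)
  pts_r <- unlist(lr, use.names = FALSE)
  rq <- round(pts_r * 4) / 4       # quantise radii so discs can be shared
  for (r in unique(rq)) {
    ii <- which(rq == r)
    rr <- max(r, 0.45)             # at least a 1-px centreline
    span <- as.integer(floor(rr))
    offs <- expand.grid(dy = -span:span, dx = -span:span)
    offs <- offs[offs$dy^2 + offs$dx^2 <= rr^2 + 1e-9, , drop = FALSE]
    yy <- round(rep(pts_y[ii], each = nrow(offs))) + rep(offs$dy, length(ii))
    xx <- round(rep(pts_x[ii], each = nrow(offs))) + rep(offs$dx, length(ii))
    ok <- yy >= 1 & yy <= H & xx >= 1 & xx <= W
    mask[cbind(yy[ok], xx[ok])] <- TRUE
  }
  mask
}

fov_disc <- function(H, W, radius_frac) {
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  R <- radius_frac * min(H, W) / 2
  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  ((yy - cy)^2 + (xx - cx)^2 <= R^2) * 1L
}

box_blur3 <- function(M) {
  H <- nrow(M); W <- ncol(M)
  P <- matrix(0, H + 2, W + 2)
  P[2:(H + 1), 2:(W + 1)] <- M
  acc <- matrix(0, H, W)
  for (dy in 0:2) for (dx in 0:2)
    acc <- acc + P[dy + seq_len(H), dx + seq_len(W)]
  acc / 9
}

#' Generate a synthetic fundus phantom
#'
#' Grows a seeded branching vessel tree, rasterises it into the exact
#' ground-truth mask (clipped to the FOV disc), and renders a
#' fundus-like RGB image: background minus `vessel_contrast` times a
#' softened vessel profile, plus an illumination ramp and Gaussian
#' noise, clipped to \[0, 1\].  Green-dominant colouring is cosmetic.
#'
#' @param spec a [phantom_spec()]
#' @param constriction_factor multiplies every vessel segment width;
#'   values < 1 emulate the vascular constriction of hypertensive
#'   retinopathy while keeping tree topology and noise identical
#' @return an image record: list(image HxWx3, mask, fov, id, split)
#' @export
generate_phantom <- function(spec, constriction_factor = 1) {
  stopifnot(constriction_factor > 0, constriction_factor <= 1)
  H <- spec$height; W <- spec$width
  segs <- grow_vessel_tree(spec)
  fov <- fov_disc(H, W, spec$fov_radius_frac)
  mask <- rasterize_tree(segs, H, W, constriction_factor) & (fov == 1L)
  if (sum(mask) == 0L)
    stop("phantom spec produced zero vessel pixels; increase n_roots, ",
         "width_root or fov_radius_frac")
  vess <- box_blur3(mask * 1)
  img <- with_seed(spec$seed + 1L, {
    dir_ang <- stats::runif(1, 0, 2 * pi)
    yy <- matrix(seq_len(H) / H - 0.5, H, W)
    xx <- matrix(seq_len(W) / W - 0.5, H, W, byrow = TRUE)
    ramp <- spec$illumination_gradient * (yy * sin(dir_ang) + xx * cos(dir_ang)) * 2
    noise <- matrix(stats::rnorm(H * W, 0, spec$noise_sd), H, W)
    lum <- 0.55 + ramp - spec$vessel_contrast * vess + noise
    arr <- array(0, dim = c(H, W, 3))
    arr[, , 1] <- lum * 1.15
    arr[, , 2] <- lum
    arr[, , 3] <- lum * 0.45
    arr <- arr * array(0.04 + 0.96 * fov, dim = c(H, W, 3))
    pmin(pmax(arr, 0), 1)
  })
  structure(list(image = img, mask = mask * 1L, fov = fov,
                 id = sprintf("phantom_%06d", spec$seed),
                 split = NA_character_),
            class = "vn_record")
}

#' Generate a constricted follow-up phantom
#'
#' Same tree topology, FOV, illumination and noise as
#' `generate_phantom(spec)`, with all vessel widths multiplied by
#' `constriction_factor`; the vessel pixel count is non-increasing in
#' the factor.
#'
#' @inheritParams generate_phantom
#' @export
generate_followup <- function(spec, constriction_factor = 0.5) {
  rec <- generate_phantom(spec, constriction_factor)
  rec$id <- sprintf("%s_followup", rec$id)
  rec
}

#' Generate a list of phantom records
#'
#' @param n number of phantoms
#' @param seed base seed; phantom i uses `seed + i - 1`
#' @param ... overrides passed to [phantom_spec()]
#' @return list of image records
#' @export
make_phantoms <- function(n, seed = 0L, ...) {
  lapply(seq_len(n), function(i)
    generate_phantom(phantom_spec(seed = seed + i - 1L, ...)))
}
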