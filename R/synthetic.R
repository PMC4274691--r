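#' Specification for a synthetic muscle image
#'
#' Describes a seeded synthetic transverse H&E muscle section: a jittered-grid
#' Voronoi tessellation of polygonal fibres separated by a pale
#' connective-tissue (endomysium) band, pink eosinophilic interiors with
#' per-fibre shade variation, peripheral dark nuclei on a subset of fibres,
#' multiplicative intra-fibre speckle at three severities and optional
#' weakening of inter-fibre boundary segments. The label mask returned with
#' the image is exact by construction.
#'
#' @param height,width canvas size in px (default 512 x 512; the full-size
#'   biopsy region-of-interest profile is 1030 x 1300).
#' @param n_seeds number of Voronoi seed points (>= 4).
#' @param boundary_width endomysium band width in px (>= 1).
#' @param noise_level `"low"`, `"medium"` or `"high"`.
#' @param weak_boundary_frac fraction of inter-fibre boundary segments whose
#'   contrast is attenuated (default 0: intact endomysium baseline).
#' @param rng_seed integer seed; fixes image and mask bit-for-bit.
#' @param px_scale_um micrometres per pixel.
#' @param jitter seed jitter amplitude as a fraction of grid spacing;
#'   controls fibre-size variability (0.35 gives a clinically normal
#'   diameter spread).
#' @param nucleus_frac fraction of fibres given a peripheral nucleus.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(height = 512L, width = 512L, n_seeds = 36L,
                           boundary_width = 5L, noise_level = "low",
                           weak_boundary_frac = 0, rng_seed = 1L,
                           px_scale_um = 0.899, jitter = 0.35,
                           nucleus_frac = 0.5) {
  noise_level <- match.arg(noise_level, c("low", "medium", "high"))
  stopifnot(n_seeds >= 4L, boundary_width >= 1,
            weak_boundary_frac >= 0, weak_boundary_frac <= 1,
            height >= 64L, width >= 64L, jitter >= 0, jitter <= 0.5,
            nucleus_frac >= 0, nucleus_frac <= 1)
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_seeds = as.integer(n_seeds),
                 boundary_width = boundary_width,
                 noise_level = noise_level,
                 weak_boundary_frac = weak_boundary_frac,
                 rng_seed = as.integer(rng_seed),
                 px_scale_um = px_scale_um, jitter = jitter,
                 nucleus_frac = nucleus_frac),
            class = "synthetic_spec")
}

# base palette, in [0,1] RGB (plausible H&E rendering, not data-derived)
SYNTH_COLOURS <- list(
  interior = c(0.93, 0.70, 0.78),
  boundary = c(0.96, 0.93, 0.95),
  nucleus  = c(0.35, 0.25, 0.55)
)

# multiplicative speckle amplitude by severity
NOISE_AMPLITUDE <- c(low = 0.05, medium = 0.12, high = 0.22)

#' Generate a synthetic H&E muscle image with exact ground truth
#'
#' Seed points are laid on a jittered grid and the canvas is partitioned by
#' nearest-seed (Voronoi) assignment. Pixels whose distance to the Voronoi
#' edge, `(d2 - d1) / 2`, is below half the boundary width form the pale
#' endomysium band (label 0); the remaining cell interiors are the fibres,
#' labelled consecutively. Interiors get the eosin-pink base colour with a
#' per-fibre shade factor and a smooth large-scale stain field; a random
#' subset of fibres receives one dark peripheral nucleus (inside the fibre,
#' so ground truth is unchanged). Boundary weakening and speckle noise are
#' then applied per the spec. The whole construction runs under the spec's
#' RNG seed, so repeated calls are bit-identical.
#'
#' @param spec a [synthetic_spec].
#' @return list with `image` ([rgb_image]), `labels` ([label_mask], exact
#'   ground truth; attribute `"boundary_pairs"` codes the two fibres
#'   adjacent to each boundary pixel for [weaken_boundaries]), `clean`
#'   (the noise-free [rgb_image]) and `spec`.
#' @examples
#' gen <- generate_muscle_image(synthetic_spec(height = 128, width = 128,
#'                                             n_seeds = 4))
#' max(gen$labels)
#' @export
generate_muscle_image <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  H <- spec$height; W <- spec$width; n <- spec$n_seeds
  if ((H * W) / n < 2 * 750)
    stop("too many seeds for the canvas: expected cell area below 2 x 750 px")

  withr::with_seed(spec$rng_seed, {
    # jittered-grid seed points
    gy <- max(1L, round(sqrt(n * H / W)))
    gx <- ceiling(n / gy)
    sy0 <- rep((seq_len(gy) - 0.5) * H / gy, times = gx)[seq_len(n)]
    sx0 <- rep((seq_len(gx) - 0.5) * W / gx, each = gy)[seq_len(n)]
    sy <- sy0 + runif(n, -spec$jitter, spec$jitter) * H / gy
    sx <- sx0 + runif(n, -spec$jitter, spec$jitter) * W / gx

    # two nearest seeds per pixel
    Y <- matrix(seq_len(H), H, W)
    X <- matrix(seq_len(W), H, W, byrow = TRUE)
    d1 <- matrix(Inf, H, W); d2 <- matrix(Inf, H, W)
    i1 <- matrix(0L, H, W);  i2 <- matrix(0L, H, W)
    for (k in seq_len(n)) {
      dk <- (Y - sy[k])^2 + (X - sx[k])^2
      closer <- dk < d1
      second <- !closer & dk < d2
      d2[closer] <- d1[closer]; i2[closer] <- i1[closer]
      d1[closer] <- dk[closer]; i1[closer] <- k
      d2[second] <- dk[second]; i2[second] <- k
    }
    d1 <- sqrt(d1); d2 <- sqrt(d2)

    interior <- (d2 - d1) / 2 >= spec$boundary_width / 2
    lab <- matrix(0L, H, W)
    lab[interior] <- i1[interior]
    lab <- renumber_labels(lab)

    # paint: boundary base, interiors with per-fibre shade + smooth field
    n_fib <- max(lab)
    shade <- 1 + rnorm(n, 0, 0.04)
    field <- smooth_field(H, W, scale = min(H, W) / 4, amp = 0.03)
    img <- array(0, c(H, W, 3))
    bcol <- SYNTH_COLOURS$boundary
    icol <- SYNTH_COLOURS$interior
    mult <- matrix(1, H, W)
    mult[interior] <- shade[i1[interior]]
    mult <- mult * (1 + field)
    for (k in 1:3) {
      plane <- matrix(bcol[k], H, W)
      plane[interior] <- icol[k]
      img[, , k] <- plane * mult
    }

    # peripheral nuclei: one small dark ellipse per selected fibre, placed
    # just inside the fibre edge; labels are untouched (nuclei lie within
    # the fibre)
    with_nucleus <- which(runif(n_fib) < spec$nucleus_frac)
    edge_dist <- (d2 - d1) / 2
    for (f in with_nucleus) {
      cand <- which(lab == f & edge_dist < spec$boundary_width / 2 + 3)
      if (!length(cand)) next
      ctr <- cand[sample.int(length(cand), 1L)]
      cy <- (ctr - 1L) %% H + 1L
      cx <- (ctr - 1L) %/% H + 1L
      rA <- runif(1, 2.5, 4); rB <- runif(1, 1.8, 2.8)
      th <- runif(1, 0, pi)
      win <- 5L
      ys <- max(1L, cy - win):min(H, cy + win)
      xs <- max(1L, cx - win):min(W, cx + win)
      dy <- outer(ys - cy, rep(1, length(xs)))
      dx <- outer(rep(1, length(ys)), xs - cx)
      u <- dy * cos(th) + dx * sin(th)
      v <- -dy * sin(th) + dx * cos(th)
      inside <- (u / rA)^2 + (v / rB)^2 <= 1 & lab[ys, xs] == f
      for (k in 1:3) {
        plane <- img[ys, xs, k]
        plane[inside] <- SYNTH_COLOURS$nucleus[k]
        img[ys, xs, k] <- plane
      }
    }

    labels <- label_mask(lab, px_scale_um = spec$px_scale_um)
    pair_code <- matrix(NA_integer_, H, W)
    bnd <- !interior
    pair_code[bnd] <- pmin(i1[bnd], i2[bnd]) * (n + 1L) + pmax(i1[bnd], i2[bnd])
    attr(labels, "boundary_pairs") <- pair_code
    attr(labels, "interior_colour") <- icol

    clean <- rgb_image(pmin(pmax(img, 0), 1), px_scale_um = spec$px_scale_um)
    out <- clean
    if (spec$weak_boundary_frac > 0)
      out <- weaken_boundaries(out, labels, spec$weak_boundary_frac)
    out <- add_noise(out, spec$noise_level)
    list(image = out, labels = labels, clean = clean, spec = spec)
  })
}

# smooth zero-mean random field: coarse gaussian noise upsampled by smoothing
smooth_field <- function(H, W, scale, amp) {
  z <- matrix(rnorm(H * W), H, W)
  f <- as_plain(gaussian_smooth(z, std = scale / 4))
  s <- sd(f)
  if (s < 1e-12) return(matrix(0, H, W))
  amp * (f - mean(f)) / s
}

#' Add intra-fibre speckle and stain-variation noise
#'
#' Multiplies the image by a smooth zero-mean speckle field (mimicking
#' myofibril texture) whose amplitude grows with severity
#' (low 0.05, medium 0.12, high 0.22), and applies a mild random per-channel
#' tint (global stain variation). Uses the current RNG state; wrap in a seed
#' for reproducibility. Ground-truth masks are never altered.
#'
#' @param img an [rgb_image].
#' @param level `"low"`, `"medium"` or `"high"`.
#' @return A noisy [rgb_image] clipped to `[0, 1]`.
#' @export
add_noise <- function(img, level = c("low", "medium", "high")) {
  level <- match.arg(level)
  amp <- NOISE_AMPLITUDE[[level]]
  px <- as_plain_rgb(img)
  H <- dim(px)[1]; W <- dim(px)[2]
  speck <- smooth_field(H, W, scale = 8, amp = amp)
  tint <- 1 + rnorm(3, 0, amp / 4)
  out <- array(0, dim(px))
  for (k in 1:3) out[, , k] <- px[, , k] * (1 + speck) * tint[k]
  rgb_image(pmin(pmax(out, 0), 1), px_scale_um = px_scale(img))
}

#' Weaken a random fraction of inter-fibre boundary segments
#'
#' A boundary segment is the set of endomysium pixels shared by one pair of
#' adjacent fibres (identified from the generator's geometry, carried on the
#' label mask as attribute `"boundary_pairs"`). For a sampled fraction of
#' segments the boundary colour is blended toward the fibre interior colour
#' by a factor drawn uniformly from 60-90%, emulating the weak, barely
#' stained endomysium that defeats boundary-based segmentation. Ground truth
#' is unchanged. Uses the current RNG state.
#'
#' @param img an [rgb_image] produced by [generate_muscle_image].
#' @param labels the matching [label_mask] (must carry `"boundary_pairs"`).
#' @param frac fraction of segments to attenuate, in `[0, 1]`.
#' @return An [rgb_image].
#' @export
weaken_boundaries <- function(img, labels, frac) {
  stopifnot(frac >= 0, frac <= 1)
  if (frac == 0) return(img)
  pairs <- attr(labels, "boundary_pairs")
  if (is.null(pairs))
    stop("labels lack the generator's boundary_pairs attribute")
  segs <- sort(unique(pairs[!is.na(pairs)]))
  n_pick <- round(frac * length(segs))
  if (n_pick == 0L) return(img)
  picked <- if (n_pick >= length(segs)) segs
            else segs[sample.int(length(segs), n_pick)]
  sel <- !is.na(pairs) & (pairs %in% picked)
  px <- as_plain_rgb(img)
  icol <- attr(labels, "interior_colour")
  if (is.null(icol)) icol <- SYNTH_COLOURS$interior
  w <- matrix(0, nrow(pairs), ncol(pairs))
  w[sel] <- runif(sum(sel), 0.6, 0.9)
  for (k in 1:3) px[, , k] <- px[, , k] + w * (icol[k] - px[, , k])
  rgb_image(pmin(pmax(px, 0), 1), px_scale_um = px_scale(img))
}
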