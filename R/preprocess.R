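#' Optical-density transform of an RGB image
#'
#' Stain mixing is linear in optical density (Beer-Lambert), so unmixing is
#' performed on `OD = -log((I + eps) / (1 + eps))` with `eps = 1/255` guarding
#' against `log(0)`; negative values (numerically possible at `I = 1`) are
#' clamped to zero.
#'
#' @param rgb an [rgb_image].
#' @return `H x W x 3` array of non-negative optical densities.
#' @keywords internal
od_transform <- function(rgb) {
  eps <- 1 / 255
  od <- -log((as_plain_rgb(rgb) + eps) / (1 + eps))
  pmax(od, 0)
}

#' Rank-2 non-negative matrix factorisation by multiplicative updates
#'
#' Frobenius-objective NMF with Lee-Seung multiplicative updates and a seeded
#' uniform initialisation, used to unmix the two H&E stains. Convergence is
#' declared when the relative objective decrease over 10 iterations falls
#' below `tol`.
#'
#' @param V non-negative `n x m` matrix (rows = pixels, columns = channels).
#' @param rank factorisation rank (2 for H&E).
#' @param seed RNG seed for the initialisation.
#' @param max_iter iteration cap.
#' @param tol relative-decrease convergence tolerance.
#' @return list with `W` (`n x rank`), `H` (`rank x m`), `iterations`,
#'   `converged`.
#' @keywords internal
nmf_multiplicative <- function(V, rank = 2L, seed = 101L, max_iter = 1000L,
                               tol = 1e-4) {
  stopifnot(all(V >= 0))
  n <- nrow(V); m <- ncol(V)
  eps <- .Machine$double.eps
  init <- withr::with_seed(seed, {
    list(W = matrix(runif(n * rank, 0.1, 1), n, rank),
         H = matrix(runif(rank * m, 0.1, 1), rank, m))
  })
  W <- init$W; H <- init$H
  v_norm <- sum(V^2)
  obj_old <- Inf
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    H <- H * (crossprod(W, V)) / (crossprod(W) %*% H + eps)
    W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
    if (it %% 10L == 0L || it == max_iter) {
      obj <- sum((V - W %*% H)^2)
      # stop on a relative plateau, or on a near-exact fit (exactly low-rank
      # input decays geometrically and never plateaus in relative terms)
      if (obj <= 1e-6 * v_norm ||
          (is.finite(obj_old) && (obj_old - obj) <= tol * max(obj, eps))) {
        converged <- TRUE
        break
      }
      obj_old <- obj
    }
  }
  list(W = W, H = H, iterations = it, converged = converged)
}

# reference eosin direction in OD space, used to label the two NMF factors
EOSIN_REF_OD <- c(0.07, 0.99, 0.11) / sqrt(sum(c(0.07, 0.99, 0.11)^2))

#' Unmix H&E stains by non-negative matrix factorisation
#'
#' Factorises the optical-density image into two non-negative stain density
#' maps and a 2 x 3 stain colour basis. The factor whose (unit-normalised)
#' colour vector has the larger cosine similarity to a fixed reference eosin
#' OD direction is labelled eosin; the other haematoxylin. Basis rows are
#' normalised to unit Euclidean norm with the scale absorbed into the density
#' maps, so densities are reproducible up to that convention.
#'
#' @param rgb an [rgb_image].
#' @param rank factorisation rank (default 2, one factor per stain).
#' @param seed NMF initialisation seed.
#' @param max_iter,tol NMF iteration cap and convergence tolerance.
#' @return list of class `stain_pair`: `eosin` and `haematoxylin`
#'   ([gray_image]-shaped density matrices, unbounded above), `basis`
#'   (2 x 3, rows eosin / haematoxylin, unit norm), `nmf_iterations`.
#' @examples
#' img <- generate_muscle_image(synthetic_spec(n_seeds = 9, height = 160,
#'                                             width = 160))$image
#' sp <- decompose_stains(img)
#' range(sp$eosin)
#' @export
decompose_stains <- function(rgb, rank = 2L, seed = 101L, max_iter = 1000L,
                             tol = 1e-4) {
  od <- od_transform(rgb)
  d <- dim(od)
  V <- matrix(od, d[1] * d[2], 3L)
  if (max(V) < 1e-6)
    stop("degenerate input: zero optical density everywhere (all-white image)")
  fit <- nmf_multiplicative(V, rank = rank, seed = seed, max_iter = max_iter,
                            tol = tol)
  if (!fit$converged)
    stop(sprintf("NMF did not converge within %d iterations", fit$iterations))
  H <- fit$H; W <- fit$W
  nrm <- sqrt(rowSums(H^2))
  nrm[nrm == 0] <- 1
  H <- H / nrm
  W <- sweep(W, 2L, nrm, `*`)
  cossim <- as.numeric(H %*% EOSIN_REF_OD)  # rows already unit norm
  eo <- which.max(cossim)
  ha <- if (eo == 1L) 2L else 1L
  # single-stain degenerate case: when the two colour vectors are nearly
  # collinear the factorisation is effectively rank 1; pool the density into
  # the matched factor and zero the other
  if (abs(sum(H[eo, ] * H[ha, ])) > 0.999) {
    W[, eo] <- W[, eo] + W[, ha]
    W[, ha] <- 0
  }
  dens <- function(k) {
    m <- matrix(pmax(W[, k], 0), d[1], d[2])
    structure(m, px_scale_um = px_scale(rgb),
              class = c("gray_image", "matrix", "array"))
  }
  structure(
    list(eosin = dens(eo), haematoxylin = dens(ha),
         basis = H[c(eo, ha), , drop = FALSE],
         nmf_iterations = fit$iterations),
    class = "stain_pair"
  )
}

#' @export
print.stain_pair <- function(x, ...) {
  cat(sprintf("<stain_pair> eosin density max %.3f, haematoxylin max %.3f (%d NMF iterations)\n",
              max(x$eosin), max(x$haematoxylin), x$nmf_iterations))
  invisible(x)
}

#' Render a stain density map back to an RGB intensity image
#'
#' Inverts Beer-Lambert for a single stain: `I_c = exp(-density * basis_c)`.
#' High stain density maps to dark pixels, so eosin-rich fibre interiors come
#' out dark and pale endomysial boundaries light.
#'
#' @param density density matrix (e.g. `stain_pair$eosin`).
#' @param basis_row length-3 unit stain OD colour vector.
#' @return An [rgb_image].
#' @export
render_stain <- function(density, basis_row) {
  d <- dim(density)
  out <- array(0, c(d, 3L))
  for (k in 1:3) out[, , k] <- exp(-as_plain(density) * basis_row[k])
  rgb_image(pmin(pmax(out, 0), 1), px_scale_um = px_scale(density))
}

#' Convert an RGB image to grayscale
#'
#' Rec. 601 luminance: `0.299 R + 0.587 G + 0.114 B`.
#'
#' @param img an [rgb_image] (or H x W x 3 array).
#' @return A [gray_image].
#' @export
to_grayscale <- function(img) {
  px <- as_plain_rgb(img)
  g <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
  gray_image(pmin(pmax(g, 0), 1), px_scale_um = px_scale(img))
}

#' Contrast-limited adaptive histogram equalisation (CLAHE)
#'
#' Zuiderveld's CLAHE: the image is divided into a grid of tiles, each tile's
#' histogram is clipped at `clip_limit` times the tile pixel count (excess
#' redistributed uniformly) and turned into an equalisation mapping; each
#' pixel is remapped by bilinear interpolation between the four surrounding
#' tile mappings. Histograms are binned over the image's own intensity range,
#' so low-contrast inputs are expanded to span `[0, 1]`. A constant image is
#' returned unchanged (there is no contrast to redistribute).
#'
#' @param gray a [gray_image].
#' @param tile_grid integer 2-vector, tiles along (rows, cols); default 8 x 8.
#' @param clip_limit histogram clip limit as a fraction of tile pixels.
#' @param nbins histogram bins.
#' @return A [gray_image] in `[0, 1]`.
#' @export
enhance_contrast <- function(gray, tile_grid = c(8L, 8L), clip_limit = 0.01,
                             nbins = 256L) {
  u <- as_plain(gray)
  H <- nrow(u); W <- ncol(u)
  ty <- as.integer(tile_grid[1]); tx <- as.integer(tile_grid[2])
  if (ty < 1L || tx < 1L) stop("tile_grid entries must be >= 1")
  if (ty > H || tx > W)
    stop("tile grid larger than image: each tile must contain pixels")
  mn <- min(u); mx <- max(u)
  if (mx - mn < 1e-12) return(gray)  # constant input

  bin <- pmin(as.integer(floor((u - mn) / (mx - mn) * nbins)) + 1L, nbins)
  dim(bin) <- dim(u)
  row_tile <- pmin(as.integer(floor((seq_len(H) - 0.5) / H * ty)) + 1L, ty)
  col_tile <- pmin(as.integer(floor((seq_len(W) - 0.5) / W * tx)) + 1L, tx)

  # per-tile clipped, redistributed equalisation mappings
  maps <- array(0, c(ty, tx, nbins))
  for (i in seq_len(ty)) {
    for (j in seq_len(tx)) {
      sel <- bin[row_tile == i, col_tile == j]
      n <- length(sel)
      h <- tabulate(sel, nbins)
      clip <- max(1, ceiling(clip_limit * n))
      excess <- sum(pmax(h - clip, 0))
      h <- pmin(h, clip) + excess / nbins
      maps[i, j, ] <- cumsum(h) / sum(h)
    }
  }

  # bilinear interpolation between tile-centre mappings
  centre_y <- (seq_len(ty) - 0.5) * H / ty
  centre_x <- (seq_len(tx) - 0.5) * W / tx
  pos_y <- interp_pos(seq_len(H) - 0.5, centre_y)
  pos_x <- interp_pos(seq_len(W) - 0.5, centre_x)

  i0 <- matrix(pos_y$lo, H, W);  i1 <- matrix(pos_y$hi, H, W)
  wy <- matrix(pos_y$w,  H, W)
  j0 <- matrix(pos_x$lo, H, W, byrow = TRUE)
  j1 <- matrix(pos_x$hi, H, W, byrow = TRUE)
  wx <- matrix(pos_x$w,  H, W, byrow = TRUE)

  lookup <- function(i, j) maps[cbind(as.vector(i), as.vector(j), as.vector(bin))]
  out <- (1 - wy) * (1 - wx) * lookup(i0, j0) +
         (1 - wy) * wx       * lookup(i0, j1) +
         wy       * (1 - wx) * lookup(i1, j0) +
         wy       * wx       * lookup(i1, j1)
  gray_image(matrix(pmin(pmax(out, 0), 1), H, W), px_scale_um = px_scale(gray))
}

# For query coordinates q and sorted tile centres, return bracketing tile
# indices and the interpolation weight toward the upper tile (clamped at the
# image border).
interp_pos <- function(q, centres) {
  k <- length(centres)
  hi <- findInterval(q, centres) + 1L
  lo <- hi - 1L
  lo <- pmin(pmax(lo, 1L), k)
  hi <- pmin(pmax(hi, 1L), k)
  w <- ifelse(hi == lo, 0,
              (q - centres[lo]) / (centres[hi] - centres[lo]))
  list(lo = lo, hi = hi, w = pmin(pmax(w, 0), 1))
}

#' Pre-process an H&E image into a boundary-bright grayscale image
#'
#' Composition of the pre-processing chain: stain unmixing
#' ([decompose_stains]), rendering of the eosin channel ([render_stain]),
#' grayscale conversion ([to_grayscale]) and contrast-limited adaptive
#' histogram equalisation ([enhance_contrast]). The output convention is that
#' lighter pixels are endomysial/perimysial boundaries and darker pixels are
#' fibre interiors, the polarity the diffusion filter expects.
#'
#' @param rgb an [rgb_image].
#' @param cfg a pipeline configuration, see [default_config()]; only the
#'   `preprocess` section is used.
#' @return A [gray_image] in `[0, 1]`.
#' @export
preprocess <- function(rgb, cfg = default_config()) {
  pc <- cfg$preprocess
  sp <- decompose_stains(rgb, seed = pc$nmf_seed, max_iter = pc$nmf_max_iter,
                         tol = pc$nmf_tol)
  eo <- render_stain(sp$eosin, sp$basis[1, ])
  g <- to_grayscale(eo)
  enhance_contrast(g, tile_grid = pc$clahe_tiles, clip_limit = pc$clahe_clip,
                   nbins = pc$clahe_bins)
}
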