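#' 8-connected component labelling
#'
#' Labels the TRUE pixels of a mask with consecutive integers from 1 in
#' raster order of first encounter (deterministic).
#'
#' @param mask logical matrix or [binary_mask].
#' @return Integer matrix of labels (0 = background).
#' @export
label_components <- function(mask) {
  m <- as_plain(mask)
  storage.mode(m) <- "logical"
  .label8_cpp(m)
}

#' Otsu threshold of a gray image
#'
#' Exhaustive search over a 256-bin histogram for the threshold maximising
#' the between-class variance. The mask is TRUE where intensity exceeds the
#' threshold; for a diffusion-filtered muscle image the bright class is the
#' connective-tissue boundary.
#'
#' @param gray a [gray_image] with at least two distinct values.
#' @param nbins histogram bins (default 256).
#' @return list with `threshold` (upper edge of the chosen bin, in `[0, 1]`)
#'   and `mask` (a boundary-semantics [binary_mask]).
#' @export
otsu_threshold <- function(gray, nbins = 256L) {
  u <- as_plain(gray)
  if (max(u) - min(u) < 1e-12)
    stop("degenerate histogram: constant image has no threshold")
  bin <- pmin(as.integer(floor(u * nbins)) + 1L, nbins)
  h <- tabulate(bin, nbins)
  p <- h / sum(h)
  mids <- (seq_len(nbins) - 0.5) / nbins
  w0 <- cumsum(p)
  m0 <- cumsum(p * mids)
  mt <- m0[nbins]
  # between-class variance for threshold after bin t (t = 1..nbins-1)
  t_range <- seq_len(nbins - 1L)
  w0t <- w0[t_range]
  valid <- w0t > 0 & w0t < 1
  bcv <- rep(-Inf, nbins - 1L)
  bcv[valid] <- (mt * w0t[valid] - m0[t_range][valid])^2 /
    (w0t[valid] * (1 - w0t[valid]))
  # empty bins give exactly flat plateaus of the criterion; take the lowest
  # threshold on the plateau (round-off guarded) so ties break deterministically
  t_star <- which(bcv >= max(bcv) - 1e-12)[1]
  thr <- t_star / nbins
  list(threshold = thr,
       mask = binary_mask(u > thr, semantics = "boundary"))
}

#' Remove small connected components from a mask
#'
#' Every 8-connected TRUE component with area strictly below `t_area` pixels
#' is removed; components of exactly `t_area` pixels survive.
#'
#' @param mask a [binary_mask].
#' @param t_area minimum area in pixels (default 750).
#' @return A [binary_mask] with the same semantics.
#' @export
remove_small_components <- function(mask, t_area = 750L) {
  lab <- label_components(mask)
  if (max(lab) == 0L) return(mask)
  areas <- tabulate(lab[lab > 0L], max(lab))
  keep <- areas >= t_area
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  out[lab > 0L] <- keep[lab[lab > 0L]]
  binary_mask(out, semantics = attr(mask, "semantics"))
}

disc_brush <- function(radius) {
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

#' Morphological closing of the boundary mask
#'
#' Closing (dilation then erosion) with a discrete disk, joining
#' disconnected boundary segments whose gap is smaller than the disk.
#' Closing is extensive (output contains the input) and idempotent.
#'
#' @param mask a [binary_mask].
#' @param radius disk radius in px (default 4).
#' @return A [binary_mask] with the same semantics.
#' @export
close_boundaries <- function(mask, radius = 4L) {
  m <- as_plain(mask) * 1
  cl <- EBImage::closing(m, disc_brush(radius))
  out <- matrix(as.vector(cl) > 0.5, nrow(mask), ncol(mask))
  binary_mask(out | as_plain(mask), semantics = attr(mask, "semantics"))
}

#' Complement a boundary mask into a fibre mask
#'
#' @param mask a boundary-semantics [binary_mask].
#' @return The logical complement as a fibre-semantics [binary_mask] (and
#'   vice versa for a fibre-semantics input).
#' @export
fibres_from_boundaries <- function(mask) {
  sem <- attr(mask, "semantics")
  binary_mask(!as_plain(mask),
              semantics = if (identical(sem, "boundary")) "fibre" else "boundary")
}

#' Split touching fibres by a marker-controlled watershed
#'
#' Markers are the connected components of the fibre mask eroded by a
#' discrete disk of `erosion_radius`; any fibre component that vanishes
#' entirely under erosion instead receives a single-pixel marker at the
#' maximum of its Euclidean distance transform (ties broken in row-major
#' order), so thin fibres are not lost. The watershed floods the negated
#' Euclidean distance transform of the fibre mask, restricted to the mask,
#' from those markers; every fibre pixel receives a label and each marker
#' yields exactly one region.
#'
#' @param fibres a fibre-semantics [binary_mask].
#' @param erosion_radius erosion disk radius in px (default 10).
#' @param px_scale_um micrometres per pixel for the output labels.
#' @return A [label_mask].
#' @export
split_touching_fibres <- function(fibres, erosion_radius = 10L,
                                  px_scale_um = 0.899) {
  m <- as_plain(fibres)
  storage.mode(m) <- "logical"
  if (!any(m))
    return(label_mask(matrix(0L, nrow(m), ncol(m)), px_scale_um = px_scale_um))

  er <- EBImage::erode(m * 1, disc_brush(erosion_radius))
  eroded <- matrix(as.vector(er) > 0.5, nrow(m), ncol(m)) & m
  markers <- label_components(eroded)

  edt <- as_edt(m)

  # fallback markers for components erased by the erosion
  comp <- label_components(m)
  n_comp <- max(comp)
  if (n_comp > 0L) {
    has_marker <- logical(n_comp)
    sel <- markers > 0L
    has_marker[unique(comp[sel])] <- TRUE
    next_id <- max(markers)
    for (k in which(!has_marker)) {
      in_comp <- comp == k
      best <- max(edt[in_comp])
      cand <- which(in_comp & edt == best)
      # row-major tie-break: smallest row, then smallest column
      rr <- (cand - 1L) %% nrow(m) + 1L
      cc <- (cand - 1L) %/% nrow(m) + 1L
      pick <- cand[order(rr, cc)][1L]
      next_id <- next_id + 1L
      markers[pick] <- next_id
    }
  }

  lab <- .marker_watershed_cpp(-edt, markers, m)
  label_mask(renumber_labels(lab), px_scale_um = px_scale_um)
}

as_edt <- function(mask_logical) {
  d <- EBImage::distmap(mask_logical * 1, metric = "euclidean")
  matrix(as.vector(d), nrow(mask_logical), ncol(mask_logical))
}

# renumber positive labels consecutively from 1, preserving ascending order
renumber_labels <- function(lab) {
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids) == 0L) return(lab)
  map <- integer(max(ids))
  map[ids] <- seq_along(ids)
  out <- lab
  out[lab > 0L] <- map[lab[lab > 0L]]
  out
}

#' Remove fibres touching the image border
#'
#' Any label with a pixel on the first/last row or column is cleared;
#' surviving labels are renumbered consecutively. Fibres clipped by the
#' region-of-interest boundary cannot be measured reliably, so they are
#' excluded before morphometry.
#'
#' @param labels a [label_mask].
#' @return A [label_mask].
#' @export
remove_border_fibres <- function(labels) {
  lab <- as_plain(labels)
  storage.mode(lab) <- "integer"
  border_ids <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border_ids <- border_ids[border_ids > 0L]
  if (length(border_ids)) lab[lab %in% border_ids] <- 0L
  label_mask(renumber_labels(lab), px_scale_um = px_scale(labels))
}

# drop labels below an area threshold, renumbering the survivors
filter_small_labels <- function(labels, t_area) {
  lab <- as_plain(labels)
  storage.mode(lab) <- "integer"
  if (max(lab) == 0L) return(labels)
  areas <- tabulate(lab[lab > 0L], max(lab))
  drop <- which(areas < t_area)
  if (length(drop)) lab[lab %in% drop] <- 0L
  label_mask(renumber_labels(lab), px_scale_um = px_scale(labels))
}

#' Segment myofibres in an H&E image
#'
#' The full pipeline: [preprocess] (stain unmixing, eosin rendering,
#' grayscale, CLAHE), [ced] (coherence-enhancing diffusion), Otsu
#' thresholding of the boundary probability map, removal of small boundary
#' components, morphological closing, complement to fibre regions,
#' marker-controlled watershed splitting, removal of small final regions and
#' of border-touching fibres.
#'
#' @param rgb an [rgb_image].
#' @param cfg pipeline configuration, see [default_config()].
#' @param keep_intermediates if TRUE, attach the eight stage images
#'   (attribute `"intermediates"`, named A-H: input, eosin render, equalised
#'   gray, diffusion output, Otsu mask, cleaned+closed boundaries, fibre
#'   mask, watershed labels).
#' @param quiet suppress per-stage progress messages.
#' @return A [label_mask]; attribute `"stages"` carries per-stage region
#'   counts.
#' @examples
#' gen <- generate_muscle_image(synthetic_spec(height = 192, width = 192,
#'                                             n_seeds = 6, rng_seed = 7))
#' seg <- segment(gen$image, quiet = TRUE)
#' @export
segment <- function(rgb, cfg = default_config(), keep_intermediates = FALSE,
                    quiet = FALSE) {
  cfg <- validate_config(cfg)
  note <- function(...) if (!quiet) message(sprintf(...))
  scale <- px_scale(rgb, default = cfg$image$px_scale_um)

  pc <- cfg$preprocess
  sp <- decompose_stains(rgb, seed = pc$nmf_seed, max_iter = pc$nmf_max_iter,
                         tol = pc$nmf_tol)
  eosin_img <- render_stain(sp$eosin, sp$basis[1, ])
  g <- enhance_contrast(to_grayscale(eosin_img), tile_grid = pc$clahe_tiles,
                        clip_limit = pc$clahe_clip, nbins = pc$clahe_bins)
  note("preprocess: NMF converged in %d iterations", sp$nmf_iterations)

  dp <- diffusion_params(tau = cfg$ced$tau, sigma = cfg$ced$sigma,
                         rho = cfg$ced$rho, c1 = cfg$ced$c1, c2 = cfg$ced$c2,
                         n_steps = cfg$ced$n_steps,
                         stable_tau = cfg$ced$stable_tau)
  u <- ced(g, dp)
  note("ced: %d steps at tau = %g", dp$n_steps, dp$tau)

  ot <- otsu_threshold(u)
  note("otsu: threshold %.4f, %d boundary px", ot$threshold, sum(ot$mask))

  pp <- cfg$postprocess
  bnd <- remove_small_components(ot$mask, pp$t_area)
  bnd <- close_boundaries(bnd, pp$closing_radius)
  fib <- fibres_from_boundaries(bnd)
  labels <- split_touching_fibres(fib, pp$erosion_radius, px_scale_um = scale)
  n_ws <- n_labels(labels)
  labels <- filter_small_labels(labels, pp$t_area)
  n_area <- n_labels(labels)
  labels <- remove_border_fibres(labels)
  n_final <- n_labels(labels)
  note("postprocess: %d watershed regions -> %d after area filter -> %d interior fibres",
       n_ws, n_area, n_final)

  attr(labels, "stages") <- c(watershed = n_ws, area_filtered = n_area,
                              final = n_final)
  if (keep_intermediates) {
    attr(labels, "intermediates") <- list(
      A_input = rgb, B_eosin = eosin_img, C_equalised = g, D_ced = u,
      E_otsu = ot$mask, F_boundaries = bnd, G_fibres = fib,
      H_labels = label_mask(as_plain(labels), px_scale_um = scale)
    )
  }
  labels
}
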