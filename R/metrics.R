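#' One-to-one matching of predicted and ground-truth fibre regions
#'
#' A predicted region is a candidate for a ground-truth fibre when at least
#' `encompass_frac` of the predicted region's area lies inside that fibre.
#' Candidates are assigned greedily, largest intersection first (ties:
#' smaller predicted id, then smaller ground-truth id), enforcing a
#' one-to-one mapping. Remaining predicted regions are false positives and
#' remaining ground-truth fibres false negatives.
#'
#' @param pred,gt [label_mask]s of the same shape.
#' @param encompass_frac minimum fraction of the predicted region inside the
#'   ground-truth region (default 0.5).
#' @return list of class `region_matching`: `pairs` (tibble with `gt`,
#'   `pred`, `intersection`), `unmatched_gt`, `unmatched_pred`.
#' @export
match_regions <- function(pred, gt, encompass_frac = 0.5) {
  if (!all(dim(pred) == dim(gt))) stop("pred and gt must share the same shape")
  p <- as.integer(as_plain(pred))
  g <- as.integer(as_plain(gt))
  np <- max(p, 0L); ng <- max(g, 0L)
  pred_area <- tabulate(p[p > 0L], np)

  both <- p > 0L & g > 0L
  if (any(both)) {
    key <- (as.numeric(p[both]) - 1) * ng + as.numeric(g[both])
    tab <- table(key)
    kv <- as.numeric(names(tab))
    cand <- data.frame(
      pred = as.integer((kv - 1) %/% ng + 1),
      gt = as.integer((kv - 1) %% ng + 1),
      intersection = as.integer(tab)
    )
    cand <- cand[cand$intersection >= encompass_frac * pred_area[cand$pred], ,
                 drop = FALSE]
    cand <- cand[order(-cand$intersection, cand$pred, cand$gt), , drop = FALSE]
  } else {
    cand <- data.frame(pred = integer(), gt = integer(),
                       intersection = integer())
  }

  used_p <- logical(np); used_g <- logical(ng)
  take <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!used_p[cand$pred[i]] && !used_g[cand$gt[i]]) {
      take[i] <- TRUE
      used_p[cand$pred[i]] <- TRUE
      used_g[cand$gt[i]] <- TRUE
    }
  }
  pairs <- cand[take, c("gt", "pred", "intersection"), drop = FALSE]
  structure(list(
    pairs = tibble::as_tibble(pairs),
    unmatched_gt = which(!used_g),
    unmatched_pred = which(!used_p)
  ), class = "region_matching")
}

#' @export
print.region_matching <- function(x, ...) {
  cat(sprintf("<region_matching> %d pairs, %d unmatched gt, %d unmatched pred\n",
              nrow(x$pairs), length(x$unmatched_gt), length(x$unmatched_pred)))
  invisible(x)
}

#' Fibre-level segmentation accuracy
#'
#' `TP / (TP + FP + FN)` over the one-to-one matching: matched pairs are
#' true positives, unmatched predicted regions false positives, unmatched
#' ground-truth fibres false negatives.
#'
#' @param m a `region_matching` from [match_regions].
#' @return Accuracy in `[0, 1]`.
#' @export
fibre_accuracy <- function(m) {
  tp <- nrow(m$pairs)
  fp <- length(m$unmatched_pred)
  fn <- length(m$unmatched_gt)
  if (tp + fp + fn == 0L)
    stop("accuracy undefined: no regions in prediction or ground truth")
  tp / (tp + fp + fn)
}

# bounding box of each positive label: rows r0, r1, c0, c1
label_bboxes <- function(lab) {
  n <- max(lab)
  pos <- which(lab > 0L)
  id <- lab[pos]
  rr <- (pos - 1L) %% nrow(lab) + 1L
  cc <- (pos - 1L) %/% nrow(lab) + 1L
  list(
    r0 = tapply(rr, id, min), r1 = tapply(rr, id, max),
    c0 = tapply(cc, id, min), c1 = tapply(cc, id, max),
    ids = sort(unique(id))
  )
}

count_components_in <- function(mask_logical, min_px) {
  lab <- .label8_cpp(mask_logical)
  if (max(lab) == 0L) return(0L)
  sum(tabulate(lab[lab > 0L], max(lab)) >= min_px)
}

#' Fragmentation: fraction of ground-truth fibres split by the segmentation
#'
#' For each ground-truth fibre, the predicted fibre mask restricted to that
#' fibre is component-labelled (8-connected); the fibre counts as fragmented
#' when more than one component of at least `min_component_px` pixels
#' remains. `F = p / n` over the `n` ground-truth fibres.
#'
#' @param pred_fibre_mask fibre-semantics [binary_mask] (or `pred > 0`).
#' @param gt ground-truth [label_mask] with `n >= 1` fibres.
#' @param min_component_px sliver guard: components smaller than this are
#'   ignored (default 5; watershed ridges can leave 1-px debris).
#' @return Fragmentation in `[0, 1]`.
#' @export
fragmentation <- function(pred_fibre_mask, gt, min_component_px = 5L) {
  if (!all(dim(pred_fibre_mask) == dim(gt))) stop("shape mismatch")
  g <- as_plain(gt); storage.mode(g) <- "integer"
  n <- max(g)
  if (n < 1L) stop("ground truth has no fibres")
  pm <- as_plain(pred_fibre_mask)
  storage.mode(pm) <- "logical"
  bb <- label_bboxes(g)
  p_count <- 0L
  for (k in seq_len(n)) {
    r <- bb$r0[as.character(k)]:bb$r1[as.character(k)]
    cc <- bb$c0[as.character(k)]:bb$c1[as.character(k)]
    sub <- pm[r, cc, drop = FALSE] & (g[r, cc, drop = FALSE] == k)
    if (count_components_in(sub, min_component_px) > 1L) p_count <- p_count + 1L
  }
  p_count / n
}

#' Congealment: fraction of ground-truth fibres merged by the segmentation
#'
#' For each predicted region, the ground-truth foreground restricted to that
#' region is component-labelled (8-connected, ignoring components below
#' `min_component_px`); when more than one component remains, the
#' ground-truth fibres they belong to are congealed. `C = q / n` with `q`
#' the number of distinct congealed fibres.
#'
#' @param pred predicted [label_mask].
#' @param gt ground-truth [label_mask] with `n >= 1` fibres.
#' @param min_component_px sliver guard (default 5).
#' @return Congealment in `[0, 1]`.
#' @export
congealment <- function(pred, gt, min_component_px = 5L) {
  if (!all(dim(pred) == dim(gt))) stop("shape mismatch")
  g <- as_plain(gt); storage.mode(g) <- "integer"
  p <- as_plain(pred); storage.mode(p) <- "integer"
  n <- max(g)
  if (n < 1L) stop("ground truth has no fibres")
  if (max(p) < 1L) return(0)
  bb <- label_bboxes(p)
  congealed <- integer(0)
  for (k in bb$ids) {
    kc <- as.character(k)
    r <- bb$r0[kc]:bb$r1[kc]
    cc <- bb$c0[kc]:bb$c1[kc]
    inside <- p[r, cc, drop = FALSE] == k
    sub <- (g[r, cc, drop = FALSE] > 0L) & inside
    lab <- .label8_cpp(sub)
    if (max(lab) == 0L) next
    areas <- tabulate(lab[lab > 0L], max(lab))
    big <- which(areas >= min_component_px)
    if (length(big) > 1L) {
      gsub <- g[r, cc, drop = FALSE]
      ids <- vapply(big, function(cmp) {
        vals <- gsub[lab == cmp]
        as.integer(vals[vals > 0L][1L])  # component lies within one gt fibre
      }, integer(1))
      congealed <- union(congealed, ids)
    }
  }
  length(congealed) / n
}

#' Pixel misclassification percentage between two binary masks
#'
#' `100 * |pred XOR gt| / (H * W)`: the percentage of pixels labelled fibre
#' in one mask but not the other.
#'
#' @param pred_mask,gt_mask [binary_mask]s (or logical matrices) of the same
#'   shape.
#' @return Percentage in `[0, 100]`.
#' @export
misclassification_percentage <- function(pred_mask, gt_mask) {
  if (!all(dim(pred_mask) == dim(gt_mask))) stop("shape mismatch")
  100 * mean(xor(as_plain(pred_mask) > 0, as_plain(gt_mask) > 0))
}

#' Smoothed CDF of per-image misclassification percentages
#'
#' Gaussian kernel density estimate of the misclassification set `S`,
#' integrated (trapezoid rule) on a uniform grid over `[0, 100]` and
#' normalised so the final value is 1. A better segmentation method has a
#' CDF closer to the unit step at 0. Bandwidth defaults to Silverman's rule
#' of thumb; for a single value or zero spread it falls back to 1 percentage
#' point.
#'
#' @param S numeric vector of per-image misclassification percentages in
#'   `[0, 100]`.
#' @param grid_points evaluation grid size (default 512).
#' @param bandwidth kernel bandwidth override (default `NULL` = Silverman).
#' @return list of class `cdf_estimate` with `grid`, `values`, `bandwidth`.
#' @export
cdf_estimate <- function(S, grid_points = 512L, bandwidth = NULL) {
  if (length(S) < 1L) stop("S must contain at least one value")
  if (any(S < 0 | S > 100)) stop("misclassification percentages must lie in [0, 100]")
  if (is.null(bandwidth)) {
    bandwidth <- if (length(S) >= 2L && sd(S) > 0) bw.nrd0(S) else 1
  }
  d <- density(S, bw = bandwidth, from = 0, to = 100, n = grid_points)
  dx <- diff(d$x)
  inc <- c(0, dx * (utils::head(d$y, -1) + utils::tail(d$y, -1)) / 2)
  cdf <- cumsum(inc)
  total <- cdf[length(cdf)]
  if (total <= 0) stop("degenerate density estimate")
  structure(list(grid = d$x, values = cdf / total, bandwidth = bandwidth),
            class = "cdf_estimate")
}

#' Minor-axis fibre diameters
#'
#' Per fibre, the minor-axis length of the ellipse with the same normalised
#' second central moments as the region — the diameter measure least
#' affected by oblique sectioning or kinking — converted to micrometres.
#'
#' @param labels a [label_mask] with at least one fibre.
#' @return Numeric vector of diameters (um), one per label.
#' @export
fibre_diameters <- function(labels) {
  lab <- as_plain(labels); storage.mode(lab) <- "integer"
  n <- max(lab)
  if (n < 1L) stop("no fibres to measure")
  pos <- which(lab > 0L)
  id <- lab[pos]
  rr <- (pos - 1L) %% nrow(lab) + 1L
  cc <- (pos - 1L) %/% nrow(lab) + 1L
  scale <- px_scale(labels)
  vapply(seq_len(n), function(k) {
    sel <- id == k
    y <- rr[sel]; x <- cc[sel]
    mu20 <- mean((x - mean(x))^2)
    mu02 <- mean((y - mean(y))^2)
    mu11 <- mean((x - mean(x)) * (y - mean(y)))
    lam_min <- (mu20 + mu02) / 2 - sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
    4 * sqrt(max(lam_min, 0)) * scale
  }, numeric(1))
}

#' Variability coefficient of fibre diameters
#'
#' `VC = scale * sd(d) / mean(d)` with the sample (n-1) standard deviation
#' and `scale = 1000`. In transverse muscle biopsies a VC below 250 is the
#' conventional normal range; VC is invariant to rescaling the diameters.
#'
#' @param diameters numeric vector of at least two positive-mean diameters.
#' @param scale multiplier (default 1000, the clinical convention).
#' @return The variability coefficient (>= 0).
#' @export
variability_coefficient <- function(diameters, scale = 1000) {
  if (length(diameters) < 2L)
    stop("variability coefficient needs at least two diameters")
  m <- mean(diameters)
  if (m <= 0) stop("mean diameter must be positive")
  scale * sd(diameters) / m
}

#' Evaluate a segmentation against ground truth
#'
#' Aggregates the region-matching accuracy, fragmentation, congealment,
#' pixel misclassification and morphometry (minor-axis diameters, mean
#' diameter, variability coefficient) for one image.
#'
#' @param pred predicted [label_mask].
#' @param gt ground-truth [label_mask] of the same shape.
#' @param encompass_frac see [match_regions].
#' @param min_component_px see [fragmentation].
#' @return list of class `metrics_report` with fields `n_gt`, `n_pred`,
#'   `tp`, `fp`, `fn`, `accuracy`, `fragmentation`, `congealment`,
#'   `misclassification_pct`, `diameters_um`, `mean_diameter_um`, `vc`
#'   (NA with fewer than two fibres).
#' @examples
#' gt <- label_mask(matrix(rep(c(0L, 1L, 0L, 2L), each = 8), 4, 8))
#' evaluate_segmentation(gt, gt)$accuracy
#' @export
evaluate_segmentation <- function(pred, gt, encompass_frac = 0.5,
                                  min_component_px = 5L) {
  if (!all(dim(pred) == dim(gt))) stop("shape mismatch")
  m <- match_regions(pred, gt, encompass_frac)
  diam <- if (max(pred) >= 1L) fibre_diameters(pred) else numeric(0)
  vc <- if (length(diam) >= 2L && mean(diam) > 0)
    variability_coefficient(diam) else NA_real_
  structure(list(
    n_gt = n_labels(gt), n_pred = n_labels(pred),
    tp = nrow(m$pairs), fp = length(m$unmatched_pred),
    fn = length(m$unmatched_gt),
    accuracy = fibre_accuracy(m),
    fragmentation = fragmentation(binary_mask(as_plain(pred) > 0L, "fibre"),
                                  gt, min_component_px),
    congealment = congealment(pred, gt, min_component_px),
    misclassification_pct = misclassification_percentage(
      as_plain(pred) > 0L, as_plain(gt) > 0L),
    diameters_um = diam,
    mean_diameter_um = if (length(diam)) mean(diam) else NA_real_,
    vc = vc
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> accuracy %.3f (TP %d / FP %d / FN %d), F %.3f, C %.3f\n",
    x$accuracy, x$tp, x$fp, x$fn, x$fragmentation, x$congealment))
  cat(sprintf("  misclassification %.2f%%, mean diameter %.1f um, VC %.1f\n",
              x$misclassification_pct, x$mean_diameter_um, x$vc))
  invisible(x)
}

#' Evaluate a batch of segmentations
#'
#' Per-image reports plus pooled statistics: accuracy from summed
#' TP/FP/FN, fragmentation and congealment pooled over fibres, the
#' misclassification set `S` with its smoothed CDF, pooled diameters and
#' both the pooled VC and the per-image VC mean/sd (the two conventions in
#' use for biopsy morphometry).
#'
#' @param preds,gts lists of [label_mask]s, aligned by position (names are
#'   preserved when given).
#' @param ... passed to [evaluate_segmentation].
#' @return list of class `metrics_batch`: `per_image` (list of
#'   `metrics_report`), `pooled` (named list), `S`, `cdf` (a
#'   `cdf_estimate`).
#' @export
evaluate_batch <- function(preds, gts, ...) {
  stopifnot(length(preds) == length(gts), length(preds) >= 1L)
  reports <- Map(function(p, g) evaluate_segmentation(p, g, ...), preds, gts)
  nm <- names(preds)
  if (is.null(nm)) nm <- sprintf("image_%02d", seq_along(preds))
  names(reports) <- nm

  tp <- sum(vapply(reports, `[[`, 0, "tp"))
  fp <- sum(vapply(reports, `[[`, 0, "fp"))
  fn <- sum(vapply(reports, `[[`, 0, "fn"))
  n_gt <- vapply(reports, `[[`, 0, "n_gt")
  frag_p <- sum(vapply(reports, function(r) r$fragmentation * r$n_gt, 0))
  cong_q <- sum(vapply(reports, function(r) r$congealment * r$n_gt, 0))
  S <- vapply(reports, `[[`, 0, "misclassification_pct")
  diam <- unlist(lapply(reports, `[[`, "diameters_um"), use.names = FALSE)
  vc_img <- vapply(reports, `[[`, 0, "vc")

  pooled <- list(
    accuracy = tp / max(tp + fp + fn, 1L),
    fragmentation = frag_p / sum(n_gt),
    congealment = cong_q / sum(n_gt),
    misclassification_pct_mean = mean(S),
    mean_diameter_um = if (length(diam)) mean(diam) else NA_real_,
    vc_pooled = if (length(diam) >= 2L) variability_coefficient(diam) else NA_real_,
    vc_per_image_mean = mean(vc_img, na.rm = TRUE),
    vc_per_image_sd = if (sum(!is.na(vc_img)) >= 2L) sd(vc_img, na.rm = TRUE)
                      else NA_real_
  )
  structure(list(per_image = reports, pooled = pooled, S = unname(S),
                 cdf = cdf_estimate(unname(S))),
            class = "metrics_batch")
}

#' @export
print.metrics_batch <- function(x, ...) {
  p <- x$pooled
  cat(sprintf("<metrics_batch> %d images | pooled accuracy %.3f, F %.3f, C %.3f\n",
              length(x$per_image), p$accuracy, p$fragmentation, p$congealment))
  cat(sprintf("  mean misclassification %.2f%%, mean diameter %.1f um, VC %.1f (pooled)\n",
              p$misclassification_pct_mean, p$mean_diameter_um, p$vc_pooled))
  invisible(x)
}

#' @rdname evaluate_segmentation
#' @param x a `metrics_report` or `metrics_batch`.
#' @method tidy metrics_report
#' @export
tidy.metrics_report <- function(x, ...) {
  tibble::tibble(
    metric = c("accuracy", "fragmentation", "congealment",
               "misclassification_pct", "mean_diameter_um", "vc"),
    value = c(x$accuracy, x$fragmentation, x$congealment,
              x$misclassification_pct, x$mean_diameter_um, x$vc)
  )
}

#' @rdname evaluate_segmentation
#' @method glance metrics_report
#' @export
glance.metrics_report <- function(x, ...) {
  tibble::tibble(
    n_gt = x$n_gt, n_pred = x$n_pred, tp = x$tp, fp = x$fp, fn = x$fn,
    accuracy = x$accuracy, fragmentation = x$fragmentation,
    congealment = x$congealment,
    misclassification_pct = x$misclassification_pct,
    mean_diameter_um = x$mean_diameter_um, vc = x$vc
  )
}

#' @rdname evaluate_batch
#' @param x a `metrics_batch`.
#' @method tidy metrics_batch
#' @export
tidy.metrics_batch <- function(x, ...) {
  rows <- Map(function(nm, r) cbind(image = nm, glance(r)),
              names(x$per_image), x$per_image)
  tibble::as_tibble(do.call(rbind, rows))
}

#' @rdname evaluate_batch
#' @method glance metrics_batch
#' @export
glance.metrics_batch <- function(x, ...) {
  tibble::as_tibble(x$pooled)
}

#' Serialise a metrics report or batch to JSON (and back)
#'
#' @param x a `metrics_report` or `metrics_batch`.
#' @param path output JSON path.
#' @return `path` invisibly; `read_metrics_json` returns the deserialised
#'   object with its class restored.
#' @export
write_metrics_json <- function(x, path) {
  payload <- unclass(x)
  if (inherits(x, "metrics_batch")) {
    payload$per_image <- lapply(payload$per_image, unclass)
    payload$cdf <- unclass(payload$cdf)
  }
  payload$.class <- class(x)[1]
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_metrics_json
#' @export
read_metrics_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- x$.class
  x$.class <- NULL
  if (identical(cls, "metrics_batch")) {
    x$per_image <- lapply(x$per_image, function(r)
      structure(r, class = "metrics_report"))
    x$cdf <- structure(x$cdf, class = "cdf_estimate")
  }
  structure(x, class = cls)
}
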