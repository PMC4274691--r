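# Fixture builders shared across the test files. Everything is generated in
# code so tests carry no binary data.

# logical matrix with filled discs at the given centres/radii
disc_mask <- function(H, W, centres, radii) {
  m <- matrix(FALSE, H, W)
  Y <- matrix(seq_len(H), H, W)
  X <- matrix(seq_len(W), H, W, byrow = TRUE)
  for (i in seq_along(radii)) {
    m <- m | ((Y - centres[[i]][1])^2 + (X - centres[[i]][2])^2 <= radii[i]^2)
  }
  m
}

# axis-aligned (or rotated) filled ellipse mask
ellipse_mask <- function(H, W, centre, a, b, theta = 0) {
  Y <- matrix(seq_len(H), H, W) - centre[1]
  X <- matrix(seq_len(W), H, W, byrow = TRUE) - centre[2]
  U <- X * cos(theta) + Y * sin(theta)
  V <- -X * sin(theta) + Y * cos(theta)
  (U / a)^2 + (V / b)^2 <= 1
}

# exact optical-density mixture of two unit stain vectors; returns the rgb
# image plus the generating concentration maps
stain_mixture_fixture <- function(H = 48, W = 48, seed = 7) {
  v_eos <- c(0.07, 0.99, 0.11); v_eos <- v_eos / sqrt(sum(v_eos^2))
  v_hem <- c(0.65, 0.70, 0.29); v_hem <- v_hem / sqrt(sum(v_hem^2))
  withr::with_seed(seed, {
    c_eos <- matrix(runif(H * W, 0.05, 1.2), H, W)
    c_hem <- matrix(runif(H * W, 0.05, 0.8), H, W)
  })
  od <- array(0, c(H, W, 3))
  for (k in 1:3) od[, , k] <- c_eos * v_eos[k] + c_hem * v_hem[k]
  eps <- 1 / 255
  I <- (1 + eps) * exp(-od) - eps
  list(rgb = rgb_image(pmin(pmax(I, 0), 1)),
       c_eos = c_eos, c_hem = c_hem, v_eos = v_eos, v_hem = v_hem)
}

# 4-fibre ground truth on a 40 x 40 canvas: quadrant squares separated by a
# 4-px background cross
four_fibre_gt <- function() {
  lab <- matrix(0L, 40, 40)
  lab[3:18, 3:18] <- 1L
  lab[3:18, 23:38] <- 2L
  lab[23:38, 3:18] <- 3L
  lab[23:38, 23:38] <- 4L
  label_mask(lab)
}

# prediction that splits fibre 1 into two halves (one-split fixture)
four_fibre_split_pred <- function() {
  gt <- four_fibre_gt()
  lab <- unclass(gt)
  attributes(lab) <- list(dim = dim(gt))
  lab[3:18, 10] <- 0L          # cut fibre 1 vertically
  lab[lab == 1L & col(lab) > 10] <- 5L
  label_mask(lab)
}

# prediction that merges fibres 1 and 2 into a single region (one-merge)
four_fibre_merge_pred <- function() {
  gt <- four_fibre_gt()
  lab <- unclass(gt)
  attributes(lab) <- list(dim = dim(gt))
  lab[lab == 2L] <- 1L
  lab[3:18, 19:22] <- 1L       # bridge across the gap
  label_mask(label_renumber_for_tests(lab))
}

label_renumber_for_tests <- function(lab) {
  ids <- sort(unique(lab[lab > 0]))
  out <- lab
  for (i in seq_along(ids)) out[lab == ids[i]] <- i
  out
}

# independent exhaustive Otsu oracle on a 256-bin histogram
otsu_oracle <- function(values, nbins = 256L) {
  bin <- pmin(floor(values * nbins) + 1, nbins)
  h <- tabulate(bin, nbins)
  n <- sum(h)
  mids <- (seq_len(nbins) - 0.5) / nbins
  best <- -Inf; best_t <- NA
  for (t in seq_len(nbins - 1L)) {
    n0 <- sum(h[1:t]); n1 <- n - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(h[1:t] * mids[1:t]) / n0
    mu1 <- sum(h[(t + 1):nbins] * mids[(t + 1):nbins]) / n1
    bcv <- (n0 / n) * (n1 / n) * (mu0 - mu1)^2
    if (bcv > best + 1e-12) { best <- bcv; best_t <- t }  # lowest threshold on plateaus
  }
  best_t / nbins
}

# independent explicit 5-point Laplacian heat step with no-flux boundaries
heat_step_oracle <- function(u, tau) {
  H <- nrow(u); W <- ncol(u)
  up <- u[c(1, 1:(H - 1)), ]; dn <- u[c(2:H, H), ]
  lf <- u[, c(1, 1:(W - 1))]; rt <- u[, c(2:W, W)]
  u + tau * ((up - u) + (dn - u) + (lf - u) + (rt - u))
}

small_synth <- function(seed = 1, ...) {
  generate_muscle_image(synthetic_spec(height = 256L, width = 256L,
                                       n_seeds = 9L, rng_seed = seed, ...))
}

# 90-degree counter-clockwise rotation of a matrix
rot90_mat <- function(m) t(m)[ncol(m):1, , drop = FALSE]
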