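#' Phenomenological recruitment kinetics
#'
#' The generator models the damage-stripe signal as a two-rate curve: zero
#' before damage, then a saturating rise with rate `k_on` multiplied by an
#' exponential dissociation with rate `k_off`,
#' `f(t) = A * (1 - exp(-k_on (t - t_d))) * exp(-k_off (t - t_d))`.
#' This is not a mechanistic binding model; its job is to produce recruitment
#' curves with controllable amplitude, time-to-half-maximum and dissociation
#' so that every downstream stage has exact ground truth.
#'
#' @param A Amplitude: fold-increase of stripe fluorescence at saturation
#'   (dimensionless, >= 0; `A = 0` renders a no-recruitment control).
#' @param k_on Recruitment rate, 1/s (> 0).
#' @param k_off Dissociation rate, 1/s (>= 0); 0 means the protein persists.
#' @param t_d Damage time in seconds (convention: 0).
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(A, k_on, k_off = 0, t_d = 0) {
  stopifnot(is.finite(A), A >= 0, is.finite(k_on), k_on > 0,
            is.finite(k_off), k_off >= 0, is.finite(t_d))
  structure(list(A = A, k_on = k_on, k_off = k_off, t_d = t_d),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("Kinetics: A = %.3g, k_on = %.3g /s, k_off = %.3g /s, t_d = %.3g s\n",
              x$A, x$k_on, x$k_off, x$t_d))
  invisible(x)
}

#' Fractional stripe signal increase at time t
#'
#' @param t Time(s) in seconds (vectorized).
#' @param p A [kinetic_params()] object.
#' @return `f(t) >= 0`, 0 for `t < t_d`, continuous at `t_d`.
#' @export
recruitment_fraction <- function(t, p) {
  stopifnot(inherits(p, "kinetic_params"), all(is.finite(t)))
  tau <- t - p$t_d
  out <- p$A * (1 - exp(-p$k_on * tau)) * exp(-p$k_off * tau)
  out[tau < 0] <- 0
  out
}

#' Time of the kinetic curve's maximum
#'
#' Closed form: `t_max = t_d + log((k_on + k_off) / k_off) / k_on`, infinite
#' when `k_off = 0` (the curve saturates monotonically).
#'
#' @param p A [kinetic_params()] object.
#' @param t_end Optional horizon; the returned time is capped at it.
#' @return Seconds (possibly `Inf` when `k_off = 0` and `t_end = Inf`).
#' @export
true_t_max <- function(p, t_end = Inf) {
  tm <- if (p$k_off == 0) Inf
        else p$t_d + log((p$k_on + p$k_off) / p$k_off) / p$k_on
  min(tm, t_end)
}

#' Ground-truth time to half-maximal recruitment
#'
#' Smallest `t` with `f(t) >= 0.5 * max f`, located by bisection on the
#' rising branch (f is strictly increasing up to its maximum) to an accuracy
#' of 1e-4 s. With `k_off = 0` this reduces to `log(2) / k_on`.
#'
#' @param p A [kinetic_params()] object.
#' @param t_end Horizon over which the maximum is taken (default infinite).
#' @return Seconds from damage.
#' @export
true_t50 <- function(p, t_end = Inf) {
  tau_end <- if (is.finite(t_end)) t_end - p$t_d else Inf
  tau_max <- if (p$k_off == 0) tau_end
             else min(log((p$k_on + p$k_off) / p$k_off) / p$k_on, tau_end)
  fmax <- if (is.finite(tau_max)) recruitment_fraction(p$t_d + tau_max, p)
          else p$A
  target <- 0.5 * fmax
  lo <- 0
  hi <- if (is.finite(tau_max)) tau_max else {
    h <- 1 / p$k_on
    while (recruitment_fraction(p$t_d + h, p) < target) h <- 2 * h
    h
  }
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    if (recruitment_fraction(p$t_d + mid, p) >= target) hi <- mid else lo <- mid
  }
  p$t_d + (lo + hi) / 2
}

#' Simulation configuration for a synthetic microirradiation movie
#'
#' Defaults emulate the standard acquisition regime this pipeline targets:
#' 600 frames at 0.5 s interval, 10 pre-damage frames, a 128x128 px field at
#' 0.11 um/px containing one elliptical nucleus, and an 11 um (100 px)
#' damage stripe. Each channel has a baseline intensity `I0` (counts), its
#' own kinetics, a per-frame photobleaching rate `k_b`, and Gaussian noise
#' `noise_sd`; the red channel additionally receives a `bleedthrough`
#' fraction of the green fluorescence. A constant camera dark offset is
#' added everywhere.
#'
#' @param shape `c(H, W)` frame size in pixels.
#' @param n_frames Number of frames.
#' @param frame_interval Seconds per frame.
#' @param pixel_size Micrometres per pixel.
#' @param n_predamage Pre-damage frame count.
#' @param nucleus List with `centre = c(x, y)` and `semiaxes = c(a, b)` in px.
#' @param stripe A [rect_roi()]; must lie inside the nucleus.
#' @param channels Named list (`green`, `red`) of per-channel settings:
#'   `I0`, `kinetics` ([kinetic_params()]), `bleach` (1/frame, >= 0),
#'   `noise_sd` (counts).
#' @param bleedthrough Fraction of green fluorescence added to red (0-0.2).
#' @param drift Linear drift velocity `c(vx, vy)` in px/frame
#'   (nearest-pixel rendering).
#' @param dark_offset Camera offset in counts, added everywhere.
#' @param noise `"gaussian"` (default) or `"poisson"`.
#' @param poisson_gain Counts per photon for the Poisson model.
#' @param seed Optional RNG seed used by [simulate_movie()].
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(shape = c(128L, 128L),
                       n_frames = 600L,
                       frame_interval = 0.5,
                       pixel_size = 0.11,
                       n_predamage = 10L,
                       nucleus = list(centre = c(63.5, 63.5),
                                      semiaxes = c(52, 40)),
                       stripe = rect_roi(14L, 61L, 100L, 6L),
                       channels = list(
                         green = list(I0 = 170, kinetics = kinetic_params(1, 0.2, 0.01),
                                      bleach = 0.001, noise_sd = 17),
                         red   = list(I0 = 300, kinetics = kinetic_params(2, 0.12, 0.005),
                                      bleach = 0.001, noise_sd = 30)
                       ),
                       bleedthrough = 0.05,
                       drift = c(0, 0),
                       dark_offset = 100,
                       noise = c("gaussian", "poisson"),
                       poisson_gain = 1,
                       seed = NULL) {
  noise <- match.arg(noise)
  stopifnot(length(shape) == 2L, all(shape >= 8L),
            n_frames > n_predamage, n_predamage >= 1L,
            frame_interval > 0, pixel_size > 0,
            bleedthrough >= 0, bleedthrough <= 0.2,
            length(drift) == 2L, dark_offset >= 0, poisson_gain > 0)
  stopifnot(inherits(stripe, "rect_roi"))
  for (ch in channels) {
    stopifnot(is.finite(ch$I0), ch$I0 > 0, inherits(ch$kinetics, "kinetic_params"),
              ch$bleach >= 0, ch$noise_sd >= 0)
  }
  cfg <- structure(list(
    shape = as.integer(shape), n_frames = as.integer(n_frames),
    frame_interval = frame_interval, pixel_size = pixel_size,
    n_predamage = as.integer(n_predamage),
    nucleus = nucleus, stripe = stripe, channels = channels,
    bleedthrough = bleedthrough, drift = as.numeric(drift),
    dark_offset = dark_offset, noise = noise, poisson_gain = poisson_gain,
    seed = seed
  ), class = "sim_config")
  m <- ellipse_mask(shape[1], shape[2], nucleus$centre, nucleus$semiaxes)
  check_roi_in_frame(stripe, shape)
  if (!all(m$mask[roi_rows(stripe), roi_cols(stripe)]))
    stop("damage stripe must lie fully inside the nucleus")
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Simulated acquisition: %d frames %dx%d px, %.3g s interval, damage after frame %d\n",
              x$n_frames, x$shape[1], x$shape[2], x$frame_interval, x$n_predamage))
  invisible(x)
}

sim_meta <- function(cfg) {
  acq_meta(cfg$frame_interval, cfg$pixel_size, cfg$n_predamage)
}

# integer-shifted copy of a logical mask, exposed pixels FALSE
shift_mask <- function(mask, dx, dy) {
  if (dx == 0 && dy == 0) return(mask)
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(FALSE, h, w)
  xs <- max(1L, 1L + dx):min(w, w + dx)
  ys <- max(1L, 1L + dy):min(h, h + dy)
  if (length(xs) && length(ys))
    out[ys, xs] <- mask[ys - dy, xs - dx]
  out
}

#' Simulate a dual-channel microirradiation movie with ground truth
#'
#' Renders, per frame and channel, the noiseless fluorescence
#' `I0 * (1 + f(t) * stripe) * exp(-k_b * (frame - 1))` inside the (possibly
#' drifting) nucleus, adds the camera dark offset everywhere, adds the
#' bleed-through fraction of green fluorescence to the red channel, then
#' applies the configured noise model. Identical seeds give identical
#' movies; different seeds change only the noise.
#'
#' @param cfg A [sim_config()].
#' @param seed RNG seed (overrides `cfg$seed` when given).
#' @return A list of class `sim_movie` with components `green`, `red`
#'   ([timelapse_movie()]s), `truth` (per channel: `I0`, `kinetics`, `k_b`,
#'   `t50`, `t_max`, and the noiseless `stripe_trace` / `nucleus_trace`),
#'   `masks` (nucleus and stripe masks at frame 1), and `cfg`.
#' @export
simulate_movie <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  H <- cfg$shape[1]; W <- cfg$shape[2]; T <- cfg$n_frames
  meta <- sim_meta(cfg)
  times <- frame_times(meta, T)
  nuc0 <- ellipse_mask(H, W, cfg$nucleus$centre, cfg$nucleus$semiaxes)$mask
  str0 <- matrix(FALSE, H, W)
  str0[roi_rows(cfg$stripe), roi_cols(cfg$stripe)] <- TRUE
  horizon <- max(times)

  fluor <- list()  # noiseless fluorescence component per channel
  for (name in c("green", "red")) {
    ch <- cfg$channels[[name]]
    f <- recruitment_fraction(times, ch$kinetics)
    decay <- exp(-ch$bleach * (seq_len(T) - 1L))
    arr <- array(0, dim = c(H, W, T))
    for (t in seq_len(T)) {
      d <- round(cfg$drift * (t - 1L))
      nuc <- shift_mask(nuc0, d[1], d[2])
      str <- shift_mask(str0, d[1], d[2])
      frame <- matrix(0, H, W)
      frame[nuc] <- ch$I0 * decay[t]
      frame[str] <- ch$I0 * (1 + f[t]) * decay[t]
      arr[, , t] <- frame
    }
    fluor[[name]] <- arr
  }
  fluor$red <- fluor$red + cfg$bleedthrough * fluor$green

  movies <- list()
  truth <- list()
  for (name in c("green", "red")) {
    ch <- cfg$channels[[name]]
    noiseless <- cfg$dark_offset + fluor[[name]]
    noisy <- switch(cfg$noise,
      gaussian = if (ch$noise_sd > 0)
        pmax(noiseless + array(stats::rnorm(length(noiseless), 0, ch$noise_sd),
                               dim = dim(noiseless)), 0)
      else noiseless,
      poisson = {
        g <- cfg$poisson_gain
        array(g * stats::rpois(length(noiseless), as.vector(noiseless) / g),
              dim = dim(noiseless))
      })
    movies[[name]] <- timelapse_movie(noisy, meta, name)
    f <- recruitment_fraction(times, ch$kinetics)
    decay <- exp(-ch$bleach * (seq_len(T) - 1L))
    truth[[name]] <- list(
      I0 = ch$I0, kinetics = ch$kinetics, k_b = ch$bleach,
      noise_sd = ch$noise_sd,
      t50 = true_t50(ch$kinetics, t_end = horizon),
      t_max = true_t_max(ch$kinetics, t_end = horizon),
      stripe_trace = cfg$dark_offset + ch$I0 * (1 + f) * decay,
      nucleus_trace = cfg$dark_offset + ch$I0 * decay
    )
  }
  structure(list(green = movies$green, red = movies$red,
                 truth = truth,
                 masks = list(nucleus = nucleus_mask(nuc0), stripe = str0),
                 cfg = cfg),
            class = "sim_movie")
}

#' Simulate a batch of cells with randomized parameters
#'
#' Draws per-cell baselines and kinetics uniformly from the supplied ranges
#' (green baseline defaults to the 140-200 count selection window, red to
#' 200-400) and simulates one dual-channel movie per cell. Noise is set per
#' channel as `I0 / snr`. Each cell gets its own sub-seed derived from
#' `seed`, so batches are reproducible and cells independent.
#'
#' @param n_cells Number of cells.
#' @param cfg Base [sim_config()]; per-cell draws override its channels.
#' @param I0_green,I0_red Baseline ranges `c(lo, hi)` in counts.
#' @param A,k_on,k_off Kinetics ranges `c(lo, hi)` shared by both channels
#'   unless `red_kinetics` is given.
#' @param red_kinetics `"independent"` (default: red redrawn from the same
#'   ranges) or `"same"` (red copies green's kinetics).
#' @param snr Per-pixel signal-to-noise ratio `I0 / noise_sd`; `Inf` for
#'   noise-free movies.
#' @param onset_delay_red Seconds added to the red channel's damage time
#'   (`t_d`), for recruitment-order studies.
#' @param seed RNG seed for the batch.
#' @return List of `n_cells` [simulate_movie()] results.
#' @export
simulate_cells <- function(n_cells, cfg = sim_config(),
                           I0_green = c(140, 200), I0_red = c(200, 400),
                           A = c(0.3, 2), k_on = c(0.05, 0.5),
                           k_off = c(0, 0.05),
                           red_kinetics = c("independent", "same"),
                           snr = 10, onset_delay_red = 0,
                           seed = 1L) {
  red_kinetics <- match.arg(red_kinetics)
  set.seed(as.integer(seed))
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_cells)
  draws <- lapply(seq_len(n_cells), function(i) {
    kin_g <- kinetic_params(stats::runif(1, A[1], A[2]),
                            stats::runif(1, k_on[1], k_on[2]),
                            stats::runif(1, k_off[1], k_off[2]))
    kin_r <- if (red_kinetics == "same") kin_g
             else kinetic_params(stats::runif(1, A[1], A[2]),
                                 stats::runif(1, k_on[1], k_on[2]),
                                 stats::runif(1, k_off[1], k_off[2]))
    kin_r <- kinetic_params(kin_r$A, kin_r$k_on, kin_r$k_off,
                            t_d = kin_r$t_d + onset_delay_red)
    list(I0_g = stats::runif(1, I0_green[1], I0_green[2]),
         I0_r = stats::runif(1, I0_red[1], I0_red[2]),
         kin_g = kin_g, kin_r = kin_r)
  })
  lapply(seq_len(n_cells), function(i) {
    d <- draws[[i]]
    ci <- cfg
    ci$channels$green$I0 <- d$I0_g
    ci$channels$green$kinetics <- d$kin_g
    ci$channels$green$noise_sd <- if (is.finite(snr)) d$I0_g / snr else 0
    ci$channels$red$I0 <- d$I0_r
    ci$channels$red$kinetics <- d$kin_r
    ci$channels$red$noise_sd <- if (is.finite(snr)) d$I0_r / snr else 0
    simulate_movie(ci, seed = sub_seeds[i])
  })
}
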