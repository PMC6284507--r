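# Shared fixture builders. Tests use a reduced field of view (64 x 96 px,
# 6.6 um stripe) so full movie pipelines stay fast; geometry is otherwise
# the generator's.

test_cfg <- function(n_frames = 150L, n_predamage = 10L, frame_interval = 0.5,
                     shape = c(64L, 96L), dark_offset = 100, drift = c(0, 0),
                     green = list(I0 = 170, kinetics = kinetic_params(1, 0.2, 0.01),
                                  bleach = 0.001, noise_sd = 0),
                     red = list(I0 = 300, kinetics = kinetic_params(2, 0.12, 0.005),
                                bleach = 0.001, noise_sd = 0),
                     bleedthrough = 0.05, noise = "gaussian", seed = NULL) {
  sim_config(shape = shape, n_frames = n_frames,
             frame_interval = frame_interval, n_predamage = n_predamage,
             nucleus = list(centre = c(47.5, 31.5), semiaxes = c(40, 26)),
             stripe = rect_roi(18L, 29L, 60L, 4L),
             channels = list(green = green, red = red),
             bleedthrough = bleedthrough, drift = drift,
             dark_offset = dark_offset, noise = noise, seed = seed)
}

test_damage_roi <- function() rect_roi(18L, 25L, 60L, 12L)

# records for a batch of simulate_cells() results
records_from_sims <- function(sims, smooth = TRUE, use_dog = TRUE,
                              interpolate_t50 = FALSE) {
  lapply(seq_along(sims), function(i) {
    s <- sims[[i]]
    analyze_cell(sprintf("cell%03d", i), s$green, s$red, test_damage_roi(),
                 s$masks$nucleus$mask, smooth = smooth, use_dog = use_dog,
                 interpolate_t50 = interpolate_t50)
  })
}

# minimal cell stub for predicate-level QC tests
stub_qc_cell <- function(id, green_i0, red_i0) {
  mk <- function(i0) list(trace = list(i0_raw = i0), curve = list(i0 = i0))
  structure(list(cell_id = as.character(id), green = mk(green_i0),
                 red = mk(red_i0)), class = "cell_record")
}

# cell stub with prescribed FMR curves for population-level unit tests
stub_curve_cell <- function(id, meta, fmr_green, fmr_red = fmr_green,
                            i0_green = 170, i0_red = 300, area = 3000) {
  mk <- function(f, ch, i0r) {
    T <- length(f)
    structure(list(time_s = frame_times(meta, T), corrected = 1 + f,
                   rfi = 1 + f, delta = f, fmr = f, i0 = 1, i0_raw = i0r,
                   max_rfi = 1 + max(f),
                   t_max = NA_real_, t50 = time_to_half_max(f, meta),
                   final_fmr = f[T], defined = TRUE, reason = NULL,
                   smooth = FALSE, meta = meta, channel_label = ch),
              class = "recruitment_curve")
  }
  structure(list(
    cell_id = as.character(id),
    green = list(trace = list(i0_raw = i0_green),
                 curve = mk(fmr_green, "green", i0_green)),
    red = list(trace = list(i0_raw = i0_red),
               curve = mk(fmr_red, "red", i0_red)),
    nucleus_area_px = area, nucleus_area_um2 = area * meta$pixel_size^2,
    meta = meta, qc_pass = NA, qc_reason = NA_character_
  ), class = "cell_record")
}
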