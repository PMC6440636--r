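# Synthetic stand-ins for the study's raw data: rigid-sphere binaural
# impulse responses, a parametric HMD acoustic perturbation shaped like the
# measured cue errors, the pink-noise stimulus, and simulated pointing
# cohorts with per-subject bias, condition-dependent noise and lapses.

with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Spherical-head model configuration
#'
#' @param head_radius Head radius in meters (default 8.75 cm).
#' @param speed_of_sound Speed of sound in m/s.
#' @param fs Sampling rate in Hz.
#' @param ir_length Impulse-response length in samples.
#' @param base_delay Propagation delay to the near ear in samples.
#' @param shadow_strength One-pole head-shadow coefficient at 90 degrees
#'   lateral angle, in (0, 1); larger = stronger high-frequency shadowing.
#' @return List of class \code{head_model_config}.
#' @export
head_model_config <- function(head_radius = 0.0875, speed_of_sound = 343,
                              fs = 48000, ir_length = 128, base_delay = 8,
                              shadow_strength = 0.85) {
  stopifnot(head_radius > 0, speed_of_sound > 0, fs > 0, ir_length > 0,
            base_delay >= 0, shadow_strength > 0, shadow_strength < 1)
  structure(as.list(environment()), class = "head_model_config")
}

# signed lateral angle in radians: positive = right, combines azimuth and
# elevation on the rigid sphere (cone-of-confusion geometry)
lateral_angle <- function(azimuth, elevation) {
  s <- sin(deg2rad(azimuth)) * cos(deg2rad(elevation))
  asin(max(-1, min(1, s)))
}

#' Woodworth interaural time difference for a rigid sphere
#'
#' ITD(theta) = (a/c) (theta + sin theta) for frontal incidence at lateral
#' angle theta.
#'
#' @param azimuth,elevation Source direction in degrees.
#' @param cfg A \code{head_model_config}.
#' @return Signed ITD in seconds (positive = source on the right).
#' @export
woodworth_itd <- function(azimuth, elevation = 0, cfg = head_model_config()) {
  th <- lateral_angle(azimuth, elevation)
  cfg$head_radius / cfg$speed_of_sound * (abs(th) + sin(abs(th))) * sign(th)
}

#' Synthesize a rigid-sphere binaural impulse response
#'
#' The near ear receives a unit impulse after the base propagation delay;
#' the far ear receives the impulse delayed by the Woodworth ITD (quantized
#' to integer samples, so integer-lag cue extraction recovers it exactly)
#' and filtered by a first-order low-pass head-shadow whose strength grows
#' with the lateral angle. Frontal sources give identical channels (ITD 0,
#' ILD 0).
#'
#' @param azimuth,elevation Source direction in degrees.
#' @param cfg A \code{head_model_config}.
#' @param radius Source distance in meters (metadata only; the model is
#'   far-field).
#' @return A \code{binaural_ir} with condition \code{"synthetic"}.
#' @export
spherical_head_brir <- function(azimuth, elevation = 0,
                                cfg = head_model_config(), radius = 2.4) {
  stopifnot(abs(azimuth) <= 180, abs(elevation) <= 90)
  th <- lateral_angle(azimuth, elevation)
  d <- as.integer(round(abs(woodworth_itd(azimuth, elevation, cfg)) * cfg$fs))
  a <- cfg$shadow_strength * abs(sin(th))

  near <- numeric(cfg$ir_length)
  near[cfg$base_delay + 1] <- 1
  far <- numeric(cfg$ir_length)
  k <- cfg$base_delay + d + 1
  if (k <= cfg$ir_length) {
    # one-pole low-pass (1-a)/(1 - a z^-1): unit DC gain, HF attenuation
    tail_len <- cfg$ir_length - k + 1
    far[k:cfg$ir_length] <- (1 - a) * a^(seq_len(tail_len) - 1)
  }
  if (th >= 0) {  # source on the right: left ear is far
    binaural_ir(left = far, right = near, fs = cfg$fs, condition = "synthetic",
                azimuth = azimuth, elevation = elevation, radius = radius)
  } else {
    binaural_ir(left = near, right = far, fs = cfg$fs, condition = "synthetic",
                azimuth = azimuth, elevation = elevation, radius = radius)
  }
}

#' HMD perturbation configuration
#'
#' Parametric emulation of the measured HMD-induced cue errors: an ITD
#' offset vanishing at 0 and 90 degrees azimuth and peaking mid-laterally;
#' per-region ILD magnitude boosts with the same end-point zeros; and
#' mid/high-frequency spectral ripple, strongest for the contralateral ear
#' at and above the horizontal plane and attenuated below it.
#'
#' @param max_itd_offset Peak ITD error in microseconds.
#' @param itd_peak_azimuth Azimuth (degrees, in (0, 90)) of the ITD peak.
#' @param max_ild_offset Peak ILD boost in dB.
#' @param ild_peak_azimuths Named vector: per-region azimuth of the ILD peak.
#' @param region_ild_scale Named vector: per-region scaling of
#'   \code{max_ild_offset} (low kept small, matching the measured < 2 dB).
#' @param high_band_ripple Peak spectral ripple amplitude in dB at
#'   elevations >= 0.
#' @param mid_band_ripple_scale Ripple amplitude in the mid region relative
#'   to the high region.
#' @param ripple_cycles_per_octave Ripple rate on the log-frequency axis.
#' @param below_plane_attenuation Multiplier (< 1) on the ripple amplitude
#'   below the horizontal plane.
#' @return List of class \code{hmd_perturbation_config}.
#' @export
hmd_perturbation_config <- function(max_itd_offset = 62.5,
                                    itd_peak_azimuth = 75,
                                    max_ild_offset = 6,
                                    ild_peak_azimuths = c(low = 45, mid = 60, high = 30),
                                    region_ild_scale = c(low = 0.25, mid = 1, high = 1),
                                    high_band_ripple = 6.3,
                                    mid_band_ripple_scale = 0.6,
                                    ripple_cycles_per_octave = 2,
                                    below_plane_attenuation = 0.4) {
  stopifnot(max_itd_offset >= 0, itd_peak_azimuth > 0, itd_peak_azimuth < 90,
            max_ild_offset >= 0, all(ild_peak_azimuths > 0),
            all(ild_peak_azimuths < 90), high_band_ripple >= 0,
            below_plane_attenuation >= 0, below_plane_attenuation < 1)
  structure(as.list(environment()), class = "hmd_perturbation_config")
}

# tent shape: 0 at 0 and 90 deg |azimuth|, 1 at the peak azimuth
azimuth_tent <- function(az, peak) {
  a <- abs(az)
  ifelse(a <= 0 | a >= 90, 0, ifelse(a <= peak, a / peak, (90 - a) / (90 - peak)))
}

#' Apply the parametric HMD perturbation to a binaural IR
#'
#' Adds an azimuth-dependent integer-sample ITD offset to the contralateral
#' ear, region-specific zero-phase attenuation of the contralateral ear
#' (boosting ILD magnitudes), and sinusoidal log-frequency ripple in the
#' mid/high bands of both ears (amplitude scaled by each ear's
#' contralaterality and reduced below the horizontal plane). Deterministic
#' given (azimuth, elevation, config); the seed sets only the ripple phase.
#'
#' @param ir A \code{binaural_ir} (typically from [spherical_head_brir()]).
#' @param cfg An \code{hmd_perturbation_config}.
#' @param seed Integer seed for the ripple phase.
#' @return A \code{binaural_ir} with condition \code{"with_hmd"}.
#' @export
apply_hmd_model <- function(ir, cfg = hmd_perturbation_config(), seed = 1) {
  az <- ir$azimuth
  el <- ir$elevation
  fs <- ir$fs
  out <- ir
  out$condition <- "with_hmd"
  if (cfg$max_itd_offset == 0 && cfg$max_ild_offset == 0 &&
      cfg$high_band_ripple == 0) {
    return(out)
  }

  contra <- if (az > 0) "left" else if (az < 0) "right" else NA

  # ITD offset: delay the contralateral ear by an integer sample count
  off_us <- cfg$max_itd_offset * azimuth_tent(az, cfg$itd_peak_azimuth)
  off_smp <- as.integer(round(off_us * fs / 1e6))
  if (!is.na(contra) && off_smp > 0) {
    x <- out[[contra]]
    out[[contra]] <- c(numeric(off_smp), x)[seq_along(x)]
  }

  n <- length(out$left)
  nfft <- max(1024L, stats::nextn(4L * n, 2))
  f <- seq(0, nfft / 2) * fs / nfft
  lf <- log2(pmax(f, 1))

  # contralateral-ear attenuation bumps per region (raised cosine in log f)
  regions <- frequency_regions()
  att_db <- numeric(length(f))
  for (i in seq_len(nrow(regions))) {
    rg <- regions$region[i]
    amp <- cfg$max_ild_offset * cfg$region_ild_scale[[rg]] *
      azimuth_tent(az, cfg$ild_peak_azimuths[[rg]])
    if (amp > 0) {
      lo <- log2(regions$f_lo[i]); hi <- log2(regions$f_hi[i])
      inb <- f >= regions$f_lo[i] & f <= regions$f_hi[i]
      # raised cosine scaled so its region average equals amp, making the
      # realized per-region ILD error track the configured offset
      att_db[inb] <- att_db[inb] +
        amp * (1 - cos(2 * pi * (lf[inb] - lo) / (hi - lo)))
    }
  }

  # mid/high band ripple: amplitude envelope over log-frequency
  phase <- 2 * pi * ((as.integer(seed) * 2654435761) %% 2^31) / 2^31
  band_env <- numeric(length(f))
  midlo <- 1000; midhi <- 5000; hihi <- 16000
  inmid <- f >= midlo & f < midhi
  band_env[inmid] <- cfg$mid_band_ripple_scale *
    (lf[inmid] - log2(midlo)) / (log2(midhi) - log2(midlo))
  inhi <- f >= midhi & f <= hihi
  band_env[inhi] <- cfg$mid_band_ripple_scale +
    (1 - cfg$mid_band_ripple_scale) * (lf[inhi] - log2(midhi)) / (log2(hihi) - log2(midhi))
  elev_scale <- if (el >= 0) 1 else cfg$below_plane_attenuation
  ripple <- sin(2 * pi * cfg$ripple_cycles_per_octave * (lf - log2(1000)) + phase)

  shape_ear <- function(x, ear) {
    lat <- sin(deg2rad(if (ear == "left") az else -az))  # contralaterality
    ear_scale <- (1 + lat) / 2
    g_db <- cfg$high_band_ripple * band_env * elev_scale * ear_scale * ripple
    # the whole perturbation, ILD bumps included, is weaker below the
    # horizontal plane (the HMD sits above the ears)
    if (!is.na(contra) && ear == contra) g_db <- g_db - att_db * elev_scale
    if (all(g_db == 0)) return(x)
    g <- 10^(g_db / 20)
    gfull <- c(g, rev(g[2:(length(g) - 1)]))  # real, even -> zero phase
    X <- stats::fft(c(x, numeric(nfft - length(x))))
    Re(stats::fft(X * gfull, inverse = TRUE))[seq_along(x)] / nfft
  }
  out$left <- shape_ear(out$left, "left")
  out$right <- shape_ear(out$right, "right")
  out
}

#' Simulate a matched with/without-HMD BRIR dataset
#'
#' @param sources Source table from [build_source_array()] (or any data.frame
#'   with azimuth_deg/elevation_deg columns).
#' @param head_cfg A \code{head_model_config}.
#' @param hmd_cfg An \code{hmd_perturbation_config}.
#' @param seed Ripple-phase seed.
#' @return Named list (by "az_el") of lists with \code{with_hmd} and
#'   \code{without_hmd} \code{binaural_ir} objects.
#' @export
simulate_ir_dataset <- function(sources = build_source_array(),
                                head_cfg = head_model_config(),
                                hmd_cfg = hmd_perturbation_config(),
                                seed = 1) {
  out <- lapply(seq_len(nrow(sources)), function(i) {
    base <- spherical_head_brir(sources$azimuth_deg[i], sources$elevation_deg[i],
                                head_cfg)
    without <- base
    without$condition <- "without_hmd"
    list(with_hmd = apply_hmd_model(base, hmd_cfg, seed = seed),
         without_hmd = without)
  })
  names(out) <- sprintf("%g_%g", sources$azimuth_deg, sources$elevation_deg)
  out
}

#' Pink-noise burst stimulus
#'
#' A fresh pink-noise realization per call with raised-cosine on/off ramps,
#' presented at a nominal level roved uniformly within +/- \code{rove_db}.
#' Digital level is referenced to \code{ref_db} dB SPL at unit RMS
#' (no acoustic calibration constant is implied).
#'
#' @param duration Burst duration in seconds (default 240 ms).
#' @param ramp Raised-cosine ramp duration in seconds (default 20 ms).
#' @param fs Sampling rate in Hz.
#' @param level_db Nominal presentation level in dB SPL.
#' @param rove_db Half-width of the uniform level rove in dB.
#' @param seed Optional integer seed.
#' @param ref_db Level mapped to unit RMS.
#' @return List: \code{samples} (numeric vector), \code{fs},
#'   \code{level_db} (the roved realized level).
#' @export
pink_noise_burst <- function(duration = 0.240, ramp = 0.020, fs = 48000,
                             level_db = 65, rove_db = 3, seed = NULL,
                             ref_db = 100) {
  if (2 * ramp > duration) stop("2 * ramp must not exceed the burst duration")
  with_local_seed(seed, {
    n <- as.integer(round(duration * fs))
    nh <- n %/% 2
    # 1/f power spectrum: complex Gaussian bins scaled by 1/sqrt(f)
    fr <- seq_len(nh) * fs / n
    amp <- 1 / sqrt(fr)
    re <- stats::rnorm(nh) * amp
    im <- stats::rnorm(nh) * amp
    spec <- complex(real = re, imaginary = im)
    if (n %% 2 == 0) spec[nh] <- complex(real = re[nh], imaginary = 0)
    full <- c(0, spec, if (n %% 2 == 0) Conj(rev(spec[-nh])) else Conj(rev(spec)))
    x <- Re(stats::fft(full, inverse = TRUE)) / n
    # ramps
    nr <- as.integer(round(ramp * fs))
    if (nr > 0) {
      w <- 0.5 * (1 - cos(pi * (seq_len(nr) - 0.5) / nr))
      x[seq_len(nr)] <- x[seq_len(nr)] * w
      x[(n - nr + 1):n] <- x[(n - nr + 1):n] * rev(w)
    }
    lev <- level_db + stats::runif(1, -rove_db, rove_db)
    x <- x / sqrt(mean(x^2)) * 10^((lev - ref_db) / 20)
    list(samples = x, fs = fs, level_db = lev)
  })
}

#' Response-simulation configuration
#'
#' Defaults are calibrated to the study's headline behavioral effects:
#' group pointing bias (-1.6, +19.0) degrees, condition-dependent angular
#' noise yielding mean absolute elevation errors of roughly 12 (blind-folded
#' with HMD), 10.2 (blind-folded), 8.1 (virtual room + hand), 6.6
#' (loudspeakers visible) and 2.4 (laser pointer) degrees, an HMD lateral
#' overshoot larger on the left than on the right, a small elevation
#' penalty when wearing the HMD blind-folded, and a 0.003 lapse rate.
#'
#' @param bias_azimuth_mean,bias_azimuth_sd Per-subject azimuth bias
#'   distribution (degrees).
#' @param bias_elevation_mean,bias_elevation_sd Per-subject elevation bias
#'   distribution (degrees).
#' @param noise_azimuth_sd,noise_elevation_sd Named numeric vectors of
#'   per-condition angular noise SDs (degrees), keyed by condition slug.
#' @param overshoot_gain_left,overshoot_gain_right Lateral overshoot in
#'   degrees per degree of |azimuth| for targets in the left/right
#'   hemifield, applied in acoustic conditions with the HMD worn.
#' @param elevation_penalty_deg Signed elevation shift in the blind-folded
#'   HMD condition (degrees; negative = downward).
#' @param lapse_prob Probability that a response is a lapse drawn uniformly
#'   over the frontal hemisphere.
#' @return List of class \code{response_sim_config}.
#' @export
response_sim_config <- function(bias_azimuth_mean = -1.6,
                                bias_azimuth_sd = 1.5,
                                bias_elevation_mean = 19.0,
                                bias_elevation_sd = 5.0,
                                noise_azimuth_sd = NULL,
                                noise_elevation_sd = NULL,
                                overshoot_gain_left = 0.10,
                                overshoot_gain_right = 0.05,
                                elevation_penalty_deg = -1.8,
                                lapse_prob = 0.003) {
  stopifnot(bias_azimuth_sd >= 0, bias_elevation_sd >= 0,
            lapse_prob >= 0, lapse_prob < 1)
  ct <- condition_table()
  if (is.null(noise_azimuth_sd)) {
    noise_azimuth_sd <- c(9, 9, 7, 3, 3, 5, 5, 3)
    names(noise_azimuth_sd) <- ct$condition
  }
  if (is.null(noise_elevation_sd)) {
    noise_elevation_sd <- c(12.8, 15.0, 10.2, 5, 5, 8.3, 8.3, 3.0)
    names(noise_elevation_sd) <- ct$condition
  }
  stopifnot(all(noise_azimuth_sd >= 0), all(noise_elevation_sd >= 0))
  structure(as.list(environment())[c(
    "bias_azimuth_mean", "bias_azimuth_sd", "bias_elevation_mean",
    "bias_elevation_sd", "noise_azimuth_sd", "noise_elevation_sd",
    "overshoot_gain_left", "overshoot_gain_right", "elevation_penalty_deg",
    "lapse_prob")], class = "response_sim_config")
}

#' Simulate a pointing-response cohort
#'
#' Generates one record per subject x condition x source x repetition.
#' Responses are target + per-subject bias (omitted in the laser-pointer
#' condition, where visual feedback removes the controller-shape bias) +
#' condition shifts (HMD lateral overshoot with asymmetric left/right
#' gains; elevation penalty in the blind-folded HMD condition) + Gaussian
#' angular noise; with probability \code{lapse_prob} the response is drawn
#' uniformly over the frontal hemisphere. One subject is left-handed by
#' default (their hemifield-specific gains are swapped, so median-plane
#' mirroring restores a homogeneous cohort). Fully reproducible from the
#' seed.
#'
#' @param n_subjects Number of subjects.
#' @param repetitions Repetitions per condition and source.
#' @param sources Source table from [build_source_array()].
#' @param conditions Condition table.
#' @param cfg A \code{response_sim_config}.
#' @param n_left_handed How many subjects are left-handed (assigned from
#'   subject 8 on, mirroring the study cohort).
#' @param seed Integer seed.
#' @return Response records data.frame (see [read_responses()] schema).
#' @export
simulate_responses <- function(n_subjects = 10, repetitions = 5,
                               sources = build_source_array(),
                               conditions = condition_table(),
                               cfg = response_sim_config(),
                               n_left_handed = 1, seed = 1) {
  with_local_seed(seed, {
    subj <- sprintf("S%02d", seq_len(n_subjects))
    handed <- rep("right", n_subjects)
    if (n_left_handed > 0) {
      idx <- ((seq_len(n_left_handed) - 1 + 7) %% n_subjects) + 1
      handed[idx] <- "left"
    }
    bias_az <- stats::rnorm(n_subjects, cfg$bias_azimuth_mean, cfg$bias_azimuth_sd)
    bias_el <- stats::rnorm(n_subjects, cfg$bias_elevation_mean, cfg$bias_elevation_sd)

    grid <- expand.grid(rep_i = seq_len(repetitions),
                        src_i = seq_len(nrow(sources)),
                        cond_i = seq_len(nrow(conditions)),
                        subj_i = seq_len(n_subjects))
    taz <- sources$azimuth_deg[grid$src_i]
    tel <- sources$elevation_deg[grid$src_i]
    cond <- conditions[grid$cond_i, ]
    n <- nrow(grid)

    lapse <- stats::runif(n) < cfg$lapse_prob
    gl <- ifelse(handed[grid$subj_i] == "left",
                 cfg$overshoot_gain_right, cfg$overshoot_gain_left)
    gr <- ifelse(handed[grid$subj_i] == "left",
                 cfg$overshoot_gain_left, cfg$overshoot_gain_right)
    hmd_acoustic <- cond$hmd & cond$stimulus == "acoustic"
    shift_az <- ifelse(hmd_acoustic,
                       sign(taz) * abs(taz) * ifelse(taz < 0, gl, gr), 0)
    shift_el <- ifelse(hmd_acoustic & cond$visual_information == "blindfolded",
                       cfg$elevation_penalty_deg, 0)
    # a left-hander's lateral motor bias mirrors with the hand, so their
    # drawn azimuth bias is negated here and restored by median-plane
    # mirroring in the analysis
    b_az_subj <- bias_az * ifelse(handed == "left", -1, 1)
    b_az <- ifelse(cond$laser, 0, b_az_subj[grid$subj_i])
    b_el <- ifelse(cond$laser, 0, bias_el[grid$subj_i])

    resp_az <- taz + b_az + shift_az +
      stats::rnorm(n) * cfg$noise_azimuth_sd[cond$condition]
    resp_el <- tel + b_el + shift_el +
      stats::rnorm(n) * cfg$noise_elevation_sd[cond$condition]

    if (any(lapse)) {
      m <- sum(lapse)
      resp_az[lapse] <- stats::runif(m, -90, 90)
      resp_el[lapse] <- rad2deg(asin(stats::runif(m, -1, 1)))
    }

    data.frame(
      subject = subj[grid$subj_i],
      condition = cond$condition,
      block = cond$block,
      target_azimuth_deg = taz,
      target_elevation_deg = tel,
      response_azimuth_deg = wrap_angle(resp_az),
      response_elevation_deg = pmin(90, pmax(-90, resp_el)),
      repetition = grid$rep_i,
      handedness = handed[grid$subj_i],
      row.names = NULL
    )
  })
}
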