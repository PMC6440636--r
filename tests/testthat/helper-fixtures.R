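# shared fixtures: tiny IR pairs and response tables built in code

make_pair <- function(azimuth = 45, elevation = 0, hmd_cfg = hmd_perturbation_config(),
                      seed = 1) {
  base <- spherical_head_brir(azimuth, elevation)
  without <- base
  without$condition <- "without_hmd"
  list(with_hmd = apply_hmd_model(base, hmd_cfg, seed = seed),
       without_hmd = without)
}

# a pair with identical channels in both conditions
null_pair <- function(azimuth = 30) {
  ir <- spherical_head_brir(azimuth)
  w <- ir; w$condition <- "with_hmd"
  o <- ir; o$condition <- "without_hmd"
  list(with_hmd = w, without_hmd = o)
}

# small deterministic response table: one subject, a few targets
make_records <- function(az = c(-30, 0, 30), el = c(0, 28),
                         condition = "I-blindfolded-acoustic-nohmd",
                         subject = "S01", offset_az = 0, offset_el = 0,
                         handedness = "right") {
  g <- expand.grid(target_azimuth_deg = az, target_elevation_deg = el)
  data.frame(
    subject = subject, condition = condition, block = "I",
    target_azimuth_deg = g$target_azimuth_deg,
    target_elevation_deg = g$target_elevation_deg,
    response_azimuth_deg = g$target_azimuth_deg + offset_az,
    response_elevation_deg = g$target_elevation_deg + offset_el,
    repetition = 1L, handedness = handedness
  )
}

# noise-free visual-localization trials with a fixed per-subject offset,
# for exact bias arithmetic
bias_fixture <- function(subjects = c("S01", "S02"),
                         offsets_az = c(2, -4), offsets_el = c(10, 6)) {
  vis <- condition_table()$condition[condition_table()$visual_localization]
  do.call(rbind, lapply(seq_along(subjects), function(i) {
    do.call(rbind, lapply(vis, function(cd) {
      r <- make_records(condition = cd, subject = subjects[i],
                        offset_az = offsets_az[i], offset_el = offsets_el[i])
      r$block <- "III"
      r
    }))
  }))
}
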