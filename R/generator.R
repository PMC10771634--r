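## Synthetic TUG recording generator.
##
## Piecewise skeleton animation, not biomechanical simulation: a seated pose,
## a trunk-flexion rise, alternating-foot gait with half-cosine swing
## profiles, an in-place arc turn rotating the shoulder axis, the reverse
## walk, and sitting. The downstream stages consume only joint trajectories,
## so shape fidelity of the driving signals (shoulder-center height,
## foot depth traces, inter-shoulder lateral distance) is what matters.

#' Generator profile for synthetic TUG recordings
#'
#' Defaults describe an older healthy-control walker: subtask durations,
#' gait speed and step geometry at the magnitudes reported for
#' instrumented TUG assessments of cognitively healthy older adults
#' (see \code{\link{hc_profile}} / \code{\link{ad_profile}}).
#'
#' @param sit_to_stand_s,turning_s,stand_to_sit_s Subtask durations (s).
#' @param walk_distance_m One-way walkway length (m); the clinical TUG uses
#'   3 m.
#' @param gait_speed_mps Average walking speed (m/s); walking duration is
#'   \code{walk_distance_m / gait_speed_mps} per direction.
#' @param step_length_m Nominal step length (m).
#' @param cadence_steps_per_min Steps per minute. \code{NA} (default) derives
#'   cadence from speed and step length; a finite value instead fixes the
#'   step time and re-derives step length as
#'   \code{gait_speed_mps * 60 / cadence}, keeping speed exact.
#' @param step_width_m Lateral distance between left and right foot lines (m).
#' @param step_height_m Swing-apex foot lift above the floor baseline (m).
#' @param left_right_asymmetry Fraction in [0, 1): the left step length and
#'   step time are scaled by \code{1 - left_right_asymmetry} relative to the
#'   right, with the stride preserved, so the step symmetry index equals
#'   \code{1 - left_right_asymmetry}.
#' @param noise_sd_m Additive i.i.d. Gaussian position noise per
#'   joint-axis-frame (m), emulating depth-sensor jitter; applied before any
#'   filtering.
#' @param age_mean,age_sd,gds_mean,gds_sd Covariate distributions used by
#'   \code{\link{generate_cohort}} (years; Geriatric Depression Scale 0--15).
#' @param subject_sdlog Between-subject dispersion: log-SD of the lognormal
#'   multipliers applied to durations, speed and step geometry when drawing
#'   per-subject profiles.
#' @param frame_rate Frames per second (default 20).
#' @param lead_in_s,lead_out_s Seated plateau recorded before and after the
#'   test proper (s).
#' @param stance_fraction Stance share of the gait cycle (duty factor);
#'   values above 0.5 create double-support intervals.
#' @param turn_radius_m Radius of the semicircular turning arc traced by the
#'   body center (m).
#' @return A validated \code{tug_profile} list.
#' @export
tug_profile <- function(sit_to_stand_s = 2.49,
                        turning_s = 2.29,
                        stand_to_sit_s = 2.57,
                        walk_distance_m = 3,
                        gait_speed_mps = 0.57,
                        step_length_m = 0.40,
                        cadence_steps_per_min = NA_real_,
                        step_width_m = 0.13,
                        step_height_m = 0.11,
                        left_right_asymmetry = 0.25,
                        noise_sd_m = 0.005,
                        age_mean = 68.47, age_sd = 2.60,
                        gds_mean = 1.24, gds_sd = 1.25,
                        subject_sdlog = 0.15,
                        frame_rate = 20,
                        lead_in_s = 1.0, lead_out_s = 1.0,
                        stance_fraction = 0.55,
                        turn_radius_m = 0.25) {
  p <- list(sit_to_stand_s = sit_to_stand_s, turning_s = turning_s,
            stand_to_sit_s = stand_to_sit_s, walk_distance_m = walk_distance_m,
            gait_speed_mps = gait_speed_mps, step_length_m = step_length_m,
            cadence_steps_per_min = cadence_steps_per_min,
            step_width_m = step_width_m, step_height_m = step_height_m,
            left_right_asymmetry = left_right_asymmetry,
            noise_sd_m = noise_sd_m,
            age_mean = age_mean, age_sd = age_sd,
            gds_mean = gds_mean, gds_sd = gds_sd,
            subject_sdlog = subject_sdlog, frame_rate = frame_rate,
            lead_in_s = lead_in_s, lead_out_s = lead_out_s,
            stance_fraction = stance_fraction, turn_radius_m = turn_radius_m)
  class(p) <- "tug_profile"
  validate_profile(p)
  p
}

validate_profile <- function(p) {
  durs <- c(p$sit_to_stand_s, p$turning_s, p$stand_to_sit_s,
            p$lead_in_s, p$lead_out_s)
  if (any(!is.finite(durs)) || any(durs <= 0))
    stop_parameter("all durations must be positive")
  if (!is.finite(p$gait_speed_mps) || p$gait_speed_mps <= 0)
    stop_parameter("gait_speed_mps must be positive")
  if (p$walk_distance_m <= 0) stop_parameter("walk_distance_m must be positive")
  if (p$step_length_m <= 0) stop_parameter("step_length_m must be positive")
  if (p$left_right_asymmetry < 0 || p$left_right_asymmetry >= 1)
    stop_parameter("left_right_asymmetry must be in [0, 1)")
  if (p$noise_sd_m < 0) stop_parameter("noise_sd_m must be non-negative")
  if (p$stance_fraction <= 0.5 || p$stance_fraction >= 0.9)
    stop_parameter("stance_fraction must be in (0.5, 0.9)")
  invisible(p)
}

#' Healthy-control group profile
#'
#' Subtask durations, gait speed, step geometry and covariate distributions
#' at the magnitudes reported for cognitively healthy older adults on the
#' 3-m TUG (gait speed 0.57 m/s, step length 40 cm, age 68.5 +/- 2.6 years,
#' GDS 1.2 +/- 1.3).
#'
#' @param ... Overrides passed to \code{\link{tug_profile}}.
#' @return A \code{tug_profile}.
#' @export
hc_profile <- function(...) tug_profile(...)

#' Alzheimer's-disease group profile
#'
#' Slower, shorter-stepped gait with longer transfers and turn, and older,
#' more depressed covariates (gait speed 0.34 m/s, step length 31 cm,
#' turning 5.75 s, age 75.8 +/- 7.2 years, GDS 6.3 +/- 5.2).
#'
#' @param ... Overrides passed to \code{\link{tug_profile}}.
#' @return A \code{tug_profile}.
#' @export
ad_profile <- function(...) {
  defaults <- list(sit_to_stand_s = 2.91, turning_s = 5.75,
                   stand_to_sit_s = 4.18, gait_speed_mps = 0.34,
                   step_length_m = 0.31, step_width_m = 0.15,
                   step_height_m = 0.10, left_right_asymmetry = 0.20,
                   age_mean = 75.75, age_sd = 7.17,
                   gds_mean = 6.30, gds_sd = 5.19)
  args <- utils::modifyList(defaults, list(...))
  do.call(tug_profile, args)
}

## gait schedule -------------------------------------------------------------

# Landing times, landing positions (sagittal, from path start) and toe-off
# times for one straight walking leg. Step 1 is led by the right foot.
plan_walk_leg <- function(profile) {
  v <- profile$gait_speed_mps
  if (is.finite(profile$cadence_steps_per_min)) {
    tau <- 60 / profile$cadence_steps_per_min
    L <- v * tau
  } else {
    L <- profile$step_length_m
    tau <- L / v
  }
  dist <- profile$walk_distance_m
  n_steps <- round(dist / L)
  if (n_steps < 2)
    stop_parameter(
      "profile implies %d step(s) per walking leg; at least 2 required",
      n_steps)
  a <- profile$left_right_asymmetry
  # alternating right/left with stride (= one right + one left step) preserved
  fac <- rep(c(2 / (2 - a), 2 * (1 - a) / (2 - a)), length.out = n_steps)
  lens <- L * fac
  lens <- lens * dist / sum(lens)           # fit the walkway exactly
  D <- dist / v
  taus <- tau * fac
  taus <- taus * D / sum(taus)              # fit the walking duration exactly
  lands <- cumsum(taus)
  # swing must fit inside the shorter step interval so that every contact
  # retains a double-support overlap
  swing <- (1 - profile$stance_fraction) * 2 * min(taus)
  list(foot = rep(c("right", "left"), length.out = n_steps),
       lens = lens, sag = cumsum(lens), lands = lands, taus = taus,
       swing = swing, duration = D, n_steps = n_steps)
}

# Evaluate one foot's sagittal position and lift for frame times t (relative
# to leg start). `offs`/`lands` are that foot's swing windows; `sags` its
# plant positions with sags[1] the initial stance position.
eval_foot_track <- function(t, offs, lands, sags, step_height) {
  pos <- rep(sags[1], length(t))
  lift <- numeric(length(t))
  if (length(offs) == 0) return(list(pos = pos, lift = lift))
  breaks <- as.vector(rbind(offs, lands))
  idx <- findInterval(t, breaks)
  swinging <- idx %% 2L == 1L
  planted <- !swinging
  pos[planted] <- sags[idx[planted] / 2L + 1L]
  if (any(swinging)) {
    j <- (idx[swinging] + 1L) / 2L
    tau <- (t[swinging] - offs[j]) / (lands[j] - offs[j])
    pos[swinging] <- sags[j] + (sags[j + 1L] - sags[j]) * (1 - cos(pi * tau)) / 2
    lift[swinging] <- step_height * sin(pi * tau)
  }
  list(pos = pos, lift = lift)
}

# Split a leg plan into per-foot swing windows and plant sequences.
foot_windows <- function(plan) {
  out <- list()
  for (f in c("right", "left")) {
    k <- which(plan$foot == f)
    lands <- plan$lands[k]
    offs <- lands - plan$swing
    sags <- c(0, plan$sag[k])
    out[[f]] <- list(offs = offs, lands = lands, sags = sags,
                     strikes = lands, toeoffs = offs)
  }
  out
}

## skeleton assembly ---------------------------------------------------------

# Rigid offsets along the body axes; y offsets relative to the hanging
# shoulder line, lateral offsets signed toward the subject's right.
ARM_DROPS <- c(ElbowLeft = -0.28, WristLeft = -0.52, HandLeft = -0.60,
               HandTipLeft = -0.68, ThumbLeft = -0.58,
               ElbowRight = -0.28, WristRight = -0.52, HandRight = -0.60,
               HandTipRight = -0.68, ThumbRight = -0.58)

TRUNK_LEN <- 0.45      # SpineBase -> SpineShoulder (m)
SHOULDER_HALF <- 0.175 # half inter-shoulder width (m)
HIP_STAND_Y <- 0.95    # SpineBase height standing (m)
HIP_SEAT_Y <- 0.48     # SpineBase height seated (m)
FOOT_Y <- 0.05         # resting foot-joint height (m)
PITCH_MAX <- 40 * pi / 180  # peak trunk flexion during transfers (rad)

#' Generate one synthetic TUG recording with ground truth
#'
#' Deterministic given \code{(profile, seed)}. The emitted signals carry the
#' canonical TUG shapes: the shoulder-center height dips through a local
#' minimum before rising to the standing plateau during sit-to-stand (and
#' mirrored during stand-to-sit), foot depth traces alternate stance plateaus
#' and swing ramps, and the inter-shoulder lateral distance collapses and
#' recovers through the turn.
#'
#' @param profile A \code{\link{tug_profile}}.
#' @param seed Integer seed for the sensor-noise and covariate draws.
#' @param subject A \code{\link{subject_meta}}; defaults to an anonymous
#'   subject with covariates drawn from the profile's distributions.
#' @return List with elements \code{recording} (a
#'   \code{\link{skeletal_recording}}) and \code{ground_truth} (subtask
#'   boundaries, per-foot heel-strike/toe-off times, per-step lengths and
#'   times, and the realized kinematic parameters).
#' @export
#' @examples
#' sim <- generate_recording(tug_profile(), seed = 42)
#' sim$ground_truth$segments
generate_recording <- function(profile, seed = 1L, subject = NULL) {
  validate_profile(profile)
  with_seed(seed, generate_recording_impl(profile, subject))
}

generate_recording_impl <- function(profile, subject = NULL) {
  fs <- profile$frame_rate
  plan <- plan_walk_leg(profile)
  D <- plan$duration
  b0 <- profile$lead_in_s
  b1 <- b0 + profile$sit_to_stand_s
  b2 <- b1 + D
  b3 <- b2 + profile$turning_s
  b4 <- b3 + D
  b5 <- b4 + profile$stand_to_sit_s
  total <- b5 + profile$lead_out_s
  n <- round(total * fs)
  t <- (seq_len(n) - 1L) / fs

  rt <- profile$turn_radius_m
  z1 <- 0.75                                  # turn-end depth (near camera)
  z0 <- z1 + profile$walk_distance_m          # standing start depth
  z_seat <- z0 + 0.20                         # seated body depth

  ## heading (0 = facing +z/away, pi = facing the camera)
  psi <- rep(pi, n)
  in_turn <- t >= b2 & t < b3
  theta <- pi * (t[in_turn] - b2) / profile$turning_s
  psi[in_turn] <- pi - theta
  psi[t >= b3] <- 0

  ## body-center horizontal path
  cx <- numeric(n); cz <- numeric(n)
  pre <- t < b0
  rise <- t >= b0 & t < b1
  wout <- t >= b1 & t < b2
  wback <- t >= b3 & t < b4
  sit <- t >= b4 & t < b5
  post <- t >= b5
  u_rise <- (t[rise] - b0) / profile$sit_to_stand_s
  u_sit <- (t[sit] - b4) / profile$stand_to_sit_s
  cz[pre] <- z_seat
  cz[rise] <- z_seat - 0.20 * smoothstep((u_rise - 0.25) / 0.75)
  cz[wout] <- z0 - profile$gait_speed_mps * (t[wout] - b1)
  cz[in_turn] <- z1 - rt * sin(theta)
  cx[in_turn] <- rt * (1 - cos(theta))
  cz[wback] <- z1 + profile$gait_speed_mps * (t[wback] - b3)
  cx[wback] <- 2 * rt
  cz[sit] <- z0 + 0.20 * smoothstep((u_sit - 0.1) / 0.65)
  cx[sit] <- 2 * rt
  cz[post] <- z_seat
  cx[post] <- 2 * rt

  ## hip height and trunk pitch
  yhip <- rep(HIP_STAND_Y, n)
  phi <- numeric(n)
  yhip[pre] <- HIP_SEAT_Y
  yhip[rise] <- HIP_SEAT_Y +
    (HIP_STAND_Y - HIP_SEAT_Y) * smoothstep((u_rise - 0.25) / 0.75)
  phi[rise] <- PITCH_MAX * sin(pi * pmin(u_rise / 0.7, 1))
  yhip[sit] <- HIP_STAND_Y -
    (HIP_STAND_Y - HIP_SEAT_Y) * smoothstep(u_sit / 0.75)
  phi[sit] <- PITCH_MAX * sin(pi * pmax((u_sit - 0.3) / 0.7, 0))
  yhip[post] <- HIP_SEAT_Y

  ## feet
  wins <- foot_windows(plan)
  half_w <- profile$step_width_m / 2
  foot <- list()
  for (f in c("right", "left")) {
    sgn <- if (f == "right") 1 else -1       # toward the subject's right
    fx <- numeric(n); fy <- rep(FOOT_Y, n); fz <- numeric(n)
    # walk-out: path from (0, z0) toward -z; right vector at psi = pi is -x
    start_xy <- c(0, z0)
    fx[t < b2] <- -sgn * half_w
    fz[t < b2] <- z0
    k <- which(wout)
    tr <- eval_foot_track(t[k] - b1, wins[[f]]$offs, wins[[f]]$lands,
                          wins[[f]]$sags, profile$step_height_m)
    fz[k] <- z0 - tr$pos
    fy[k] <- FOOT_Y + tr$lift
    end_out <- c(-sgn * half_w, z0 - wins[[f]]$sags[length(wins[[f]]$sags)])
    # walk-back: path from (2 rt, z1) toward +z; right vector at psi = 0 is +x
    start_back <- c(2 * rt + sgn * half_w, z1)
    k <- which(in_turn)
    s <- smoothstep(((t[k] - b2) / profile$turning_s - 0.15) / 0.7)
    fx[k] <- end_out[1] + (start_back[1] - end_out[1]) * s
    fz[k] <- end_out[2] + (start_back[2] - end_out[2]) * s
    k <- which(t >= b3)
    fx[k] <- start_back[1]
    fz[k] <- start_back[2]
    k <- which(wback)
    tr <- eval_foot_track(t[k] - b3, wins[[f]]$offs, wins[[f]]$lands,
                          wins[[f]]$sags, profile$step_height_m)
    fz[k] <- z1 + tr$pos
    fy[k] <- FOOT_Y + tr$lift
    k <- which(t >= b4)
    fz[k] <- z1 + wins[[f]]$sags[length(wins[[f]]$sags)]
    foot[[f]] <- list(x = fx, y = fy, z = fz)
  }

  ## assemble joints
  fdirx <- sin(psi); fdirz <- cos(psi)        # facing direction
  rlatx <- cos(psi); rlatz <- -sin(psi)       # subject's right, horizontal
  trx <- sin(phi) * fdirx; trym <- cos(phi); trz <- sin(phi) * fdirz

  joints <- kinect_joints()
  xyz <- array(NA_real_, dim = c(n, length(joints), 3),
               dimnames = list(NULL, joints, c("x", "y", "z")))
  put <- function(j, x, y, z) {
    xyz[, j, 1] <<- x; xyz[, j, 2] <<- y; xyz[, j, 3] <<- z
  }
  put("SpineBase", cx, yhip, cz)
  along_trunk <- function(frac)
    list(x = cx + frac * TRUNK_LEN * trx, y = yhip + frac * TRUNK_LEN * trym,
         z = cz + frac * TRUNK_LEN * trz)
  sm <- along_trunk(0.5);  put("SpineMid", sm$x, sm$y, sm$z)
  ss <- along_trunk(1.0);  put("SpineShoulder", ss$x, ss$y, ss$z)
  nk <- along_trunk(1.16); put("Neck", nk$x, nk$y, nk$z)
  hd <- along_trunk(1.42); put("Head", hd$x, hd$y, hd$z)
  for (side in c("Left", "Right")) {
    sgn <- if (side == "Right") 1 else -1
    shx <- ss$x + sgn * SHOULDER_HALF * rlatx
    shz <- ss$z + sgn * SHOULDER_HALF * rlatz
    shy <- ss$y - 0.02
    put(paste0("Shoulder", side), shx, shy, shz)
    for (j in grep(paste0(side, "$"),
                   names(ARM_DROPS), value = TRUE)) {
      put(j, shx, shy + ARM_DROPS[[j]], shz)
    }
    hipx <- cx + sgn * 0.10 * rlatx
    hipz <- cz + sgn * 0.10 * rlatz
    put(paste0("Hip", side), hipx, yhip - 0.05, hipz)
    ft <- foot[[tolower(side)]]
    put(paste0("Foot", side), ft$x, ft$y, ft$z)
    put(paste0("Ankle", side), ft$x - 0.03 * fdirx, ft$y + 0.04,
        ft$z - 0.03 * fdirz)
    put(paste0("Knee", side),
        (hipx + ft$x) / 2 + 0.10 * fdirx,
        (yhip - 0.05 + ft$y + 0.04) / 2,
        (hipz + ft$z) / 2 + 0.10 * fdirz)
  }

  if (profile$noise_sd_m > 0)
    xyz <- xyz + stats::rnorm(length(xyz), sd = profile$noise_sd_m)

  if (is.null(subject)) {
    age <- max(45, stats::rnorm(1, profile$age_mean, profile$age_sd))
    gds <- min(15, max(0, round(stats::rnorm(1, profile$gds_mean,
                                             profile$gds_sd))))
    subject <- subject_meta("synthetic", age = age, gds = gds)
  }
  rec <- skeletal_recording(xyz, frame_rate = fs, subject = subject)

  seg_bounds <- c(b0, b1, b2, b3, b4, b5)
  seg_frames <- round(seg_bounds * fs)
  segments <- data.frame(
    label = c("sit_to_stand", "walk_out", "turning", "walk_back",
              "stand_to_sit"),
    start_frame = seg_frames[1:5], end_frame = seg_frames[2:6],
    stringsAsFactors = FALSE)
  segments$start_s <- segments$start_frame / fs
  segments$end_s <- segments$end_frame / fs

  steps <- rbind(
    data.frame(leg = "out", foot = plan$foot, land_s = b1 + plan$lands,
               length_m = plan$lens, duration_s = plan$taus,
               stringsAsFactors = FALSE),
    data.frame(leg = "back", foot = plan$foot, land_s = b3 + plan$lands,
               length_m = plan$lens, duration_s = plan$taus,
               stringsAsFactors = FALSE))

  events <- do.call(rbind, lapply(c("out", "back"), function(leg) {
    off0 <- if (leg == "out") b1 else b3
    do.call(rbind, lapply(c("right", "left"), function(f)
      data.frame(leg = leg, foot = f,
                 heel_strike_s = off0 + wins[[f]]$strikes,
                 toe_off_s = off0 + wins[[f]]$toeoffs,
                 stringsAsFactors = FALSE)))
  }))

  gt <- structure(list(
    segments = segments, steps = steps, events = events,
    params = list(gait_speed_mps = profile$gait_speed_mps,
                  step_length_m = mean(plan$lens),
                  cadence_steps_per_min = 60 * plan$n_steps / D,
                  n_steps_per_leg = plan$n_steps,
                  walk_leg_s = D,
                  sit_to_stand_s = profile$sit_to_stand_s,
                  turning_s = profile$turning_s,
                  stand_to_sit_s = profile$stand_to_sit_s,
                  total_s = n / fs,
                  standing_shoulder_y = HIP_STAND_Y + TRUNK_LEN,
                  seated_shoulder_y = HIP_SEAT_Y + TRUNK_LEN)),
    class = "tug_ground_truth")
  list(recording = rec, ground_truth = gt)
}

ground_truth_to_list <- function(gt) {
  list(segments = gt$segments, steps = gt$steps, events = gt$events,
       params = gt$params)
}

#' Generate a synthetic cohort with group-dependent kinematics
#'
#' Per-subject profiles are drawn around the group profile with lognormal
#' dispersion (\code{subject_sdlog}) on durations, gait speed and step
#' geometry; covariates (age, GDS) are drawn from the group distributions, so
#' group differences in kinematics arrive confounded with age and GDS, as in
#' real AD/control cohorts.
#'
#' @param n_hc,n_ad Number of control and patient subjects (each >= 1).
#' @param hc_prof,ad_prof Group-level \code{\link{tug_profile}}s.
#' @param seed Integer seed; the cohort is deterministic given
#'   \code{(n_hc, n_ad, profiles, seed)}.
#' @return A \code{\link{tug_cohort}}; each recording carries its
#'   \code{ground_truth} as an attribute.
#' @export
generate_cohort <- function(n_hc, n_ad, hc_prof = hc_profile(),
                            ad_prof = ad_profile(), seed = 1L) {
  if (n_hc < 1 || n_ad < 1) stop_parameter("need at least 1 subject per group")
  with_seed(seed, {
    specs <- c(
      lapply(seq_len(n_hc), function(i)
        list(id = sprintf("hc_%02d", i), group = "HC", prof = hc_prof)),
      lapply(seq_len(n_ad), function(i)
        list(id = sprintf("ad_%02d", i), group = "AD", prof = ad_prof)))
    recs <- lapply(specs, function(sp) {
      p <- sp$prof
      jitter <- function(x) x * stats::rlnorm(1, 0, p$subject_sdlog)
      sp_prof <- tug_profile(
        sit_to_stand_s = jitter(p$sit_to_stand_s),
        turning_s = jitter(p$turning_s),
        stand_to_sit_s = jitter(p$stand_to_sit_s),
        walk_distance_m = p$walk_distance_m,
        gait_speed_mps = jitter(p$gait_speed_mps),
        step_length_m = jitter(p$step_length_m),
        step_width_m = jitter(p$step_width_m),
        step_height_m = jitter(p$step_height_m),
        left_right_asymmetry = min(0.9, p$left_right_asymmetry *
                                     stats::rlnorm(1, 0, p$subject_sdlog)),
        noise_sd_m = p$noise_sd_m,
        age_mean = p$age_mean, age_sd = p$age_sd,
        gds_mean = p$gds_mean, gds_sd = p$gds_sd,
        subject_sdlog = p$subject_sdlog, frame_rate = p$frame_rate,
        lead_in_s = p$lead_in_s, lead_out_s = p$lead_out_s,
        stance_fraction = p$stance_fraction, turn_radius_m = p$turn_radius_m)
      subj <- subject_meta(
        sp$id, group = sp$group,
        age = max(45, stats::rnorm(1, p$age_mean, p$age_sd)),
        gds = min(15, max(0, round(stats::rnorm(1, p$gds_mean, p$gds_sd)))),
        sex = sample(c("F", "M"), 1),
        height_cm = stats::rnorm(1, 167, 8),
        weight_kg = stats::rnorm(1, 68, 10))
      sub_seed <- sample.int(.Machine$integer.max, 1)
      sim <- generate_recording(sp_prof, seed = sub_seed, subject = subj)
      rec <- sim$recording
      attr(rec, "ground_truth") <- sim$ground_truth
      rec
    })
    tug_cohort(recs, provenance = sprintf("synthetic (seed %d)", seed))
  })
}
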