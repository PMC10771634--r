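test_that("generation is deterministic given profile and seed", {
  a <- generate_recording(tug_profile(), seed = 42)
  b <- generate_recording(tug_profile(), seed = 42)
  expect_identical(a$recording$xyz, b$recording$xyz)
  expect_identical(a$ground_truth, b$ground_truth)
  c <- generate_recording(tug_profile(), seed = 43)
  expect_false(identical(a$recording$xyz, c$recording$xyz))
})

test_that("ground-truth walking duration follows distance over speed", {
  sim <- generate_recording(tug_profile(gait_speed_mps = 0.57,
                                        walk_distance_m = 3,
                                        noise_sd_m = 0), seed = 1)
  expect_lt(abs(sim$ground_truth$params$walk_leg_s - 3 / 0.57) / (3 / 0.57),
            0.10)
  segs <- sim$ground_truth$segments
  wo <- segs[segs$label == "walk_out", ]
  expect_equal(wo$end_s - wo$start_s, sim$ground_truth$params$walk_leg_s,
               tolerance = 0.06)
})

test_that("asymmetry controls ground-truth step geometry", {
  sym <- generate_recording(tug_profile(left_right_asymmetry = 0,
                                        noise_sd_m = 0), seed = 1)
  st <- sym$ground_truth$steps
  expect_equal(mean(st$length_m[st$foot == "right"]),
               mean(st$length_m[st$foot == "left"]))
  expect_equal(mean(st$duration_s[st$foot == "right"]),
               mean(st$duration_s[st$foot == "left"]))

  asym <- generate_recording(tug_profile(left_right_asymmetry = 0.25,
                                         noise_sd_m = 0), seed = 1)
  st <- asym$ground_truth$steps
  si <- similarity_index(st$length_m[st$foot == "right"][1],
                         st$length_m[st$foot == "left"][1])
  expect_equal(si, 0.75, tolerance = 1e-9)
})

test_that("degenerate gait profiles are rejected", {
  expect_error(generate_recording(tug_profile(step_length_m = 2.9), seed = 1),
               class = "tug_parameter_error")
  expect_error(tug_profile(gait_speed_mps = -1),
               class = "tug_parameter_error")
  expect_error(tug_profile(left_right_asymmetry = 1),
               class = "tug_parameter_error")
  expect_error(tug_profile(noise_sd_m = -0.1),
               class = "tug_parameter_error")
})

test_that("ground truth is internally consistent for every seed", {
  for (seed in 1:5) {
    sim <- generate_recording(tug_profile(), seed = seed)
    gt <- sim$ground_truth
    expect_equal(gt$params$total_s,
                 n_frames(sim$recording) / sim$recording$frame_rate)
    segs <- gt$segments
    expect_identical(segs$label,
                     c("sit_to_stand", "walk_out", "turning", "walk_back",
                       "stand_to_sit"))
    expect_true(all(diff(c(t(segs[, c("start_frame", "end_frame")]))) >= 0))
    expect_true(all(segs$start_frame < segs$end_frame))
    # five phases tile the span between first and last boundary
    expect_equal(segs$start_frame[-1], segs$end_frame[-5])
  }
})

test_that("faster gait strictly shortens the walking ground truth", {
  speeds <- c(0.3, 0.45, 0.6, 0.9)
  durs <- vapply(speeds, function(v)
    generate_recording(tug_profile(gait_speed_mps = v, noise_sd_m = 0),
                       seed = 1)$ground_truth$params$walk_leg_s, numeric(1))
  expect_true(all(diff(durs) < 0))
})

test_that("generated signals carry the canonical TUG shapes", {
  for (seed in c(2, 7, 19)) {
    sim <- generate_recording(tug_profile(), seed = seed)
    rec <- filter_recording(sim$recording)
    gt <- sim$ground_truth$segments
    y <- rec$xyz[, "SpineShoulder", "y"]
    fs <- rec$frame_rate

    # rise: local minimum below the seated level, then a standing plateau
    rise <- gt[gt$label == "sit_to_stand", ]
    ri <- (rise$start_frame + 1):(rise$end_frame)
    seated_level <- median(y[1:(rise$start_frame)])
    expect_lt(min(y[ri]), seated_level - 0.03)
    expect_gt(y[ri[length(ri)]], seated_level + 0.3)

    # descent: local minimum below the final seated level, slight recovery
    sit <- gt[gt$label == "stand_to_sit", ]
    si <- (sit$start_frame + 1):(sit$end_frame)
    final_level <- median(y[(sit$end_frame + 1):length(y)])
    expect_lt(min(y[si]), final_level - 0.03)

    # turn: inter-shoulder x-distance collapses and recovers
    d <- abs(rec$xyz[, "ShoulderRight", "x"] - rec$xyz[, "ShoulderLeft", "x"])
    turn <- gt[gt$label == "turning", ]
    ti <- (turn$start_frame + 1):(turn$end_frame)
    expect_lt(min(d[ti]), 0.2 * median(d))
    expect_gt(min(d[-ti]), 0.5 * median(d))

    # feet alternate stance plateaus and swing ramps during walking
    wo <- gt[gt$label == "walk_out", ]
    wi <- (wo$start_frame + 1):(wo$end_frame)
    vz <- abs(diff(rec$xyz[wi, "FootRight", "z"])) * fs
    expect_gt(mean(vz < 0.08), 0.35)   # substantial stance time
    expect_gt(max(vz), 0.8)            # and genuine swings
  }
})

test_that("cohorts are labeled, unique, deterministic and group-separated", {
  coh <- generate_cohort(5, 5, seed = 9)
  expect_length(coh$recordings, 10)
  ids <- vapply(coh$recordings, function(r) r$subject$subject_id, "")
  groups <- vapply(coh$recordings, function(r) r$subject$group, "")
  expect_false(anyDuplicated(ids) > 0)
  expect_equal(sum(groups == "HC"), 5)
  expect_equal(sum(groups == "AD"), 5)

  coh2 <- generate_cohort(5, 5, seed = 9)
  expect_identical(lapply(coh$recordings, `[[`, "xyz"),
                   lapply(coh2$recordings, `[[`, "xyz"))

  big <- generate_cohort(20, 20, seed = 10)
  gv <- vapply(big$recordings, function(r)
    attr(r, "ground_truth")$params$gait_speed_mps, numeric(1))
  grp <- vapply(big$recordings, function(r) r$subject$group, "")
  expect_lt(mean(gv[grp == "AD"]), mean(gv[grp == "HC"]))
  age <- vapply(big$recordings, function(r) r$subject$age, numeric(1))
  gds <- vapply(big$recordings, function(r) r$subject$gds, numeric(1))
  expect_gt(mean(age[grp == "AD"]), mean(age[grp == "HC"]))
  expect_gt(mean(gds[grp == "AD"]), mean(gds[grp == "HC"]))
})
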