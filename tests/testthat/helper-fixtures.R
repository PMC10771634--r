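# Shared fixtures, computed once per test run.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# default-profile simulation, filtered, with segmentation and features
default_sim <- function() cached("default_sim", {
  sim <- generate_recording(tug_profile(), seed = 101)
  rec <- filter_recording(sim$recording)
  seg <- segment_tug(rec)
  list(raw = sim$recording, rec = rec, gt = sim$ground_truth, seg = seg,
       features = extract_features(rec, seg))
})

# hand-written two-frame recording: all joints at a resting pose, with
# SpineShoulder y = 0.90 then 0.95
two_frame_recording <- function() {
  joints <- kinect_joints()
  xyz <- array(0, dim = c(2, 25, 3),
               dimnames = list(NULL, joints, c("x", "y", "z")))
  xyz[, , "y"] <- 0.5
  xyz[, , "z"] <- 2
  xyz[, "SpineShoulder", "y"] <- c(0.90, 0.95)
  skeletal_recording(xyz, frame_rate = 20,
                     subject = subject_meta("fix2", group = "HC",
                                            age = 70, gds = 2))
}

# keep a frame subset of a recording (1-based indices)
crop_recording <- function(rec, idx) {
  skeletal_recording(rec$xyz[idx, , , drop = FALSE],
                     frame_rate = rec$frame_rate, subject = rec$subject)
}

# small synthetic feature table: two Gaussian classes, k informative
# features with the given separation (in SDs), rest pure noise
toy_feature_table <- function(n_per_group = 20, k_informative = 3,
                              separation = 2, n_features = 8, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  group <- rep(c("HC", "AD"), each = n_per_group)
  x <- matrix(rnorm(n * n_features), n, n_features)
  for (j in seq_len(k_informative))
    x[group == "AD", j] <- x[group == "AD", j] + separation
  colnames(x) <- sprintf("f%02d", seq_len(n_features))
  feature_table(x, group = group,
                age = rnorm(n, 70, 5), gds = pmax(0, rnorm(n, 3, 2)))
}
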