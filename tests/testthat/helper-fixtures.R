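# Shared in-code fixtures. Everything is generated at test time from
# seeded generators; nothing is stored on disk.

# A small, fast parameter set whose front reaches the traveling-wave
# regime within a short simulated time (used where the full founder
# presets would be needlessly slow).
fast_rd_params <- function(...) {
  rd_params(Db = 0.02, Dc = 0.036, k0 = 0.65, KD = 2, kg = 1.23,
            Kg = 0.13, Y = 5e7, c0 = 1, domain_radius = 3, ...)
}

# Straight constant-speed trajectory sampled at fps.
straight_trajectory <- function(n = 60, speed = 20, fps = 30) {
  tt <- (seq_len(n) - 1) / fps
  d <- data.frame(frame = seq_len(n) - 1L, time_s = tt,
                  x_um = speed * tt, y_um = 0, cell_id = "straight")
  attr(d, "frame_rate") <- fps
  class(d) <- c("swim_trajectory", "data.frame")
  d
}

# Circular motion at constant angular rate Omega (rad/s).
circular_trajectory <- function(n = 90, radius = 20, Omega = 2, fps = 30) {
  tt <- (seq_len(n) - 1) / fps
  d <- data.frame(frame = seq_len(n) - 1L, time_s = tt,
                  x_um = radius * cos(Omega * tt),
                  y_um = radius * sin(Omega * tt), cell_id = "circle")
  attr(d, "frame_rate") <- fps
  class(d) <- c("swim_trajectory", "data.frame")
  d
}
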