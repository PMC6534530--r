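# shared fixtures and small utilities for the suite

kc12 <- function(chi = 0.2, delta_scale = 1) {
  kc_params(alpha = 270, beta = 0.1, gamma = 35, e_A = 95, e_R = 100,
            chi = chi, delta_scale = delta_scale)
}

all_presets <- c("kc2012", "kc-adapted", "kc-reparam", "piecewise",
                 "oscillator2014")

# smallest unsigned difference between two line-field angles (mod pi)
angle_diff <- function(a, b) {
  d <- abs(a - b) %% pi
  pmin(d, pi - d)
}

# sample the true field angle on the pixel grid of a rendered image
field_truth_matrix <- function(field, res) {
  centers <- (seq_len(res) - 0.5) / res
  xy <- cbind(rep(centers, times = res), rep(centers, each = res))
  matrix(field_angle(field, xy), nrow = res, byrow = TRUE)
}

# 2-D rotation matrix
rot2 <- function(phi) matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)

# torus arithmetic mirrors of the package's conventions
wrap_torus <- function(p) p - floor(p)
torus_delta <- function(d) d - floor(d + 0.5)
torus_err <- function(a, b) torus_delta(a - b)
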