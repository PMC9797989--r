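# shared fixtures: small fast anatomies and closed-form oracles

quick_params <- function(...) {
  lv_shape_params(n_frames = 6, n_boundary_points = 120, ...)
}

quick_series <- function(...) generate_anatomy(quick_params(...))

# area of the intersection of two discs (lens), closed form
circle_lens_area <- function(r1, r2, d) {
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(pi * min(r1, r2)^2)
  a1 <- r1^2 * acos((d^2 + r1^2 - r2^2) / (2 * d * r1))
  a2 <- r2^2 * acos((d^2 + r2^2 - r1^2) / (2 * d * r2))
  a3 <- 0.5 * sqrt((-d + r1 + r2) * (d + r1 - r2) * (d - r1 + r2) * (d + r1 + r2))
  a1 + a2 - a3
}

# n-point circle boundary
circle_boundary <- function(r = 25, n = 200, centre = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(centre[1] + r * cos(th), centre[2] + r * sin(th))
}

# brute-force double-loop Hausdorff (independent of the packaged one)
hausdorff_bruteforce <- function(A, B) {
  dab <- 0
  for (i in seq_len(nrow(A))) {
    best <- Inf
    for (j in seq_len(nrow(B))) {
      best <- min(best, sqrt(sum((A[i, ] - B[j, ])^2)))
    }
    dab <- max(dab, best)
  }
  dba <- 0
  for (j in seq_len(nrow(B))) {
    best <- Inf
    for (i in seq_len(nrow(A))) {
      best <- min(best, sqrt(sum((A[i, ] - B[j, ])^2)))
    }
    dba <- max(dba, best)
  }
  max(dab, dba)
}

# assemble a wss_record directly from tau component matrices
make_wss_record <- function(times, tau_x, tau_y, systole = range(times)) {
  structure(list(times = times, tau_x = tau_x, tau_y = tau_y,
                 sites = NULL, systole_window = systole),
            class = "wss_record")
}
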