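# fixtures built in code; no data files

# a small deterministic track: straight line along x
straight_track <- function(n = 3, step = 1, frame_interval = 10) {
  trajectory("straight", t = (0:(n - 1)) * frame_interval,
             x = (0:(n - 1)) * step, y = rep(0, n),
             frame_interval = frame_interval)
}

# random-walk track with Gaussian steps
random_track <- function(id = "rw", n = 100, sd = 1, seed = 1,
                         frame_interval = 10) {
  set.seed(seed)
  trajectory(id, t = (0:(n - 1)) * frame_interval,
             x = cumsum(c(0, rnorm(n - 1, 0, sd))),
             y = cumsum(c(0, rnorm(n - 1, 0, sd))),
             frame_interval = frame_interval)
}

# noise-free single-site binding table: green fixed, free red swept
binding_table <- function(kd = 50, green = 50,
                          free_red = c(10, 25, 50, 100, 200, 400)) {
  cx <- green * free_red / (kd + free_red)
  data.frame(green_total = rep(green, length(free_red)),
             red_total = free_red + cx,
             complex = cx)
}

# noise-free model correlation curve
model_curve <- function(channel = "green_auto", N = 8,
                        f = c(0.6, 0.4), tau_d = c(3e-4, 5e-3),
                        T_trip = 0.15, tau_t = 5e-6,
                        lags = 10^seq(-6, 0, length.out = 160)) {
  cfg <- if (channel == "cross")
    acf_fit_config(n_components = 1, triplet = FALSE)
  else acf_fit_config(n_components = length(tau_d), triplet = T_trip > 0)
  correlation_curve(channel, lags,
                    correlation_model(lags, N, f, tau_d, T_trip, tau_t,
                                      cfg))
}
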