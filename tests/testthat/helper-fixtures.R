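# shared fixtures, all generated in code

# a minimal 2-sample trace
tiny_trace <- function(plant_id = "p1", test_label = "A") {
  force_rotation_trace(
    data.frame(index = 0:1, rotation_deg = c(0, 5), force_N = c(0, 2.5)),
    load_height_m = 0.64, plant_id = plant_id, test_label = test_label
  )
}

# hand-built hysteretic force-deflection pairs: loading points on slope k_load,
# unloading points on slope k_unload (both through the origin)
hysteretic_fd <- function(k_load = 50, k_unload = 40, n_leg = 50,
                          max_defl = 0.15) {
  x_load <- seq(0, max_defl, length.out = n_leg)
  x_unload <- seq(max_defl, 0, length.out = n_leg + 2)[-c(1, n_leg + 2)]
  data.frame(
    deflection_m = c(x_load, x_unload),
    force_N = c(k_load * x_load, k_unload * x_unload),
    leg = rep(c("load", "unload"), c(n_leg, n_leg))
  )
}

# noiseless proportional trace with given slope
linear_trace <- function(k, plant_id = "p1", test_label = "A",
                         load_height_m = 0.64) {
  simulate_trace(k, protocol_config(noise_sd_N = 0, hysteresis_factor = 1,
                                    load_height_m = load_height_m),
                 plant_id = plant_id, test_label = test_label)
}

# OLS slope computed independently of the package's fitting code
oracle_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}
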