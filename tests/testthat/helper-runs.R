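# Shared builders for simulated fixtures. Everything is generated in code at
# test time; seeds are fixed so expectations are stable.

# minimal one-species-per-class composition
tiny_composition <- function() {
  data.frame(cn = c(30, 37, 41, 43), db = 0:3,
             geometry = c("", "cis", "cis", "cis"),
             abundance_pct = rep(100, 4),
             class_share_pct = c(10, 20, 30, 40))
}

# a single-species run, noiseless by default
single_species_run <- function(cn = 32, db = 1, seed = 7, noise_sd = 0,
                               baseline_rate = 0, ...) {
  comp <- data.frame(cn = cn, db = db,
                     geometry = ifelse(db > 0, "cis", ""),
                     abundance_pct = 100, class_share_pct = 100)
  simulate_run(comp, retention = retention_model(rt_jitter_rel = 0),
               seed = seed, noise_sd = noise_sd,
               baseline_rate = baseline_rate, ...)
}

# deterministic (jitter-free, noiseless) run of an arbitrary composition
clean_run <- function(comp, seed = 7, ...) {
  simulate_run(comp, retention = retention_model(rt_jitter_rel = 0),
               seed = seed, noise_sd = 0, baseline_rate = 0, ...)
}

# noiseless Gaussian EIC built directly (independent of the simulator)
gaussian_trace <- function(rt, mu, sigma, area = 1) {
  data.frame(rt = rt, intensity = area * dnorm(rt, mu, sigma))
}
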