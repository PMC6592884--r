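# One-time moment-matching of the default regime-response intercepts to the
# target per-regime chlorophyll-a means (28.6 / 24.1 / 26.7 mg/m3, cold to
# warm). Run from the package root after changing any generator default,
# then freeze the printed intercepts into default_regime_effects().
suppressMessages(devtools::load_all("."))

targets <- c(diatom = 28.6, transition = 24.1, cyanobacteria = 26.7)
intercepts <- bloomregime:::default_regime_effects(TRUE)$intercept

for (iter in 1:4) {
  eff <- bloomregime:::default_regime_effects(TRUE)
  eff$intercept <- intercepts
  cfg <- generator_config(n_days = 36500, seed = 12345, regime_effects = eff)
  sim <- simulate_monitoring(cfg)
  m <- tapply(sim$data$CHLA, sim$truth$regime, mean)
  cat(sprintf("iter %d means: %s\n", iter,
              paste(sprintf("%.3f", m), collapse = " ")))
  intercepts <- intercepts + log(targets / as.numeric(m[names(targets)]))
}
cat(sprintf("calibrated intercepts: %.4f %.4f %.4f\n",
            intercepts[1], intercepts[2], intercepts[3]))
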