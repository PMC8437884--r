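# Shared fixtures: small deterministic banks and simulated trials.

# small bank with well-separated intercepts; slopes recycled over items
small_bank <- function(K = 3, ncat = 3, slopes = c(2.0, 1.6, 2.4, 1.9, 2.2),
                       s = 0.8) {
  items <- lapply(seq_len(K), function(k) {
    a <- slopes[(k - 1) %% length(slopes) + 1]
    cc <- stats::qlogis(((ncat - 1):1) / ncat) * 2 - 0.2 * k
    graded_item(paste0("i", k), a, cc, s = s)
  })
  item_bank(items)
}

# single-site trial without dropout, for likelihood/estimation fixtures
sim_fixture <- function(spec, params, bank, n, seed, keep_latents = FALSE) {
  des <- trial_design(spec, params, bank, n_sites = 1,
                      size_range = c(n, n), target_n = n,
                      retention = rep(1, spec$T), missing_baseline = 0,
                      seed = seed)
  simulate_trial(des, keep_latents = keep_latents)
}

# two-tier generating values mirroring the published two-tier fit
two_tier_truth <- function(bank) {
  sp <- two_tier_spec(length(bank$items), 3)
  p <- default_start(sp, bank)
  p$mu[] <- c(1.43, 0.60, 0.35)
  p$Sigma[] <- matrix(c(0.73, 0.33, 0.28,
                        0.33, 0.96, 0.89,
                        0.28, 0.89, 1.13), 3)
  p$s[] <- rep_len(c(0.96, 1.16, 0, 1.14, 0.64, 0.33, 1.17, 1.33),
                   length(bank$items))
  list(spec = sp, params = p)
}
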