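# Lazily computed, memoized design/MC results shared across test files.
# The optimized schemes and the 1000-replicate recovery study are the most
# expensive objects in the suite; they are computed once per test run.

.design_cache <- new.env(parent = emptyenv())

cached <- function(name, compute) {
  if (!exists(name, envir = .design_cache)) {
    assign(name, compute(), envir = .design_cache)
  }
  get(name, envir = .design_cache)
}

cached_designs <- function() {
  cached("designs", function() {
    p <- nominal_params()
    prior <- make_b1_prior()
    cfg <- design_config(n_starts = 25)
    list(
      params = p, prior = prior, config = cfg,
      cfa = optimize_cfa(p, design_weights(p), prior),
      vfa_k = optimize_vfa(p, design_weights(p), prior, cfg, seed = 7),
      vfa_r1s = optimize_vfa(p, design_weights(p, "R1S"), prior, cfg,
                             seed = 7),
      vfa_r1p = optimize_vfa(p, design_weights(p, "R1P"), prior, cfg,
                             seed = 7),
      vfa_all = optimize_vfa(p, design_weights(p, c("k", "R1S", "R1P")),
                             prior, cfg, seed = 7))
  })
}

# shared standard-normal noise cube for the scheme-comparison MC
cached_noise <- function() {
  cached("noise", function() {
    vfadesign:::draw_standard_noise(91, 1000, seed = 11)
  })
}

cached_mc <- function() {
  cached("mc", function() {
    d <- cached_designs()
    noise <- cached_noise()
    lapply(list(cfa = d$cfa, vfa_k = d$vfa_k, vfa_r1s = d$vfa_r1s,
                vfa_r1p = d$vfa_r1p, vfa_all = d$vfa_all),
           function(des) mc_distribution(des$scheme, d$params, nominal_sigma,
                                         1000L, noise = noise))
  })
}
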