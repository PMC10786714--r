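# Shared simulation fixtures. Building a mosaic panel is the slow part of
# every end-to-end test, so the default configuration/panel pair is built
# once per test run and reused; tests that need different geometry build
# their own.

shared_mosaic_cfg <- function() mosaic_config()

.shared_panel_env <- new.env(parent = emptyenv())

shared_panel <- function() {
  if (is.null(.shared_panel_env$panel)) {
    cfg <- shared_mosaic_cfg()
    set.seed(777)
    .shared_panel_env$panel <- simulate_panel(cfg$n_panel, mosaic_sites(cfg))
  }
  .shared_panel_env$panel
}

# The simulated marker density is 150 SNPs/cM, well below the ~220/cM of
# the dense array the default caller is tuned for; evaluation runs on
# simulated data therefore use a density floor scaled to the simulation
# (about half the simulated density).
sim_caller <- function(...) {
  caller_params(density_min_snps_per_cm = 75, ...)
}

sim_fit <- function(sim, ...) {
  ibd_hmm(sim$gm, sim$sites, c("ind1", "ind2"),
          caller = sim_caller(...), keep_trace = FALSE)
}
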