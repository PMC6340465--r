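# Shared simulation fixtures for the heavier end-to-end tests, built once per
# test run on first use. The default-condition dataset uses the study design
# (sample sizes, divergence calibration, SDR placement) at a 2-Mb scale.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

master_sim <- function() {
  fixture("master_sim", function() {
    suppressMessages(simulate_scenario(scenario_config(seed = 2025)))
  })
}

# per-window simulation stream: class label + scenario -> list of hap windows
stream_windows <- function(scenario, label, n, seed, window_bp = 5e4,
                           config_args = list()) {
  cfg <- do.call(scenario_config,
                 utils::modifyList(list(scenario = scenario, seed = seed),
                                   config_args))
  md <- scenario_samples(cfg)
  set.seed(seed)
  males <- md$sample_id[md$species == "pungitius" & md$sex == "male"]
  y_map <- stats::setNames(sample(c("A", "B"), length(males), replace = TRUE),
                           males)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(seed + 7 * i)
    gen <- simulate_window_genealogy(cfg, label, y_map)
    hap <- drop_mutations(gen, cfg$mu, window_bp)
    attr(hap, "y_tips") <- attr(gen, "y_tips")
    out[[i]] <- hap
  }
  list(windows = out, metadata = md, y_map = y_map, config = cfg,
       window_bp = window_bp)
}
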