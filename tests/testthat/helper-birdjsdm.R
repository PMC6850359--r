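# shared fixtures and independent oracles, built in code

# a small observation table: 2 sites x 2 visits x 2 points
make_observations <- function() {
  data.frame(
    site_id = rep(c("A", "B"), each = 8),
    visit = rep(rep(1:2, each = 4), 2),
    point_id = rep(rep(1:2, each = 2), 4),
    observer_id = rep(c("o1", "o2", "o2", "o3"), each = 4),
    species = rep(c("Skylark", "Starling"), 8),
    count = c(2, 3, 1, 6, 4, 9, 2, 3, 1, 1, 3, 2, 5, 3, 1, 9),
    distance_m = c(10, 50, 120, 150, 30, 80, 149, 60,
                   20, 40, 100, 151, 90, 10, 70, 140),
    date = rep(c("2011-05-20", "2011-06-10"), each = 4),
    stringsAsFactors = FALSE
  )
}

# exhaustive shortest-window HPD search (independent of hpd_interval)
brute_hpd <- function(x, mass = 0.95) {
  x <- sort(x)
  n <- length(x)
  m <- ceiling(mass * n)
  best <- c(-Inf, Inf)
  for (i in seq_len(n - m + 1)) {
    if (x[i + m - 1] - x[i] < best[2] - best[1])
      best <- c(x[i], x[i + m - 1])
  }
  best
}

# memoized tiny fitted model shared by summary-level tests
tiny_fit_cache <- new.env(parent = emptyenv())
tiny_fit <- function() {
  if (is.null(tiny_fit_cache$fit)) {
    set.seed(42)
    tr <- jsdm_truth(n_sites = 15, J = 3, seed = 42)
    ds <- suppressWarnings(simulate_dataset(tr))
    cfg <- jsdm_config(chains = 2, iter = 600, seed = 42)
    tiny_fit_cache$fit <- suppressMessages(
      fit_model(ds$counts, ds$design, cfg))
    tiny_fit_cache$truth <- tr
    tiny_fit_cache$dataset <- ds
  }
  tiny_fit_cache
}
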