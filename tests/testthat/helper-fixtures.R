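# Expensive shared fixtures, built once per test run and cached.

.suite_cache <- new.env(parent = emptyenv())

# The suite's overlap classifier, trained at the package defaults.
suite_model <- function() {
  if (is.null(.suite_cache$model))
    .suite_cache$model <- train_overlap_model(seed = 1007L)
  .suite_cache$model
}

# Three seeds x 15 fabricated images under the default study conditions,
# counted with the suite model: the Experiment-3-style evaluation set.
suite_runs <- function() {
  if (is.null(.suite_cache$runs)) {
    cfg <- scc_config()
    model <- suite_model()
    .suite_cache$runs <- lapply(1:3, function(s) {
      batch <- fabricate_batch(15L, synthetic_spec(), cfg, seed = 100L + s)
      gt <- vapply(batch, function(b) b$truth$gt_count, integer(1))
      res <- lapply(batch, function(b)
        count_cells(b$image, cfg, model, image_id = b$image_id))
      list(seed = 100L + s, gt = gt, results = res,
           counts = vapply(res, function(r) r$total_count, integer(1)))
    })
  }
  .suite_cache$runs
}

# A small folder of fabricated PNGs for batch/sweep tests.
suite_folder <- function() {
  if (is.null(.suite_cache$folder)) {
    dir <- file.path(tempdir(), "scc-suite-images")
    spec <- synthetic_spec(n_circles = c(8L, 15L), radius_range = c(11, 15),
                           cluster_probs = c(single = 1, pair = 0, triple = 0),
                           width = 512L, height = 512L)
    fabricate_batch(3L, spec, scc_config(), seed = 77L, dir = dir)
    .suite_cache$folder <- dir
  }
  .suite_cache$folder
}
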