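# shared fixtures: built once per test run, all seeded

fixture_env <- new.env()

# the default seed-42 calibration world used across modules
default_fixture <- function() {
  if (is.null(fixture_env$ps)) fixture_env$ps <- build_calibration_fixture(42)
  fixture_env$ps
}

default_model <- function() {
  if (is.null(fixture_env$model)) {
    fixture_env$model <- calibrate_patch_set(default_fixture())
  }
  fixture_env$model
}

table1_csv <- function(which) {
  system.file("extdata", paste0("confusion_", which, ".csv"),
              package = "endohsi", mustWork = TRUE)
}

# independent normal-equations least-squares oracle: solve B minimising
# ||B V - target||_F by solving the normal equations directly
normal_equations_fit <- function(V, target) {
  # V: n_terms x n ; target: k x n ; returns k x n_terms
  t(solve(V %*% t(V), V %*% t(target)))
}

# brute-force PR-curve AP oracle on a single-image toy case
brute_force_ap <- function(conf, is_tp, n_truth) {
  ord <- order(-conf)
  tp <- cumsum(is_tp[ord]); fp <- cumsum(!is_tp[ord])
  recall <- tp / n_truth
  precision <- tp / (tp + fp)
  mean(sapply(seq(0, 1, 0.01), function(r) {
    ok <- recall >= r
    if (!any(ok)) 0 else max(precision[ok])
  }))
}

# test-local mirrors of small internal utilities
as_float32 <- function(x) endohsi:::as_float32(x)
round_half_up <- function(x, digits = 2) endohsi:::round_half_up(x, digits)
empty_boxes <- function() endohsi:::empty_boxes()
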