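# Shared small renders, cached per test run: unit tests use a reduced raster
# (4 scans, 1024 x 256) which keeps sub-micron geometry but renders ~4x faster
# than the default acquisition raster.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

small_phantom <- function(...) phantom_spec(...)

small_volume <- function(spec, truth = make_phantom(spec), n_scans = 4L,
                         width = 256L) {
  render_volume(truth, spec, n_scans = n_scans, width = width)
}

noiseless_case <- function() cached("noiseless", {
  spec <- phantom_spec()
  truth <- make_phantom(spec)
  list(spec = spec, truth = truth, volume = small_volume(spec, truth))
})

noisy_case <- function() cached("noisy", {
  spec <- phantom_spec(speckle_sigma = 0.3, outlier_column_fraction = 0.2, seed = 7L)
  truth <- make_phantom(spec)
  list(spec = spec, truth = truth, volume = small_volume(spec, truth))
})

# compact hand-built cohort used by the survival unit tests
hand_cohort <- function() {
  tibble::tibble(
    patient_id = c("A", "A", "A", "B", "B", "B", "B", "B", "C", "C"),
    group = c(rep("rejected", 3), rep("clear", 5), rep("rejected", 2)),
    age_years = 50, transplant_type = "PK",
    visit_month = c(1, 3, 6, 1, 3, 6, 9, 12, 1, 3),
    endmt_um = c(14, 20, 22, 14, 14.5, 14, 14.2, 14.1, 15, 16),
    cct_um = 600,
    rejection_month = c(rep(9, 3), rep(NA, 5), rep(6, 2)),
    censor_month = c(rep(NA, 3), rep(12, 5), rep(NA, 2)))
}
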