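# Shared fixtures, built once per test run and cached. Everything is
# generated in code; no data files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# Small default-parameter cohort used across metric / radiomics / CNN tests.
small_cohort <- function(n_per_class = 6, seed = 42) {
  fixture(sprintf("cohort_%d_%d", n_per_class, seed), function()
    generate_cohort(n_per_class, n_per_class, phantom_params(), seed = seed))
}

cohort_masks <- function(cohort) lapply(cohort$subjects, `[[`, "mask")

# Noise-free, high-contrast parameters: make tiny trainings converge fast.
crisp_params <- function() {
  phantom_params(hc_mean = 80, pd_mean = 140, hc_sd = 4, pd_sd = 6,
                 texture_sd = 4, background_sd = 4)
}

# A random prediction table over n subjects for property tests.
random_predictions <- function(n, seed) {
  withr::with_seed(seed, {
    sc <- runif(n)
    data.frame(subject_id = sprintf("S%03d", 1:n),
               true_class = sample(c("PD", "HC"), n, replace = TRUE),
               predicted_class = ifelse(sc >= 0.5, "PD", "HC"),
               score = sc, stringsAsFactors = FALSE)
  })
}
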