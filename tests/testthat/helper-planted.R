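# The full-scale planted-network study is expensive, so it is built once
# per test run and shared by the validation tests that need it.

planted_env <- new.env(parent = emptyenv())

planted_study_cached <- function() {
  if (is.null(planted_env$study)) {
    st <- simulate_planted_study(seed = 1)
    st$tmaps <- cohort_tmaps(st$connectome, st$lesions)
    idx <- in_mask_indices(st$grid)
    st$hub_mask <- idx %in% st$hub
    st$lesion_union <- Reduce(`|`, lapply(st$lesions, function(l)
      l$volume$data[idx] == 1))
    planted_env$study <- st
  }
  planted_env$study
}
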