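# Shared builders for small test worlds.

# One adult cohort (age 40+) with given smoking split and a flat-rate chain.
adult_cohort_state <- function(n_current = 1000, n_never = 0, former1 = 0,
                               ages = 40:59) {
  never <- ag_grid(0, ages = ages)
  current <- ag_grid(0, ages = ages)
  never["40", ] <- n_never / 2
  current["40", ] <- n_current / 2
  former <- array(0, c(length(ages), 2, 16))
  former[1, , 1] <- former1 / 2
  smoking_state(never, current, former)
}

adult_rates <- function(cessation = 0, relapse = 0, ages = 40:59) {
  cess <- ag_grid(0, ages = ages)
  cess[, ] <- cessation
  transition_rates(ag_grid(0, ages = ages), cess, relapse, ages = ages)
}

# The Brazil-like bundle is deterministic and moderately expensive to build;
# share one across tests.
brazil_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_brazil_like_fixture()
    cache
  }
})
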