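## Shared fixtures, built once per test run on first use.
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, .fixture_cache)) {
    assign(name, build(), .fixture_cache)
  }
  get(name, .fixture_cache)
}

## 60 s, 8 non-Gaussian sources (5 bands + blink + cardiac + 50 Hz mains)
fix_sim60 <- function() {
  fixture("sim60", function() {
    simulate_recording(synth_config(duration = 60, line_hz = 50, seed = 101))
  })
}

## the default-condition fixture: ~600 one-per-second epochs, 10 min,
## theta/alpha amplitude multiplier 1.5 in the RH state
fix_sim600 <- function() {
  fixture("sim600", function() {
    simulate_recording(synth_config(duration = 602, seed = 202))
  })
}

## epochs + PSD of the default fixture, cut from the raw (unfiltered)
## recording
fix_epochs600 <- function() {
  fixture("epochs600", function() {
    sim <- fix_sim600()
    rec <- rereference(sim$recording)
    extract_epochs(rec, sim$events)
  })
}

## artifact-free 10-minute simulation: isolates the oscillatory class
## contrast from ocular/cardiac interference (removing that interference
## is the ICA stage's job, tested separately)
fix_epochs600_clean <- function() {
  fixture("epochs600_clean", function() {
    sim <- simulate_recording(synth_config(duration = 602,
                                           artifact_rate = 0,
                                           blink_amplitude = 0,
                                           cardiac_amplitude = 0,
                                           seed = 203))
    extract_epochs(rereference(sim$recording), sim$events)
  })
}

## brute-force O(N^2) one-sided periodogram oracle (direct DFT summation)
oracle_periodogram <- function(x) {
  N <- length(x)
  n <- 0:(N - 1)
  half <- floor(N / 2) + 1
  P <- vapply(0:(half - 1), function(k) {
    Mod(sum(x * exp(-2i * pi * k * n / N)))^2 / N
  }, 0)
  dbl <- 2:(half - if (N %% 2 == 0) 1 else 0)
  P[dbl] <- 2 * P[dbl]
  P
}
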