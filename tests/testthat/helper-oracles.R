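# Independent oracles and small fixture builders shared across tests.
# Everything here is deliberately naive/brute-force: these functions must
# stay implementation-independent of the package code they check.

# steady-state gain of a tap vector at frequency f (direct DFT of taps)
fir_gain_oracle <- function(taps, f, rate) {
  abs(sum(taps * exp(-2i * pi * f * (seq_along(taps) - 1) / rate)))
}

# Brute-force exact two-sided Mann-Whitney p by enumerating every
# assignment of the pooled values to group A (midranks, |U - mu| rule).
mw_enum_oracle <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a); n <- length(pooled)
  r <- rank(pooled)
  mu <- na * (n - na) / 2
  u_of <- function(idx) sum(r[idx]) - na * (na + 1) / 2
  u_obs <- u_of(seq_len(na))
  combs <- utils::combn(n, na)
  us <- apply(combs, 2, u_of)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Brute-force reimplementation of the three-step index rule for a cohort
# of responses (data frame with the 13 symptom columns): step 1 group
# scores, step 2 cohort max, step 3 threshold at max/3 (ties labelled 1).
index_rule_oracle <- function(responses) {
  stom <- c("stomach_awareness", "sweating", "nausea", "salivation", "burping")
  head <- c("headache", "fullness_of_head", "blurred_vision")
  fatig <- c("fatigue", "eye_strain", "difficulty_focusing")
  score_fns <- list(
    I_GenDis = function(r) r[["general_discomfort"]],
    I_Dizz = function(r) r[["dizziness_vertigo"]],
    I_Stom = function(r) mean(unlist(r[stom])),
    I_Head = function(r) mean(unlist(r[head])),
    I_Fatig = function(r) mean(unlist(r[fatig])),
    I_PV = function(r) mean(unlist(r[c(stom, "general_discomfort")])),
    I_NM = function(r) mean(unlist(r[c(fatig, head, "general_discomfort")])),
    I_MS = function(r) 0.2 * (r[["general_discomfort"]] +
                                r[["dizziness_vertigo"]] +
                                sum(unlist(r[stom])) + sum(unlist(r[fatig])) +
                                sum(unlist(r[head]))))
  out <- sapply(score_fns, function(fn)
    apply(responses, 1, function(row) fn(as.list(row))))
  out <- matrix(out, nrow = nrow(responses),
                dimnames = list(NULL, names(score_fns)))
  apply(out, 2, function(v) {
    t <- max(v) / 3
    if (t <= 0) rep(0L, length(v)) else as.integer(v >= t)
  })
}

# response/questionnaire builders -------------------------------------------

zero_response <- function() {
  stats::setNames(rep(0L, 13), symptom_names())
}

response_with <- function(...) {
  r <- zero_response()
  v <- c(...)
  r[names(v)] <- as.integer(v)
  r
}

# data frame of n zero responses, optionally with id columns
response_table <- function(n, subject = seq_len(n), protocol = "P0") {
  cbind(data.frame(subject_id = subject, protocol = protocol),
        as.data.frame(matrix(0L, n, 13,
                             dimnames = list(NULL, symptom_names()))))
}

# recording builders ---------------------------------------------------------

tone <- function(freq, rate, dur, amp = 1, phase = 0) {
  amp * sin(2 * pi * freq * seq(0, dur - 1 / rate, by = 1 / rate) + phase)
}

# 64-channel EEG recording from one per-channel generator function
make_eeg <- function(dur = 120, rate = 500, gen = NULL, seed = 42) {
  set.seed(seed)
  labels <- mssignal:::eeg_channel_names()
  n <- dur * rate
  if (is.null(gen)) gen <- function(ch) rnorm(n, 0, 10)
  samples <- t(vapply(seq_along(labels), gen, numeric(n)))
  recording(samples, rate, labels, "EEG")
}

# quick feature table for ML tests: binary label plus noise features, with
# `informative` features shifted by `effect` between classes
make_ml_table <- function(n = 80, p = 19, informative = 1, effect = 2,
                          seed = 99, label = "I_MS") {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  X <- matrix(rnorm(n * p), n, p)
  for (j in seq_len(informative)) X[, j] <- X[, j] + effect * y
  colnames(X) <- feature_names()[seq_len(p)]
  df <- data.frame(X, check.names = FALSE)
  df[[label]] <- y
  df
}

# cached small cohorts (built once per test run)
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, .fixture_cache)) assign(key, builder(), .fixture_cache)
  get(key, .fixture_cache)
}

small_strong_cohort <- function() {
  cached("small_strong", function() {
    sim <- simulate_cohort(6, list(), coupling_preset("strong", seed = 11))
    build_cohort_table(sim$features, compute_indexes(sim$questionnaire))
  })
}

# Heavy shared fixtures for the acceptance checks (built once per run).
# Sizes are the package's calibration-study design: the default cohort is
# the 28-subject study layout; the null-calibration cohort uses 48
# subjects (144 measurements) so the null AUC sampling spread is narrow;
# the recovery cohort uses 200 subjects as the stated recovery condition.

default_cohort83 <- function() {
  cached("default83", function() {
    sim <- simulate_cohort(28, config = coupling_preset("strong", seed = 1))
    list(sim = sim,
         cohort = build_cohort_table(sim$features,
                                     compute_indexes(sim$questionnaire)))
  })
}

null_cohort144 <- function() {
  cached("null144", function() {
    sim <- simulate_cohort(48, list(), coupling_preset("null", seed = 1313))
    list(sim = sim,
         cohort = build_cohort_table(sim$features,
                                     compute_indexes(sim$questionnaire)))
  })
}

strong_cohort600 <- function() {
  cached("strong600", function() {
    sim <- simulate_cohort(200, list(), coupling_preset("strong", seed = 2121))
    build_cohort_table(sim$features, compute_indexes(sim$questionnaire))
  })
}
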