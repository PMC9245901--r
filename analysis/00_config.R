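# Shared settings for the analysis scripts. Three synthetic sessions
# stand in for a recording cohort: same latent-state layout (so states
# can be matched across sessions), different neurons and trials. Sizes
# are kept moderate so the whole sequence runs in a few minutes.

library(neuroethogram)

RESULTS <- "results"
# regenerable per-session data (spike tables, fitted models) are bulky
# intermediates and live under scratch/; results/ keeps the small tables
SESSIONS_DIR <- file.path("scratch", "sessions")
COHORT_SEEDS <- c(101, 102, 103)
MASTER_SEED <- 1

cohort_config <- function(n_neurons) {
  synth_config(K_true = 8, d_true = 3, n_neurons = n_neurons,
               n_trials = 8, roles = c("hide", "seek"),
               mean_trial_duration_s = 40, tag_jitter_s = 0.5,
               tag_mislabel_rate = 0.05, n_free_states = 2)
}
COHORT_NEURONS <- c(9, 12, 15)

HMM_K <- 8
HMM_RESTARTS <- 10
N_NULL <- 2000

session_path <- function(seed) file.path(SESSIONS_DIR, sprintf("s%d", seed))
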