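# Shared setup for the numbered analysis drivers.
#
# Each driver runs one pipeline stage over the default synthetic study
# design, reports what it found, and leaves its tables under results/.
# Intermediate in-memory state is cached under scratch/ so the drivers can
# be run one after another (or rerun individually).

suppressMessages(library(acrpoly))

RESULTS_DIR <- "results"
STATE_FILE <- file.path("scratch", "pipeline_state.rds")
CONFIG <- sim_config(seed = 20260925L)

dir.create(RESULTS_DIR, showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

load_state <- function() {
  if (file.exists(STATE_FILE)) readRDS(STATE_FILE) else list()
}

save_state <- function(state) {
  saveRDS(state, STATE_FILE)
  invisible(state)
}

run_stage <- function(stage) {
  state <- load_state()
  state <- run_pipeline(CONFIG, outdir = RESULTS_DIR, stages = stage,
                        state = state)
  save_state(state)
}
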