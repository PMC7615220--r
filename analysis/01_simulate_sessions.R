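#!/usr/bin/env Rscript
# Generate the synthetic study: virgin-like and late-pregnancy-like (D18)
# imaging sessions, behavioral ethograms for both states, and intracellular
# recording cohorts. All later analysis steps read these from results/.
#
# The state presets plant the contrasts the downstream analyses are meant to
# detect: at D18, more silent neurons, fewer retrieval-responsive neurons,
# stronger and faster pup-evoked responses, weaker object responses; in
# behavior, mass on retrieve -> crouch -> nest_build chains instead of
# sniff -> groom -> nest_enter cycles.

suppressMessages(library(galpop))

out_root <- "results/synthetic"
dir.create(out_root, showWarnings = FALSE, recursive = TRUE)

## imaging sessions: 5 animals per state ------------------------------------
# Full trace matrices are too large to keep as text; the study is defined by
# a manifest of (state, animal, seed) and every later step regenerates its
# sessions from it (generators are pure functions of their configs).
manifest <- expand.grid(animal = 1:5, state = c("Vir", "D18"),
                        stringsAsFactors = FALSE)
manifest$seed <- 100L * manifest$animal + ifelse(manifest$state == "D18",
                                                 50L, 0L)
manifest$n_neurons <- 60L
utils::write.csv(manifest, file.path(out_root, "imaging_manifest.csv"),
                 row.names = FALSE)
gt <- do.call(rbind, lapply(seq_len(nrow(manifest)), function(r) {
  s <- generate_population_session(state_preset_config(
    manifest$state[r], n_neurons = manifest$n_neurons[r],
    seed = manifest$seed[r]))
  data.frame(state = manifest$state[r], animal = manifest$animal[r],
             n_silent_true = sum(s$ground_truth$silent),
             n_bouts = nrow(s$events))
}))
utils::write.csv(gt, file.path(out_root, "imaging_ground_truth.csv"),
                 row.names = FALSE)
cat("imaging: 5 Vir + 5 D18 session configs (60 neurons, 400 s @ 20 Hz)\n")
cat(sprintf("  planted silent neurons/session: Vir %.1f, D18 %.1f\n",
            mean(gt$n_silent_true[gt$state == "Vir"]),
            mean(gt$n_silent_true[gt$state == "D18"])))

## ethograms: 10 animals per state -------------------------------------------
labels <- c("sniff", "groom", "nest_enter", "retrieve", "crouch", "nest_build")
P_vir <- rbind(c(0, .6, .3, .04, .03, .03),
               c(.5, 0, .4, .04, .03, .03),
               c(.55, .35, 0, .04, .03, .03),
               c(.3, .3, .2, 0, .1, .1),
               c(.3, .3, .2, .1, 0, .1),
               c(.3, .3, .2, .1, .1, 0))
P_d18 <- rbind(c(0, .1, .1, .6, .1, .1),
               c(.1, 0, .1, .5, .2, .1),
               c(.1, .1, 0, .5, .2, .1),
               c(.05, .05, .05, 0, .65, .2),
               c(.05, .05, .05, .15, 0, .7),
               c(.1, .1, .1, .3, .4, 0))
rows <- list()
for (state in c("Vir", "D18")) {
  P <- if (state == "Vir") P_vir else P_d18
  for (animal in 1:10) {
    ev <- generate_ethogram(
      ethogram_config(labels, P, dwell_mean = 8, n_bouts = 60,
                      seed = 7000L + 37L * animal +
                        ifelse(state == "D18", 1000L, 0L)),
      timepoint = state, animal_id = sprintf("m%02d", animal))
    # round dwell times to 10 ms, keeping bouts contiguous
    dwell <- pmax(round(ev$offset_s - ev$onset_s, 2), 0.01)
    ev$offset_s <- cumsum(dwell)
    ev$onset_s <- c(0, ev$offset_s[-nrow(ev)])
    ev$animal_id <- sprintf("m%02d", animal)
    ev$timepoint <- state
    rows[[length(rows) + 1L]] <- ev
  }
}
etho <- do.call(rbind, rows)
utils::write.csv(etho, file.path(out_root, "ethograms.csv"),
                 row.names = FALSE)
cat(sprintf("ethograms: %d bouts across 20 animals -> %s\n", nrow(etho),
            file.path(out_root, "ethograms.csv")))

## intracellular cohorts: 25 cells per group ---------------------------------
# Vir cells: active, often with depolarization block, fewer excitatory
# inputs. D18 cells: 40% silent, lower resting potential, no block, more
# and faster sPSCs dominated by EPSCs.
# 20 kHz voltage traces are far too large to store; the cohort is defined by
# its config table and each record is regenerated from its seed on demand
# (generators are pure functions of their configs).
cfg_tab <- do.call(rbind, lapply(c("Vir", "D18"), function(grp) {
  i <- 1:25
  if (grp == "Vir")
    data.frame(group = grp, cell = i, seed = 5000L + i,
               resting_potential = -58, spike_rate = 3,
               silent = (i %% 10 == 0),
               depol_block_current = ifelse(i %% 3 != 0, 200, NA),
               psc_rate = 2, epsc_fraction = 0.55)
  else
    data.frame(group = grp, cell = i, seed = 6000L + i,
               resting_potential = -65, spike_rate = 1.5,
               silent = (i %% 5 <= 1), depol_block_current = NA,
               psc_rate = 4.5, epsc_fraction = 0.75)
}))
utils::write.csv(cfg_tab, file.path(out_root, "patch_cohort.csv"),
                 row.names = FALSE)
cat("patch cohorts: 25 Vir + 25 D18 cell configs ->",
    file.path(out_root, "patch_cohort.csv"), "\n")
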