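#!/usr/bin/env Rscript
# Behavioral-sequence analysis of the synthetic ethograms: per-assay
# summaries (retrieval latency, crouch and nest-time fractions), Kaplan-Meier
# retrieval-latency analysis with log-rank test, and per-edge transition
# comparisons between virgin-like and D18-like animals (Mann-Whitney U).

suppressMessages(library(galpop))

etho <- utils::read.csv("results/synthetic/ethograms.csv")
assays <- split(etho, interaction(etho$timepoint, etho$animal_id, drop = TRUE))

## per-assay summaries --------------------------------------------------------
summ <- do.call(rbind, lapply(assays, function(df) {
  ev <- event_table(df$onset_s, df$offset_s, df$label,
                    animal_id = df$animal_id[1], timepoint = df$timepoint[1],
                    assay_duration_s = 600)
  s <- summarize_assay(ev, assay_duration_s = 600,
                       nest_labels = c("nest_enter", "nest_build"))
  data.frame(timepoint = df$timepoint[1], animal_id = df$animal_id[1],
             retrieval_latency_s = s$retrieval_latency_s,
             retrieval_censored = s$retrieval_censored,
             crouch_fraction = s$crouch_fraction,
             nest_time_fraction = s$nest_time_fraction)
}))
utils::write.csv(summ, "results/behavior_summary.csv", row.names = FALSE)
agg <- stats::aggregate(cbind(retrieval_latency_s, crouch_fraction) ~
                          timepoint, summ, mean)
cat("mean retrieval latency (s):\n"); print(agg)

## Kaplan-Meier retrieval latency ---------------------------------------------
km <- km_survival(summ$retrieval_latency_s, !summ$retrieval_censored,
                  summ$timepoint)
cat(sprintf("log-rank: chi-square = %.2f (df %d), p = %.4g\n",
            km$chisq, km$df, km$p_value))
jsonlite::write_json(list(chisq = km$chisq, df = km$df,
                          p_value = km$p_value, curves = km$curves),
                     "results/behavior_km.json", auto_unbox = TRUE,
                     digits = NA)

## transition-matrix edge comparison ------------------------------------------
tmx_by <- lapply(assays, function(df) {
  ev <- event_table(df$onset_s, df$offset_s, df$label,
                    animal_id = df$animal_id[1], timepoint = df$timepoint[1])
  transition_matrix(ev)
})
grp <- function(tp) tmx_by[vapply(tmx_by, function(t) t$timepoint == tp,
                                  logical(1))]
res <- compare_transition_groups(grp("Vir"), grp("D18"))
utils::write.csv(res$edges, "results/behavior_edges.csv", row.names = FALSE)
flagged <- res$edges[res$edges$flagged, ]
cat(sprintf("%d of %d edges differ at p < 0.05; strongest shifts:\n",
            nrow(flagged), nrow(res$edges)))
print(utils::head(flagged[order(flagged$p_value),
                          c("from", "to", "mean_a", "mean_b", "p_value")], 8))
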