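#!/usr/bin/env Rscript

# Stage 5: sensitivity analyses. One-way (tornado) analysis of the
# camrelizumab-vs-sintilimab ICER, probabilistic sensitivity analysis with
# 10,000 Monte Carlo draws, and cost-effectiveness acceptability curves.
# Figures are drawn when ggplot2 is available.

library(pd1cea)

cfg <- read_config("results/config.yaml")

load_selected <- function(s, e) {
  j <- jsonlite::read_json(sprintf("results/fits/fits_%s_%s.json", s, e))
  parametric_fit_from_params(j$selected, unlist(j$selected_params))
}
fitted <- lapply(names(cfg$strategies), function(s)
  list(PFS = list(selected = load_selected(s, "PFS")),
       OS = list(selected = load_selected(s, "OS"))))
names(fitted) <- names(cfg$strategies)
ctx <- build_context(fitted, cfg)

tor <- one_way_sa(ctx, config_oneway_specs(cfg), comparator = cfg$comparator)
write.csv(tor, "results/tornado.csv", row.names = FALSE)
cat("Tornado (ICER", paste(cfg$comparator, collapse = " vs "), "):\n")
print(head(tor[, c("parameter", "icer_low", "icer_high", "width")], 8),
      row.names = FALSE, digits = 6)

psa <- run_psa(ctx, config_dist_specs(cfg), n_iterations = cfg$psa$n_iterations,
               seed = cfg$psa$seed)
psa_df <- data.frame(iteration = seq_len(psa$n_iterations))
for (s in psa$strategies) {
  psa_df[[paste0("cost_", s)]] <- psa$cost[, s]
  psa_df[[paste0("qalys_", s)]] <- psa$qalys[, s]
}
write.csv(psa_df, "results/psa_samples.csv", row.names = FALSE)

cc <- ceac(psa)
write.csv(cc, "results/ceac.csv", row.names = FALSE)
wtp <- wtp_threshold(cfg)
at <- cc[which.min(abs(cc$wtp - wtp)), ]
cat(sprintf("\nCEAC at the %d CNY/QALY threshold: %s\n", wtp,
            paste(sprintf("%s %.1f%%", psa$strategies,
                          100 * unlist(at[psa$strategies])), collapse = ", ")))

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  dir.create("results/figures", showWarnings = FALSE)
  top <- head(tor[!is.na(tor$width) & tor$width > 0, ], 10)
  top$parameter <- factor(top$parameter, levels = rev(top$parameter))
  p1 <- ggplot(top) +
    geom_segment(aes(x = icer_low, xend = icer_high,
                     y = parameter, yend = parameter), linewidth = 5,
                 colour = "steelblue") +
    geom_vline(xintercept = top$icer_base[1], linetype = 2) +
    labs(x = "ICER (CNY/QALY)", y = NULL,
         title = "One-way sensitivity of the camrelizumab vs sintilimab ICER") +
    theme_minimal()
  ggsave("results/figures/tornado.png", p1, width = 8, height = 4.5, dpi = 150)

  long <- do.call(rbind, lapply(psa$strategies, function(s)
    data.frame(wtp = cc$wtp, strategy = s, prob = cc[[s]])))
  p2 <- ggplot(long, aes(wtp, prob, colour = strategy)) +
    geom_line(linewidth = 0.8) +
    geom_vline(xintercept = wtp, linetype = 2) +
    labs(x = "Willingness to pay (CNY/QALY)",
         y = "Probability cost-effective",
         title = "Cost-effectiveness acceptability curves") +
    theme_minimal()
  ggsave("results/figures/ceac.png", p2, width = 8, height = 4.5, dpi = 150)
  cat("Figures written to results/figures.\n")
}
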