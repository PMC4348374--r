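#!/usr/bin/env Rscript
# Baseline forecast to 2027: continued (capped) risk-factor trends plus
# demographic change.

library(t2dmarkov)
dir.create("results", showWarnings = FALSE)

inp <- tunisia_inputs()
run <- suppressWarnings(run_model(build_model_spec(inp)))

series <- run$summary[, c("year", "sex", "live", "t2d", "prevalence")]
series$prevalence_pct <- round(100 * series$prevalence, 2)
write.csv(series, "results/prevalence_series.csv", row.names = FALSE)

tab <- summary_tables(run, c(2015, 2020, 2027))
write.csv(tab, "results/forecast_summary.csv", row.names = FALSE)

cat("Projection summary (baseline, no intervention):\n")
print(tab, row.names = FALSE)
s <- run$summary
n97 <- s$t2d[s$year == 1997 & s$sex == "total"]
n27 <- s$t2d[s$year == 2027 & s$sex == "total"]
cat(sprintf("\nT2D caseload grows from %.0f thousand (1997) to %.0f thousand (2027), x%.1f.\n",
            n97, n27, n27 / n97))
cat("The published projection is higher (26.6% overall, 2125 thousand);\n")
cat("see 03_hindcast_validation.R and 06_extremes.R for the gap analysis.\n")
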