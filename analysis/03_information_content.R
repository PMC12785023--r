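#!/usr/bin/env Rscript
# Information-content analysis: compare binary vs denary PNG sizes and fit
# the per-mode trend of image size across the four mass windows, with the
# slope-difference t-test between ionization modes. Reads the per-case
# table produced by 02_segment_margins.R.

library(msimargin)

per_case <- read.delim("results/per_case.tsv")

binary <- per_case[per_case$k == 2, ]
denary <- per_case[per_case$k == 10, ]
key <- function(df) paste(df$case, df$mode, df$window)
m <- match(key(binary), key(denary))
frac_ge <- mean(denary$bytes[m] >= binary$bytes)
cat(sprintf("denary PNG >= binary PNG in %.0f%% of case/mode/window cells\n",
            100 * frac_ge))

tt <- trend_tests(binary)
cat("\nper-mode OLS of image size (kb) on window index (1-4):\n")
print(tt$per_mode, row.names = FALSE)
if (!is.null(tt$slope_difference))
  cat(sprintf("\nslope difference between modes: %.4g kb/window (p = %.3g)\n",
              tt$slope_difference$estimate, tt$slope_difference$p_value))

write.table(tt$per_mode, "results/info_content_trends.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
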