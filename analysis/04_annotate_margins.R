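#!/usr/bin/env Rscript
# Tentative annotation of the dominant m/z of the candidate margin class
# (the smallest binary cluster) per case and window, against the shipped
# metabolite table at +/- 0.1 Da.

library(msimargin)

per_case <- read.delim("results/per_case.tsv")
binary <- per_case[per_case$k == 2 & !is.na(per_case$dominant_mz), ]

rows <- lapply(seq_len(nrow(binary)), function(i) {
  r <- binary[i, ]
  hits <- annotate(r$dominant_mz, r$mode, tolerance = 0.1)
  if (nrow(hits) == 0)
    return(data.frame(case = r$case, mode = r$mode, window = r$window,
                      dominant_mz = r$dominant_mz, name = NA, adduct = NA,
                      delta = NA))
  data.frame(case = r$case, mode = r$mode, window = r$window,
             dominant_mz = r$dominant_mz, name = hits$name[1],
             adduct = hits$adduct[1], delta = hits$delta[1])
})
out <- do.call(rbind, rows)
write.table(out, "results/margin_annotations.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

annotated <- out[!is.na(out$name), ]
cat(sprintf("%d of %d margin spectra annotated within 0.1 Da\n",
            nrow(annotated), nrow(out)))
if (nrow(annotated) > 0)
  print(head(annotated, 10), row.names = FALSE)
cat("all annotations are tentative: MS1 mass alone cannot identify a species\n")
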