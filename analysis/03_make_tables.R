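#!/usr/bin/env Rscript
# Turn the per-replicate records from analysis/02_run_simulation_study.R into
# method-comparison tables: one wide table per metric with methods as rows,
# scenario cells as columns, entries "median (min,max)".
#
# Usage: Rscript analysis/03_make_tables.R [--in results/study] [--out results]
# Output: <out>/table_<metric>.csv

suppressPackageStartupMessages({
  library(optparse)
  library(lassosim)
})
opts <- parse_args(OptionParser(option_list = list(
  make_option("--in", type = "character", default = "results/study",
              dest = "in_dir"),
  make_option("--out", type = "character", default = "results"))))

rec_path <- file.path(opts$in_dir, "replicates.csv")
if (!file.exists(rec_path))
  stop("no replicate records at ", rec_path,
       "; run analysis/02_run_simulation_study.R first", call. = FALSE)
records <- read.csv(rec_path)
summary <- summarize_records(records)
tabs <- compare_report(summary, out_dir = opts$out)
for (metric in names(tabs)) {
  cat("\n==", metric, "==\n")
  print(tabs[[metric]], right = FALSE)
}
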