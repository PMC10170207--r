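# Shared configuration for the analysis scripts. Run the scripts from the
# repository root in order; each writes its tables under results/analysis/.

library(gencontrib)

OUT <- "results/analysis"
dir.create(OUT, showWarnings = FALSE, recursive = TRUE)

MASTER_SEED <- 20260921L
FINAL_YEAR <- 1990L

# study conditions: two parishes at their historical sizes, followed over
# four centuries, with the historical-demography defaults (high infant
# mortality, marriage-driven migration, median four offspring among
# reproducers)
SIM_CONFIG <- sim_config(years = c(1560L, FINAL_YEAR))

load_genealogy_stage <- function() {
  load_genealogy(file.path(OUT, "genealogy.csv"))
}
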