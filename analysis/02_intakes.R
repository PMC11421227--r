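#!/usr/bin/env Rscript
# Step 2 — recall items to daily intakes.
#
# Converts recall rows to per-child daily nutrient totals, applies the
# 3-SD energy-outlier exclusion within 1-y age strata, computes dairy
# servings (250 g per serving) and adherence to the 2-3 servings/d
# recommendation, and writes childday.csv plus the dairy consumption
# table (the descriptive table analogue).

library(dairymod)
library(readr)

recall <- read_csv("results/recall.csv", show_col_types = FALSE)
foods <- read_csv("results/foods.csv", show_col_types = FALSE)

issues <- validate_inputs(recall, foods)
stopifnot(nrow(issues) == 0)

cd <- compute_intakes(recall, foods)
cd <- flag_energy_outliers(cd)
kept <- exclude_energy_outliers(cd)
cat(sprintf("Excluded %d energy outliers (3 SD within age strata); %d children remain.\n",
            attr(kept, "n_excluded"), nrow(kept)))

write_csv(kept, "results/childday.csv")

tab <- dairy_consumption_table(kept)
write_csv(tab, "results/dairy_table.csv")
print(as.data.frame(tab), digits = 3)

adh <- table(classify_dairy_adherence(kept$servings))
cat("Dairy adherence categories (%):\n")
print(round(100 * adh / nrow(kept), 1))
cat(sprintf("Meeting the >=2 servings/d recommendation: %.1f%%.\n",
            100 * mean(meets_dairy_recommendation(kept$servings))))
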