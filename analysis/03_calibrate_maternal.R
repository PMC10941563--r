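#!/usr/bin/env Rscript
# Step 3 -- Calibrate the adult model to the observed maternal exposure.
#
# The lumped two-compartment oral model has two free adult parameters: the
# total unbound intrinsic clearance (L/h per kg liver) and the central volume
# per kg. Both are pinned by the observed day-14 median exposure in nursing
# mothers (Cmax 129 ng/mL, AUC 988 ng/mL*h under 0.5 mg/kg q.d. x 14).

library(lactpbpk)
dir.create("results", showWarnings = FALSE)

cal <- calibrate_adult()
cat(sprintf("achieved day-14 Cmax %.2f ng/mL, AUC %.1f ng/mL*h\n",
            cal$achieved[["cmax"]], cal$achieved[["auc"]]))
cat(sprintf("adult CL_int: MAOA %.2f, CYP2D6 %.2f L/h per kg liver\n",
            cal$drug$cl_int_by_pathway[["MAOA"]],
            cal$drug$cl_int_by_pathway[["CYP2D6"]]))
cat(sprintf("central volume %.3f L/kg; apparent CL/F %.4f L/h/kg (dose/AUC = %.4f)\n",
            cal$disposition$vc_per_kg, cal$cl_over_f_per_kg, 500 / 988))

if (requireNamespace("jsonlite", quietly = TRUE)) {
  jsonlite::write_json(
    list(cl_int_by_pathway = as.list(cal$drug$cl_int_by_pathway),
         disposition = cal$disposition,
         achieved = as.list(cal$achieved),
         cl_over_f_per_kg = cal$cl_over_f_per_kg),
    "results/03_calibrated_model.json", auto_unbox = TRUE, digits = NA)
  cat("wrote results/03_calibrated_model.json\n")
}
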