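#!/usr/bin/env Rscript
## Intensified-DoE experiment: train a hybrid ensemble on the six iDoE
## bioreactor runs with leave-one-run-out cross-validation and evaluate on
## the five static bioreactor runs; compare against the transfer-trained
## ensemble from 04_fit_transfer.R on the same test set.

suppressMessages(library(hybridoe))
seed <- 1

idoe <- make_dataset("idoe_training", seed = seed)
static5 <- make_dataset("idoe_test", seed = seed)

ens_idoe <- fit_hybrid(idoe, cv = cv_config(mode = "leave_one_run_out",
                                            seed = 7))
write_ensemble(ens_idoe, "results/ensemble_idoe")

ev_tr <- evaluate_ensemble(ens_idoe, idoe)
ev_te <- evaluate_ensemble(ens_idoe, static5)
jsonlite::write_json(list(training = as.list(ev_tr$nrmse),
                          test = as.list(ev_te$nrmse)),
                     "results/idoe_summary.json", auto_unbox = TRUE,
                     digits = NA)
write.csv(rbind(cbind(set = "training", ev_tr$per_run),
                cbind(set = "test", ev_te$per_run)),
          "results/idoe_nrmse.csv", row.names = FALSE)

cat(sprintf("iDoE-trained, training NRMSE: VCC %.2f%%, titer %.2f%%\n",
            ev_tr$nrmse["vcc"], ev_tr$nrmse["titer"]))
cat(sprintf("iDoE-trained, static test NRMSE: VCC %.2f%%, titer %.2f%%\n",
            ev_te$nrmse["vcc"], ev_te$nrmse["titer"]))

if (dir.exists("results/ensemble_transfer")) {
  ens_doe <- read_ensemble("results/ensemble_transfer")
  ev_doe <- evaluate_ensemble(ens_doe, static5)
  cat(sprintf("transfer-trained ensemble on the same static runs: VCC %.2f%%, titer %.2f%%\n",
              ev_doe$nrmse["vcc"], ev_doe$nrmse["titer"]))
  cat(sprintf("iDoE/DoE NRMSE ratios: VCC %.2f, titer %.2f\n",
              ev_te$nrmse["vcc"] / ev_doe$nrmse["vcc"],
              ev_te$nrmse["titer"] / ev_doe$nrmse["titer"]))
}
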