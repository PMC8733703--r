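#!/usr/bin/env Rscript
## Scale-transfer experiment: train the hybrid ensemble on the 18 shake-flask
## runs plus the three bioreactor center points (repeated random 60/40 run
## splits), then evaluate on the remaining 8 bioreactor runs (2 static, 6
## intensified).  Writes the ensemble and the NRMSE tables under results/.

suppressMessages(library(hybridoe))
seed <- 1

training <- make_dataset("transfer_training", seed = seed)
test <- make_dataset("transfer_test", seed = seed)

ens <- fit_hybrid(training, cv = cv_config(n_repeats = 10, seed = 7))
write_ensemble(ens, "results/ensemble_transfer")

ev_train <- evaluate_ensemble(ens, training)
ev_test <- evaluate_ensemble(ens, test)
dir.create("results", showWarnings = FALSE)
write.csv(rbind(cbind(set = "training", ev_train$per_run),
                cbind(set = "test", ev_test$per_run)),
          "results/transfer_nrmse.csv", row.names = FALSE)
jsonlite::write_json(list(training = as.list(ev_train$nrmse),
                          test = as.list(ev_test$nrmse),
                          members = length(ens$members), seed = seed),
                     "results/transfer_summary.json", auto_unbox = TRUE,
                     digits = NA)

## time-resolved estimate with confidence band for one static and one
## intensified test run
for (id in c("bioreactor_02", "bioreactor_06")) {
  pr <- average_predict(ens, test[[id]])
  write.csv(pr, sprintf("results/prediction_%s.csv", id), row.names = FALSE)
}

cat(sprintf("training NRMSE: VCC %.2f%%, titer %.2f%%\n",
            ev_train$nrmse["vcc"], ev_train$nrmse["titer"]))
cat(sprintf("test NRMSE:     VCC %.2f%%, titer %.2f%%\n",
            ev_test$nrmse["vcc"], ev_test$nrmse["titer"]))
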