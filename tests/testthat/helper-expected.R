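# Published Table-1-style expected values for the 1-MeTHIQ + AED study:
# the printed component doses, additive predictions and significance stars
# that the pipeline must reproduce from the summary inputs in
# methiq_mes_summaries(). These are frozen expectations, not inputs.
methiq_expected <- function() {
  utils::read.csv(text = "drug,ratio,dose1_exp,dose2_exp,ed50_add,sem_add,dose2_add,dose1_add,star,label
CZP,200:1,45.54,0.23,48.85,5.37,0.24,48.61,ns,additive
CZP,100:1,42.28,0.42,49.09,5.40,0.48,48.61,ns,additive
CZP,50:1,33.66,0.67,49.56,5.45,0.95,48.61,0.05,supra-additive
CZP,25:1,31.09,1.24,50.48,5.55,1.87,48.61,0.01,supra-additive
ETS,1:1,43.95,43.95,97.22,10.69,48.61,48.61,ns,additive
ETS,1:2,44.73,89.47,145.83,16.04,97.22,48.61,ns,additive
ETS,1:5,38.02,190.08,291.66,32.07,243.05,48.61,ns,additive
ETS,1:10,31.53,315.25,534.71,58.80,486.10,48.61,0.01,supra-additive
GBP,1:1,25.83,25.83,97.22,10.69,48.61,48.61,0.001,supra-additive
GBP,1:2,21.78,43.56,145.83,16.04,97.22,48.61,0.001,supra-additive
GBP,1:5,14.42,72.12,291.66,32.07,243.05,48.61,0.001,supra-additive
GBP,1:10,13.04,130.36,534.71,58.80,486.10,48.61,0.001,supra-additive
LEV,1:1,49.33,49.33,97.22,10.69,48.61,48.61,ns,additive
LEV,1:2,47.89,95.79,145.83,16.04,97.22,48.61,ns,additive
LEV,1:5,40.20,201.02,291.66,32.07,243.05,48.61,ns,additive
LEV,1:10,40.01,400.12,534.71,58.80,486.10,48.61,ns,additive
TGB,200:1,53.84,0.27,48.85,5.37,0.24,48.61,ns,additive
TGB,100:1,44.84,0.45,49.09,5.40,0.48,48.61,ns,additive
TGB,50:1,41.08,0.82,49.56,5.45,0.95,48.61,ns,additive
TGB,25:1,39.37,1.58,50.48,5.55,1.87,48.61,ns,additive
VGB,1:1,37.68,37.68,97.22,10.69,48.61,48.61,ns,additive
VGB,1:2,42.80,85.59,145.83,16.04,97.22,48.61,ns,additive
VGB,1:5,40.18,200.91,291.66,32.07,243.05,48.61,ns,additive
VGB,1:10,40.18,401.81,534.71,58.80,486.10,48.61,ns,additive",
    stringsAsFactors = FALSE, colClasses = list(star = "character"))
}

# Run the whole published-summary replay: one combination_study per
# ineffective drug, flattened, in the input row order.
methiq_replay <- function() {
  d <- methiq_mes_summaries()
  alone <- summary_fit(d$alone$ed50, d$alone$ci95_lower, d$alone$ci95_upper)
  out <- lapply(unique(d$mixtures$drug), function(dr) {
    sm <- d$mixtures[d$mixtures$drug == dr, ]
    st <- run_combination_analysis(
      alone,
      mixtures = lapply(seq_len(nrow(sm)), function(i) {
        list(ed50 = sm$ed50_exp[i], sem = sm$sem_exp[i], n = sm$n_exp[i])
      }),
      ratios = sm$ratio,
      n_add = d$n_add,
      effective_drug = d$alone$drug,
      ineffective_drug = dr
    )
    cbind(drug = dr, as.data.frame(st), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
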