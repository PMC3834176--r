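#' Published summary statistics: 1-MeTHIQ with six antiepileptic drugs
#'
#' Summary statistics from a published type II isobolographic study of
#' 1-methyl-1,2,3,4-tetrahydroisoquinoline (1-MeTHIQ, the drug fully
#' effective against maximal electroshock-induced seizures in mice)
#' combined with six antiepileptic drugs that are virtually ineffective
#' alone in that model: clonazepam (CZP), ethosuximide (ETS), gabapentin
#' (GBP), levetiracetam (LEV), tiagabine (TGB) and vigabatrin (VGB).
#' CZP and TGB were tested at mass ratios 200:1, 100:1, 50:1 and 25:1
#' (1-MeTHIQ : drug), the others at 1:1, 1:2, 1:5 and 1:10.
#'
#' Only quantities the study prints are included — these are the inputs
#' of summary-mode analysis, not results of this package:
#' the alone-drug ED50 with its 95% confidence limits, the experimental
#' mixture ED50 +/- SEM and probit-window n for each of the 24 fixed
#' ratios, and the theoretical animal count `n_add = 22` attached to
#' every additivity prediction.
#'
#' @return A list with elements:
#'   \describe{
#'     \item{alone}{list: `drug`, `ed50`, `ci95_lower`, `ci95_upper` (mg/kg).}
#'     \item{n_add}{integer, the published theoretical n for every ratio.}
#'     \item{mixtures}{data frame with columns `drug`, `ratio`,
#'       `ed50_exp`, `sem_exp`, `n_exp`.}
#'   }
#' @seealso [run_combination_analysis()]
#' @export
#' @examples
#' d <- methiq_mes_summaries()
#' subset(d$mixtures, drug == "GBP")
methiq_mes_summaries <- function() {
  mixtures <- utils::read.csv(text = "drug,ratio,ed50_exp,sem_exp,n_exp
CZP,200:1,45.77,4.94,24
CZP,100:1,42.70,4.76,8
CZP,50:1,34.33,2.71,16
CZP,25:1,32.33,1.54,24
ETS,1:1,87.90,3.82,16
ETS,1:2,134.20,16.48,16
ETS,1:5,228.10,27.41,24
ETS,1:10,346.78,23.83,16
GBP,1:1,51.66,5.85,32
GBP,1:2,65.34,7.12,16
GBP,1:5,86.54,12.95,24
GBP,1:10,143.40,19.33,16
LEV,1:1,98.66,8.58,24
LEV,1:2,143.68,14.56,32
LEV,1:5,241.22,24.31,32
LEV,1:10,440.13,25.25,32
TGB,200:1,54.11,4.75,16
TGB,100:1,45.29,4.57,24
TGB,50:1,41.90,2.59,16
TGB,25:1,40.94,3.35,24
VGB,1:1,75.36,4.96,24
VGB,1:2,128.39,9.26,24
VGB,1:5,241.09,21.02,24
VGB,1:10,441.99,38.53,24", stringsAsFactors = FALSE)
  list(
    alone = list(drug = "1-MeTHIQ", ed50 = 48.61,
                 ci95_lower = 39.18, ci95_upper = 60.31),
    n_add = 22L,
    mixtures = mixtures
  )
}
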