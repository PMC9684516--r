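## Clinical endpoint labeling. Genitourinary (GU) toxicities are CTCAE v5
## graded events (frequency, nocturia, dysuria, urgency, obstruction,
## incontinence) recorded with the accumulated BED at onset and a phase
## (during or after radiotherapy). The binary category rule is grade >= 2.
## The IPSS endpoint is the change in total International Prostate Symptom
## Score, final minus initial; category 1 encodes improvement (delta < 0).

gu_symptoms <- c("frequency", "nocturia", "dysuria", "urgency",
                 "obstruction", "incontinence")

#' Build a toxicity-event table
#'
#' @param grade integer CTCAE grades 1..5.
#' @param onset_bed accumulated BED at onset in Gy (>= 0).
#' @param phase `"during_RT"` or `"post_RT"`.
#' @param symptom GU symptom names (optional, default "frequency").
#' @return data.frame of events.
#' @export
toxicity_events <- function(grade = integer(0), onset_bed = numeric(0),
                            phase = character(0), symptom = NULL) {
  if (length(grade) > 0) {
    if (any(grade < 1 | grade > 5)) stop("CTCAE grade must be 1..5")
    if (any(onset_bed < 0)) stop("onset BED must be >= 0")
    if (any(!phase %in% c("during_RT", "post_RT")))
      stop("phase must be during_RT or post_RT")
  }
  if (is.null(symptom)) symptom <- rep("frequency", length(grade))
  data.frame(symptom = symptom, grade = as.integer(grade),
             onset_bed = as.numeric(onset_bed), phase = phase,
             stringsAsFactors = FALSE)
}

#' Acute GU toxicity label for one BED bin
#'
#' Category 1 iff the maximum grade among during-RT events with onset
#' strictly after `bin_bed` is >= 2; patients with no qualifying event are
#' category 0. The label is monotone non-increasing in `bin_bed`.
#'
#' @param events a [toxicity_events()] table.
#' @param bin_bed BED bin upper in Gy.
#' @return 0 or 1.
#' @export
label_acute_gu <- function(events, bin_bed) {
  q <- events$phase == "during_RT" & events$onset_bed > bin_bed
  as.integer(any(q) && max(events$grade[q]) >= 2)
}

#' Sub-acute GU toxicity label (bin-invariant)
#'
#' Category 1 iff any post-RT event has grade >= 2; by construction the same
#' for every BED bin.
#'
#' @param events a [toxicity_events()] table.
#' @return 0 or 1.
#' @export
label_subacute_gu <- function(events) {
  q <- events$phase == "post_RT"
  as.integer(any(q) && max(events$grade[q]) >= 2)
}

#' IPSS change and its binary category
#'
#' `delta = ipss_f - ipss_i`; category 1 iff `delta < 0` (symptom
#' improvement), 0 otherwise. Scores must be in 0..35.
#'
#' @param ipss_i initial (pre-treatment) total IPSS.
#' @param ipss_f final (post-treatment) total IPSS.
#' @return list with `delta` and `category`.
#' @export
label_delta_ipss <- function(ipss_i, ipss_f) {
  if (any(c(ipss_i, ipss_f) < 0) || any(c(ipss_i, ipss_f) > 35))
    stop("IPSS scores must be within 0..35")
  delta <- ipss_f - ipss_i
  list(delta = delta, category = as.integer(delta < 0))
}
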