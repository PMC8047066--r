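#' The 13 motion-sickness symptoms
#'
#' Order and naming of the questionnaire items: each is answered on an
#' ordinal 0/1/2 scale after every protocol.
#'
#' @return Character vector of length 13.
#' @export
symptom_names <- function() {
  c("general_discomfort", "dizziness_vertigo", "stomach_awareness",
    "sweating", "nausea", "salivation", "burping", "headache",
    "fullness_of_head", "blurred_vision", "fatigue", "eye_strain",
    "difficulty_focusing")
}

#' @rdname symptom_names
#' @export
index_names <- function() {
  c("I_GenDis", "I_Dizz", "I_Stom", "I_Head", "I_Fatig", "I_PV", "I_NM",
    "I_MS")
}

# symptom groups feeding the averaged indexes
index_groups <- function() {
  stom <- c("stomach_awareness", "sweating", "nausea", "salivation", "burping")
  head <- c("headache", "fullness_of_head", "blurred_vision")
  fatig <- c("fatigue", "eye_strain", "difficulty_focusing")
  list(I_GenDis = "general_discomfort",
       I_Dizz = "dizziness_vertigo",
       I_Stom = stom, I_Head = head, I_Fatig = fatig,
       I_PV = c(stom, "general_discomfort"),
       I_NM = c(fatig, head, "general_discomfort"))
}

check_response <- function(response) {
  r <- unlist(response[symptom_names()])
  if (length(r) != 13 || anyNA(r))
    stop("response must score all 13 symptoms")
  if (any(r != round(r)) || any(r < 0) || any(r > 2))
    stop("symptom scores must be integers in 0..2")
  r
}

#' Per-measurement score of one symptom group
#'
#' Averaged groups return the mean of their member scores; the two
#' single-symptom indexes (general discomfort, dizziness/vertigo) return
#' the raw response unchanged.
#'
#' @param response Named scores over [symptom_names()] (vector or one-row
#'   data frame).
#' @param group An index name (see [index_names()], `"I_MS"` excluded) or a
#'   character vector of member symptoms.
#' @return Scalar group score.
#' @export
group_score <- function(response, group) {
  r <- check_response(response)
  if (is.character(group) && length(group) == 1 && startsWith(group, "I_")) {
    groups <- index_groups()
    if (!group %in% names(groups)) stop("unknown group: ", group)
    group <- groups[[group]]
  }
  if (!all(group %in% symptom_names())) stop("unknown symptom in group")
  mean(r[group])
}

#' Weighted symptom sum
#'
#' The scalar severity score behind the overall motion-sickness index:
#' `0.2 * (GenDis + Dizz + sum(5 stomach items) + sum(3 fatigue items) +
#' sum(3 head items))`.  Ranges from 0 (no symptoms) to 5.2 (all symptoms
#' at 2) and is monotone in every item.
#'
#' @inheritParams group_score
#' @return Scalar in `[0, 5.2]`.
#' @examples
#' r <- setNames(rep(2L, 13), symptom_names())
#' sum_ms(r)  # 5.2
#' @export
sum_ms <- function(response) {
  r <- check_response(response)
  g <- index_groups()
  0.2 * (r[["general_discomfort"]] + r[["dizziness_vertigo"]] +
           sum(r[g$I_Stom]) + sum(r[g$I_Fatig]) + sum(r[g$I_Head]))
}

#' Cohort-relative binarization at one third of the maximum
#'
#' The cohort's maximum value sets the threshold `t = max(values) / 3`;
#' measurements at or above `t` are labelled 1 ("symptomatic"), the rest 0.
#' A tie at the threshold is labelled 1 (a symptomatic tie is never called
#' asymptomatic); an all-zero cohort has no positives.  Labels are
#' invariant to positive rescaling of the values.
#'
#' @param values Non-negative scalar per measurement.
#' @param threshold Optional frozen threshold; when supplied the cohort
#'   maximum is ignored (for scoring new data against a reference cohort).
#' @param tie `">="` (default) or `">"`: whether a value exactly at the
#'   threshold is labelled 1.
#' @return Integer 0/1 vector, same length as `values`.
#' @examples
#' cohort_binarize(c(3, 1, 0.9))  # 1 1 0
#' @export
cohort_binarize <- function(values, threshold = NULL, tie = c(">=", ">")) {
  tie <- match.arg(tie)
  values <- as.numeric(values)
  if (length(values) == 0) stop("empty cohort")
  if (anyNA(values) || any(values < 0)) stop("values must be non-negative")
  t <- if (is.null(threshold)) max(values) / 3 else threshold
  if (t <= 0) return(rep(0L, length(values)))
  as.integer(if (tie == ">=") values >= t else values > t)
}

#' Compute the eight binary indexes for a cohort
#'
#' Applies the three-step rule to every index: (1) per-measurement group
#' score (mean of member symptoms; the raw response for the two
#' single-symptom indexes; the weighted sum [sum_ms()] for the overall
#' index), (2) cohort maximum, (3) binarization at one third of that
#' maximum.  Thresholds are cohort-relative: they are recomputed for the
#' table passed in (pooled across protocols), which is what makes the
#' labels a within-cohort severity contrast rather than an absolute scale.
#'
#' @param responses Data frame with one row per measurement and the 13
#'   symptom columns (extra columns such as `subject_id`/`protocol` are
#'   carried through).
#' @param tie Passed to [cohort_binarize()].
#' @return List of class `index_set`: `indexes` (data frame: carried id
#'   columns, 8 binary index columns, `SumMS`), `group_scores` (the
#'   pre-binarization scalars), `thresholds` (named vector), and
#'   `marginals` (percentage report, see [index_marginals()]).
#' @export
compute_indexes <- function(responses, tie = ">=") {
  responses <- as.data.frame(responses)
  if (nrow(responses) == 0) stop("empty cohort")
  miss <- setdiff(symptom_names(), names(responses))
  if (length(miss)) stop("missing symptom columns: ",
                         paste(miss, collapse = ", "))
  apply(responses[symptom_names()], 1, check_response)
  groups <- index_groups()
  scores <- data.frame(lapply(groups, function(g)
    rowMeans(responses[, g, drop = FALSE])))
  scores$I_MS <- apply(responses[symptom_names()], 1,
                       function(r) sum_ms(r))
  thresholds <- vapply(scores, function(v) max(v) / 3, numeric(1))
  idx <- data.frame(lapply(scores, cohort_binarize, tie = tie))
  id_cols <- intersect(c("subject_id", "protocol"), names(responses))
  indexes <- cbind(responses[id_cols], idx,
                   SumMS = scores$I_MS)
  structure(list(indexes = indexes, group_scores = scores,
                 thresholds = thresholds,
                 marginals = index_marginals(responses, idx)),
            class = "index_set")
}

#' @export
print.index_set <- function(x, ...) {
  cat(sprintf("<index_set> %d measurements; positive rates:\n",
              nrow(x$indexes)))
  rates <- vapply(index_names(), function(i) mean(x$indexes[[i]]), numeric(1))
  print(round(100 * rates, 1))
  invisible(x)
}

#' Marginal percentage report for symptoms and indexes
#'
#' The cohort-level summary layout: percentage of 0/1/2 answers per
#' symptom and percentage of 0/1 labels per index.
#'
#' @param responses Symptom score data frame (see [compute_indexes()]).
#' @param indexes Data frame of the 8 binary index columns.
#' @return List with data frames `symptoms` (`pct0`, `pct1`, `pct2`) and
#'   `indexes` (`pct0`, `pct1`), percentages to one decimal.
#' @export
index_marginals <- function(responses, indexes) {
  sy <- t(vapply(symptom_names(), function(s) {
    v <- responses[[s]]
    100 * c(mean(v == 0), mean(v == 1), mean(v == 2))
  }, numeric(3)))
  ix <- t(vapply(names(indexes), function(i) {
    v <- indexes[[i]]
    100 * c(mean(v == 0), mean(v == 1))
  }, numeric(2)))
  list(symptoms = data.frame(symptom = symptom_names(),
                             pct0 = round(sy[, 1], 1),
                             pct1 = round(sy[, 2], 1),
                             pct2 = round(sy[, 3], 1)),
       indexes = data.frame(index = names(indexes),
                            pct0 = round(ix[, 1], 1),
                            pct1 = round(ix[, 2], 1)))
}
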