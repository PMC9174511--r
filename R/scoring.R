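#' Symptom endorsement under the ICD-11 cut
#'
#' An ITQ item is endorsed when scored at least 2 ("Moderately") on the
#' 0-4 Likert scale; this is the diagnostic cut used throughout the
#' PTSD/cPTSD algorithm.
#'
#' @param score integer vector of item scores in 0-4 (NA allowed and
#'   propagated).
#' @return logical vector.
#' @examples
#' itq_endorse(c(0, 1, 2, 4))
#' @export
itq_endorse <- function(score) {
  check_scores(score, "item score")
  score >= 2L
}

#' Symptom-cluster criterion
#'
#' Each ICD-11 cluster holds two items; the cluster criterion is met when
#' at least one of the two is endorsed.
#'
#' @param score_a,score_b scores of the two cluster items.
#' @return logical vector.
#' @export
itq_cluster_met <- function(score_a, score_b) {
  itq_endorse(score_a) | itq_endorse(score_b)
}

# Internal single-pass diagnostic kernel on a data frame of item columns.
.diagnose_kernel <- function(d, require_exposure = TRUE) {
  for (col in c(itq_symptom_items(), itq_impairment_items())) {
    if (!col %in% names(d)) stop_input("missing required item column '%s'", col)
    check_scores(d[[col]], sprintf("item %s", col))
  }
  ptsd_sym <- itq_cluster_met(d$Re1, d$Re2) &
    itq_cluster_met(d$Av1, d$Av2) &
    itq_cluster_met(d$Hyp1, d$Hyp2)
  ptsd_imp <- itq_endorse(d$Pimp1) | itq_endorse(d$Pimp2) | itq_endorse(d$Pimp3)
  dso_sym <- itq_cluster_met(d$Dys1, d$Dys2) &
    itq_cluster_met(d$Nsc1, d$Nsc2) &
    itq_cluster_met(d$Rel1, d$Rel2)
  dso_imp <- itq_endorse(d$Dimp1) | itq_endorse(d$Dimp2) | itq_endorse(d$Dimp3)
  gate <- if (require_exposure) {
    if (!"trauma_exposed" %in% names(d)) {
      stop_input("missing 'trauma_exposed' column (or set require_exposure = FALSE)")
    }
    as.logical(d$trauma_exposed)
  } else rep(TRUE, nrow(d))
  ptsd_criteria <- gate & ptsd_sym & ptsd_imp
  cptsd_criteria <- ptsd_criteria & dso_sym & dso_imp
  # any missing diagnostic item -> missing diagnosis (excluded from
  # prevalence denominators), even if the observed items already fail
  any_missing <- rowSums(is.na(as.matrix(
    d[c(itq_symptom_items(), itq_impairment_items())]))) > 0 | is.na(gate)
  out <- dplyr::case_when(
    any_missing ~ NA_character_,
    cptsd_criteria ~ "cPTSD",
    ptsd_criteria ~ "PTSD",
    TRUE ~ "none"
  )
  factor(out, levels = c("none", "PTSD", "cPTSD"))
}

#' ICD-11 PTSD/cPTSD diagnostic algorithm
#'
#' Applies the ITQ screening algorithm to each row of a cohort table.
#' PTSD requires trauma exposure, at least one endorsed symptom in each of
#' the three core clusters (re-experiencing, avoidance, sense of current
#' threat), and at least one endorsed PTSD functional-impairment item.
#' cPTSD additionally requires one endorsed symptom in each of the three
#' DSO clusters (affective dysregulation, negative self-concept,
#' relational disturbance) and one endorsed DSO impairment item. The two
#' diagnoses are mutually exclusive: a respondent meeting the full cPTSD
#' criteria receives cPTSD only. Rows with a missing diagnostic item get a
#' missing diagnosis and drop out of prevalence denominators.
#'
#' @param data data frame with the 12 symptom columns (\code{Re1}..\code{Rel2}),
#'   6 impairment columns (\code{Pimp1}..\code{Dimp3}) and, unless
#'   \code{require_exposure = FALSE}, a logical \code{trauma_exposed} column.
#' @param require_exposure gate diagnoses on trauma exposure (default TRUE,
#'   the ICD-11 rule).
#' @return the input as a tibble with a \code{diagnosis} factor column
#'   (levels \code{none}, \code{PTSD}, \code{cPTSD}).
#' @export
itq_diagnose <- function(data, require_exposure = TRUE) {
  out <- tibble::as_tibble(data)
  out$diagnosis <- .diagnose_kernel(out, require_exposure)
  out
}

#' PTSD and DSO subscale sums
#'
#' Adds \code{ptsd_sum} (six core symptom items) and \code{dso_sum} (six
#' DSO items), each ranging 0-24.
#'
#' @inheritParams itq_diagnose
#' @return tibble with \code{ptsd_sum} and \code{dso_sum} columns added.
#' @export
itq_subscales <- function(data) {
  out <- tibble::as_tibble(data)
  for (col in itq_symptom_items()) {
    if (!col %in% names(out)) stop_input("missing required item column '%s'", col)
    check_scores(out[[col]], sprintf("item %s", col))
  }
  ptsd_cols <- itq_symptom_items()[1:6]
  dso_cols <- itq_symptom_items()[7:12]
  out$ptsd_sum <- rowSums(as.matrix(out[ptsd_cols]))
  out$dso_sum <- rowSums(as.matrix(out[dso_cols]))
  out
}

#' Cronbach's alpha internal-consistency coefficient
#'
#' \deqn{\alpha = \frac{k}{k-1}\Big(1 - \frac{\sum_j s_j^2}{s_{total}^2}\Big)}
#' with unbiased (n-1 denominator) sample variances throughout.
#'
#' @param items numeric matrix or data frame, n subjects x k items, no
#'   missing entries, k >= 2 and n >= 3.
#' @return list of class \code{"reliability"}: \code{alpha}, \code{n_items},
#'   \code{n_subjects}.
#' @export
cronbach_alpha <- function(items) {
  m <- as.matrix(items)
  if (ncol(m) < 2) stop_input("need at least two items")
  if (nrow(m) < 3) stop_input("need at least three subjects")
  if (anyNA(m)) stop_input("missing entries are not allowed")
  total_var <- var(rowSums(m))
  if (total_var <= 0) {
    stop_input("total-score variance is zero: alpha is undefined")
  }
  k <- ncol(m)
  alpha <- k / (k - 1) * (1 - sum(apply(m, 2, var)) / total_var)
  structure(list(alpha = alpha, n_items = k, n_subjects = nrow(m)),
            class = "reliability")
}

#' @export
print.reliability <- function(x, ...) {
  cat(sprintf("Cronbach's alpha = %.3f (%d items, %d subjects)\n",
              x$alpha, x$n_items, x$n_subjects))
  invisible(x)
}

#' Default intentional/unintentional classification of the trauma checklist
#'
#' The 21 checklist events partitioned as agreed by independent expert
#' raters: events implying deliberate intent to harm (weapon threat,
#' assault, sexual violence, war, captivity, stalking, bullying,
#' humiliation, emotional neglect) are intentional; illness, bereavement,
#' accidents and disasters are unintentional; two events judged pertinent
#' to neither class (causing or witnessing suffering) are excluded and
#' never contribute to either class indicator.
#'
#' @return tibble with columns \code{item} (1-21) and \code{class}.
#' @export
event_classification_map <- function() {
  ref <- item_exposure_reference()
  ref <- ref[!is.na(ref$class), c("row", "class")]
  tibble::tibble(item = as.integer(ref$row), class = ref$class)
}

.PERIODS <- c("child", "adol", "6mo")

exposure_flag_columns <- function() {
  as.vector(t(outer(sprintf("item%02d", 1:21), .PERIODS, paste, sep = "_")))
}

#' Per-subject trauma-exposure class indicators
#'
#' Collapses the 21 x 3 item-by-period exposure flags into intentional and
#' unintentional indicators per developmental period (childhood,
#' adolescence, last 6 months) plus lifetime (any period). Excluded
#' checklist items never contribute.
#'
#' @param flags data frame with logical columns \code{item01_child} ..
#'   \code{item21_6mo}.
#' @param map classification map as from
#'   \code{\link{event_classification_map}}; may be edited to reclassify
#'   events.
#' @return tibble with eight logical columns
#'   \code{intentional_child}, \code{intentional_adol},
#'   \code{intentional_6mo}, \code{intentional_lifetime}, and the
#'   \code{unintentional_*} counterparts.
#' @export
classify_exposures <- function(flags, map = event_classification_map()) {
  needed <- exposure_flag_columns()
  missing_cols <- setdiff(needed, names(flags))
  if (length(missing_cols) > 0) {
    stop_input("missing exposure flag columns: %s",
               paste(head(missing_cols, 3), collapse = ", "))
  }
  if (!all(map$item %in% 1:21)) stop_input("unknown checklist item id in classification map")
  out <- tibble::tibble(.rows = nrow(flags))
  for (cls in c("intentional", "unintentional")) {
    ids <- map$item[map$class == cls]
    for (per in .PERIODS) {
      cols <- sprintf("item%02d_%s", ids, per)
      ind <- if (length(cols) == 0) rep(FALSE, nrow(flags)) else {
        rowSums(as.matrix(flags[cols]) * 1L) > 0
      }
      out[[paste(cls, per, sep = "_")]] <- ind
    }
    out[[paste0(cls, "_lifetime")]] <-
      out[[paste0(cls, "_child")]] | out[[paste0(cls, "_adol")]] |
      out[[paste0(cls, "_6mo")]]
  }
  out
}
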