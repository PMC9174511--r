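#' ITQ symptom-item labels in canonical order
#'
#' The 12 ICD-11 ITQ symptom items: two per cluster for re-experiencing
#' (Re), avoidance (Av), sense of current threat / hyperarousal (Hyp),
#' affective dysregulation (Dys), negative self-concept (Nsc) and
#' disturbances in relationships (Rel).
#'
#' @return character vector of length 12.
#' @export
itq_symptom_items <- function() {
  c("Re1", "Re2", "Av1", "Av2", "Hyp1", "Hyp2",
    "Dys1", "Dys2", "Nsc1", "Nsc2", "Rel1", "Rel2")
}

#' @rdname itq_symptom_items
#' @export
itq_impairment_items <- function() {
  c("Pimp1", "Pimp2", "Pimp3", "Dimp1", "Dimp2", "Dimp3")
}

#' Reference item response distributions
#'
#' Category counts (scores 0-4) of the 12 ITQ symptom items observed in a
#' published Italian community validation cohort of late adolescents
#' (N = 992 analyzed). These marginals anchor the default thresholds of the
#' synthetic cohort generator, so simulated item distributions mirror a real
#' late-adolescent sample.
#'
#' @return tibble with columns \code{item}, \code{factor}, and counts
#'   \code{k0}..\code{k4}.
#' @export
itq_item_reference <- function() {
  tibble::tribble(
    ~item,  ~factor, ~k0, ~k1, ~k2, ~k3, ~k4,
    "Re1",  "Re",    463, 266, 138,  79,  38,
    "Re2",  "Re",    338, 248, 176, 152,  71,
    "Av1",  "Av",    372, 233, 186, 118,  74,
    "Av2",  "Av",    427, 205, 157, 119,  77,
    "Hyp1", "Hyp",   463, 250, 127,  94,  50,
    "Hyp2", "Hyp",   504, 209, 139,  80,  50,
    "Dys1", "Dys",   156, 284, 263, 201,  85,
    "Dys2", "Dys",   519, 216, 126,  82,  46,
    "Nsc1", "Nsc",   723, 132,  66,  38,  30,
    "Nsc2", "Nsc",   729, 139,  58,  39,  24,
    "Rel1", "Rel",   678, 190,  56,  46,  18,
    "Rel2", "Rel",   577, 238, 104,  53,  17
  )
}

#' Reference lifetime trauma-exposure and prevalence table
#'
#' Per-item lifetime endorsement of the 21-item ITEM trauma checklist by
#' gender, the intentional/unintentional/excluded classification agreed by
#' independent raters, aggregate exposure rows, and screened PTSD/cPTSD
#' prevalence rows, from the same published late-adolescent cohort. Counts
#' and percentages are as printed in the source report; percentages carry
#' the information needed to reconstruct the gender denominators (see
#' \code{\link{reconstruct_denominator}}).
#'
#' @return tibble with columns \code{row} (item number or aggregate label),
#'   \code{label}, \code{class} (\code{intentional}, \code{unintentional},
#'   \code{excluded} or NA for aggregates), \code{male_n}, \code{male_pct},
#'   \code{female_n}, \code{female_pct}, \code{total_n}, \code{total_pct}.
#' @export
item_exposure_reference <- function() {
  tibble::tribble(
    ~row, ~label,                               ~class,          ~male_n, ~male_pct, ~female_n, ~female_pct, ~total_n, ~total_pct,
    "1",  "Life-threatening illness",           "unintentional",  10,  2.00,  16,  3.22,  26,  2.61,
    "2",  "Someone close died in an awful manner", "unintentional", 91, 18.20, 154, 30.99, 245, 24.57,
    "3",  "Someone close life-threatening illness/accident", "unintentional", 217, 43.49, 247, 49.70, 464, 46.59,
    "4",  "Threatened with a weapon",           "intentional",    37,  7.39,  17,  3.41,  54,  5.41,
    "5",  "Physically assaulted by parent",     "intentional",    37,  7.41,  41,  8.23,  78,  7.82,
    "6",  "Physically assaulted by non-parent", "intentional",    84, 16.80,  45,  9.05, 129, 12.94,
    "7",  "Sexually assaulted by parent",       "intentional",     0,  0.00,   0,  0.00,   0,  0.00,
    "8",  "Sexually assaulted by non-parent",   "intentional",    10,  2.00,  22,  4.42,  32,  3.21,
    "9",  "Sexually harassed",                  "intentional",    14,  2.80,  66, 13.25,  80,  8.02,
    "10", "War or combat",                      "intentional",     2,  0.40,   0,  0.00,   2,  0.20,
    "11", "Held captive and/or tortured",       "intentional",     2,  0.40,   1,  0.20,   3,  0.30,
    "12", "Caused extreme suffering or death",  "excluded",        7,  1.40,   3,  0.60,  10,  1.00,
    "13", "Witnessed suffering or death",       "excluded",       55, 11.02,  80, 16.06, 135, 13.54,
    "14", "Technological accident",             "unintentional",  89, 17.84,  58, 11.67, 147, 14.76,
    "15", "Natural disaster",                   "unintentional", 288, 57.95, 309, 63.06, 597, 60.49,
    "16", "Man-made disaster",                  "unintentional",  30,  6.02,  19,  3.89,  49,  4.96,
    "17", "Stalked",                            "intentional",    35,  7.06,  50, 10.06,  85,  8.56,
    "18", "Bullied (online or offline)",        "intentional",    60, 12.07,  88, 17.71, 148, 14.89,
    "19", "Humiliated, put down, or insulted",  "intentional",   142, 28.63, 194, 39.03, 336, 33.84,
    "20", "Made to feel unloved or worthless",  "intentional",   162, 32.60, 249, 50.20, 411, 41.39,
    "21", "Neglected, ignored, or isolated",    "intentional",   141, 28.54, 199, 40.28, 340, 34.41,
    "any_unintentional", "Lifetime unintentional TE", NA,        404, 80.64, 421, 84.54, 825, 82.58,
    "any_intentional",   "Lifetime intentional TE",   NA,        269, 53.69, 336, 67.47, 605, 60.56,
    "any_te",            "Lifetime TE",               NA,        444, 88.62, 461, 92.57, 905, 90.59,
    "ptsd",              "PTSD",                      NA,         28,  5.63,  63, 12.96,  91,  9.26,
    "cptsd",             "cPTSD",                     NA,         10,  2.01,  30,  6.17,  40,  4.07
  )
}
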