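#' Grade mitral stenosis severity from the maximum valve opening area
#'
#' Applies the planimetric severity cutoffs: areas of at least 4.0 cm^2 are
#' graded as no stenosis, areas strictly between 1.5 and 4.0 cm^2 as mild,
#' areas from 1.0 to 1.5 cm^2 inclusive as moderate, and areas below 1.0 cm^2
#' as severe. The four intervals partition the non-negative axis, so exactly
#' one grade matches any valid area; there is no upper bound on the
#' no-stenosis grade.
#'
#' @param area_cm2 numeric vector of maximum mitral valve opening areas, cm^2
#' @return factor with levels `no_stenosis`, `mild`, `moderate`, `severe`
#' @export
#' @examples
#' classify_mva(c(2.7, 4.0, 1.0, 0.9))
classify_mva <- function(area_cm2) {
  if (!is.numeric(area_cm2) || length(area_cm2) == 0L)
    stop_validation("area_cm2 must be a non-empty numeric vector")
  if (anyNA(area_cm2) || any(area_cm2 < 0))
    stop_validation("areas must be non-negative and non-missing")
  grade <- ifelse(area_cm2 >= 4.0, "no_stenosis",
           ifelse(area_cm2 > 1.5, "mild",
           ifelse(area_cm2 >= 1.0, "moderate", "severe")))
  factor(grade, levels = grade_levels())
}

#' Summarise a cohort of valve-area measurements
#'
#' @param areas numeric vector of MVA measurements in cm^2, one per exam
#' @return tibble with one row per grade: `grade`, `n`, `fraction`, and
#'   `percent` (rounded to one decimal, the convention used when reporting
#'   cohort composition)
#' @export
summarize_cohort <- function(areas) {
  if (!is.numeric(areas) || length(areas) == 0L)
    stop_validation("areas must be a non-empty numeric vector")
  grades <- classify_mva(areas)
  tab <- table(grades)
  tibble(
    grade = factor(grade_levels(), levels = grade_levels()),
    n = as.integer(tab[grade_levels()]),
    fraction = as.numeric(tab[grade_levels()]) / length(areas),
    percent = round(100 * as.numeric(tab[grade_levels()]) / length(areas), 1)
  )
}

#' Reference cohort of 30 TEE planimetry measurements
#'
#' The packaged reference cohort: maximum mitral valve opening areas for 30
#' transesophageal echocardiogram exams (one per patient) measured by the
#' planimetry pipeline, together with the severity grade reported for each.
#' Useful as a worked fixture for [classify_mva()] and [summarize_cohort()].
#'
#' @return tibble with columns `exam`, `mva_cm2`, `reported_grade`
#' @export
mva_reference_cohort <- function() {
  path <- system.file("extdata", "table1_mva.csv", package = "echoplanim",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble(exam = as.integer(df$exam),
         mva_cm2 = as.numeric(df$mva_cm2),
         reported_grade = factor(df$reported_grade, levels = grade_levels()))
}
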