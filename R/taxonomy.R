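#' Symptom taxonomy
#'
#' The fixed mapping from the nine tracked reflux symptoms to clinical
#' categories: heartburn, regurgitation and dysphagia are typical reflux
#' symptoms; chest pain, cough, globus and throat clearing are atypical
#' (laryngopharyngeal) symptoms; abdominal pain and nausea are non-reflux
#' symptoms. Any other label maps to category \code{"other"}.
#'
#' @return \code{known_symptoms()} returns the nine canonical symptom names.
#' @export
known_symptoms <- function() names(.symptom_category_map)

.symptom_category_map <- c(
  heartburn       = "typical",
  regurgitation   = "typical",
  dysphagia       = "typical",
  chest_pain      = "atypical",
  cough           = "atypical",
  globus          = "atypical",
  throat_clearing = "atypical",
  abdominal_pain  = "non_reflux",
  nausea          = "non_reflux"
)

#' @rdname known_symptoms
#' @param symptom character vector of symptom labels.
#' @param strict if \code{TRUE}, an unknown label is an error; otherwise it is
#'   assigned category \code{"other"} with a warning.
#' @export
symptom_category <- function(symptom, strict = FALSE) {
  cat <- unname(.symptom_category_map[symptom])
  unknown <- is.na(cat)
  if (any(unknown)) {
    if (strict)
      stop("unknown symptom label(s): ",
           paste(unique(symptom[unknown]), collapse = ", "))
    warning("unknown symptom label(s) mapped to category 'other': ",
            paste(unique(symptom[unknown]), collapse = ", "))
    cat[unknown] <- "other"
  }
  cat
}

symptom_categories <- function() c("typical", "atypical", "non_reflux")
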