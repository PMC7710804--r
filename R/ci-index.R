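#' @title Cognitive-impairment index
#'
#' @description The impairment score used to split an MS cohort into
#'   cognitively non-impaired (MSNI) and impaired (MSCI) groups. A battery
#'   of 20 neuropsychological parameters (MACFIMS-derived) is scored
#'   against normative data; a parameter is *failed* when performance is
#'   more than 1 standard deviation below the normative mean, and the CI
#'   index is the fraction of failed parameters. Subjects with index below
#'   0.2 are MSNI, above 0.35 MSCI, and in between borderline (excluded
#'   from all group statistics).
#' @name ci-index
NULL

N_MACFIMS_PARAMETERS <- 20L

#' Classification thresholds for the CI index
#'
#' @param msni_max index values strictly below this are MSNI (default 0.2).
#' @param msci_min index values strictly above this are MSCI (default
#'   0.35); values in `[msni_max, msci_min]` are borderline.
#' @return a list with elements `msni_max`, `msci_min`.
#' @export
ci_thresholds <- function(msni_max = 0.2, msci_min = 0.35) {
  stopifnot(msni_max > 0, msci_min >= msni_max, msci_min < 1)
  list(msni_max = msni_max, msci_min = msci_min)
}

#' Bundle one subject's battery scores with normative data
#'
#' @param subject_id character scalar.
#' @param scores named numeric vector of raw parameter scores; names must
#'   cover every parameter of the normative table.
#' @param normative data frame with columns `parameter`, `mean`, `sd`
#'   (`sd > 0`) and `higher_is_better` (logical; parameters where a *lower*
#'   raw score indicates better performance are sign-flipped before the
#'   1-SD failure rule is applied).
#' @param n_parameters expected battery size (default 20).
#' @return An object of class `macfims_scores`.
#' @export
macfims_scores <- function(subject_id, scores, normative,
                           n_parameters = N_MACFIMS_PARAMETERS) {
  stopifnot(is.data.frame(normative))
  need <- c("parameter", "mean", "sd", "higher_is_better")
  missing_cols <- setdiff(need, names(normative))
  if (length(missing_cols) > 0L)
    stop("normative table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(normative) != n_parameters)
    stop(sprintf("expected %d battery parameters, normative table has %d",
                 n_parameters, nrow(normative)), call. = FALSE)
  if (any(normative$sd <= 0))
    stop("normative sd must be > 0", call. = FALSE)
  miss <- setdiff(normative$parameter, names(scores))
  if (length(miss) > 0L)
    stop("missing parameter score(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  structure(list(subject_id = as.character(subject_id),
                 scores = scores[normative$parameter],
                 normative = normative),
            class = "macfims_scores")
}

#' Per-parameter failure indicators
#'
#' A parameter is failed when the direction-corrected z-score is strictly
#' below -1, i.e. performance is *more than* one standard deviation below
#' the normative mean (exactly 1 SD below is not a failure).
#'
#' @param x a [macfims_scores()] object.
#' @return integer vector of 0/1 flags, one per parameter, named.
#' @export
failure_indicators <- function(x) {
  stopifnot(inherits(x, "macfims_scores"))
  nt <- x$normative
  z <- (as.numeric(x$scores) - nt$mean) / nt$sd
  z <- ifelse(nt$higher_is_better, z, -z)
  setNames(as.integer(z < -1), nt$parameter)
}

#' CI index from failure flags
#'
#' The fraction of failed battery parameters: `n_failed / n_parameters`.
#'
#' @param flags vector of 0/1 failure indicators.
#' @return numeric in `[0, 1]`.
#' @export
ci_index <- function(flags) {
  stopifnot(all(flags %in% c(0L, 1L)))
  mean(as.integer(flags))
}

#' Classify a CI index value
#'
#' @param value CI index in `[0, 1]` (vectorized; `NA` maps to
#'   `"unknown"`).
#' @param thresholds a [ci_thresholds()] list.
#' @return character vector of labels `"MSNI"`, `"borderline"`, `"MSCI"`
#'   or `"unknown"`. Both boundary values belong to `"borderline"`.
#' @export
classify_ci <- function(value, thresholds = ci_thresholds()) {
  if (any(!is.na(value) & (value < 0 | value > 1)))
    stop("ci_index must lie in [0, 1]", call. = FALSE)
  out <- rep("unknown", length(value))
  ok <- !is.na(value)
  out[ok & value < thresholds$msni_max] <- "MSNI"
  out[ok & value >= thresholds$msni_max &
        value <= thresholds$msci_min] <- "borderline"
  out[ok & value > thresholds$msci_min] <- "MSCI"
  out
}

#' Score a subject's battery and classify impairment
#'
#' @inheritParams failure_indicators
#' @param thresholds a [ci_thresholds()] list.
#' @return list with `ci_index`, `n_failed`, `label` and the per-parameter
#'   `flags`.
#' @export
ci_classification <- function(x, thresholds = ci_thresholds()) {
  flags <- failure_indicators(x)
  idx <- ci_index(flags)
  list(ci_index = idx, n_failed = sum(flags),
       label = classify_ci(idx, thresholds), flags = flags)
}

#' Read a normative table
#'
#' Delimited text with columns `parameter`, `mean`, `sd`,
#' `higher_is_better` (TRUE/FALSE or 1/0).
#'
#' @param path file path.
#' @return data frame usable as the `normative` argument of
#'   [macfims_scores()].
#' @export
read_normative_table <- function(path) {
  sep <- detect_sep(path)
  nt <- read.table(path, header = TRUE, sep = sep,
                   stringsAsFactors = FALSE, strip.white = TRUE,
                   fileEncoding = "UTF-8-BOM", comment.char = "")
  nt$higher_is_better <- as.logical(nt$higher_is_better)
  nt
}

#' Read a battery score table
#'
#' Delimited text with a `subject_id` column plus one named column per
#' battery parameter.
#'
#' @param path file path.
#' @param normative normative table ([read_normative_table()]).
#' @return list of [macfims_scores()] objects, one per row.
#' @export
read_macfims_scores <- function(path, normative) {
  sep <- detect_sep(path)
  tb <- read.table(path, header = TRUE, sep = sep,
                   stringsAsFactors = FALSE, strip.white = TRUE,
                   fileEncoding = "UTF-8-BOM", comment.char = "",
                   check.names = FALSE)
  if (!"subject_id" %in% names(tb))
    stop("score table is missing column subject_id", call. = FALSE)
  lapply(seq_len(nrow(tb)), function(k) {
    row <- tb[k, setdiff(names(tb), "subject_id"), drop = FALSE]
    macfims_scores(tb$subject_id[k],
                   setNames(as.numeric(row), names(row)), normative,
                   n_parameters = nrow(normative))
  })
}
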