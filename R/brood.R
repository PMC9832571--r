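#' Fit the brood-cells vs cavity-length regression
#'
#' For species whose brood cells cannot always be counted directly (e.g.
#' bees without organized cells, or nests from which adults emerged before
#' inspection), the number of cells is estimated from the length of the
#' cavity occupied by provisions. The calibration is an ordinary least
#' squares regression of counted cells (or pupal cocoons) on occupied
#' cavity length, fitted on the subset of nests with both measurements.
#'
#' @param train nest records with both `brood_cells` and `cavity_length`
#'   present; at least 3 rows with non-degenerate lengths.
#' @param bee_taxon optional label; defaults to the training records'
#'   taxon.
#' @return object of class `cells_length_model`: list with `bee_taxon`,
#'   `intercept` (cells), `slope` (cells per mm), `n_train`, `r_squared`,
#'   and the underlying `lm` fit.
#' @export
fit_cells_vs_length <- function(train, bee_taxon = NULL) {
  keep <- !is.na(train$brood_cells) & !is.na(train$cavity_length)
  train <- train[keep, , drop = FALSE]
  if (nrow(train) < 3)
    md_contract_error("need >= 3 nests with both brood_cells and cavity_length")
  if (var(train$cavity_length) == 0)
    md_contract_error("cavity lengths are all equal: regression undefined")
  fit <- lm(brood_cells ~ cavity_length, data = train)
  slope <- unname(coef(fit)[2])
  if (slope <= 0)
    warning("cells-vs-length slope is not positive; check the training data",
            call. = FALSE)
  structure(list(bee_taxon = bee_taxon %||% train$bee_taxon[1],
                 intercept = unname(coef(fit)[1]), slope = slope,
                 n_train = nrow(train),
                 r_squared = summary(fit)$r.squared, fit = fit),
            class = "cells_length_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cells_length_model <- function(x, ...) {
  cat(sprintf(
    "cells ~ length for %s: intercept %.3f, slope %.4f cells/mm (n = %d, r2 = %.3f)\n",
    x$bee_taxon, x$intercept, x$slope, x$n_train, x$r_squared))
  invisible(x)
}

#' Predict a brood-cell count from cavity length
#'
#' The linear prediction is rounded to the nearest integer and floored at
#' 1: cells are counts and a completed nest holds at least one cell.
#' Predictions below 1 are clamped with a warning.
#'
#' @param model a `cells_length_model`.
#' @param cavity_length occupied cavity length(s) in mm.
#' @return integer vector of estimated cell counts (>= 1).
#' @export
predict_cells <- function(model, cavity_length) {
  if (!inherits(model, "cells_length_model"))
    md_contract_error("model must be a cells_length_model")
  if (anyNA(cavity_length) || any(cavity_length < 0))
    md_validation_error("cavity_length must be non-negative and non-missing")
  raw <- model$intercept + model$slope * cavity_length
  pred <- as.integer(round(raw))
  if (any(pred < 1)) {
    warning(sprintf("%d prediction(s) below 1 cell clamped to 1",
                    sum(pred < 1)), call. = FALSE)
    pred[pred < 1] <- 1L
  }
  pred
}

#' Impute missing brood-cell counts from cavity length
#'
#' Applies per-species cells-vs-length models to nests whose `brood_cells`
#' is missing but whose `cavity_length` is recorded. Direct counts are
#' never overwritten; imputed records are flagged in a new `estimated`
#' column.
#'
#' @param nests validated nest-record table.
#' @param models named list of `cells_length_model` objects, keyed by bee
#'   taxon. Only taxa present in this list are imputed.
#' @return `nests` with `brood_cells` filled where imputable and a logical
#'   `estimated` column.
#' @export
impute_brood_cells <- function(nests, models) {
  if (length(models) > 0 && is.null(names(models)))
    md_contract_error("models must be a named list keyed by bee taxon")
  nests$estimated <- FALSE
  todo <- is.na(nests$brood_cells) & !is.na(nests$cavity_length)
  missing_model <- unique(nests$bee_taxon[todo &
                                          !(nests$bee_taxon %in% names(models))])
  if (length(missing_model) > 0)
    md_contract_error(paste0("no cells-vs-length model for taxa needing ",
                             "imputation: ",
                             paste(missing_model, collapse = ", ")))
  for (bt in intersect(names(models), unique(nests$bee_taxon[todo]))) {
    sel <- todo & nests$bee_taxon == bt
    nests$brood_cells[sel] <- predict_cells(models[[bt]],
                                            nests$cavity_length[sel])
    nests$estimated[sel] <- TRUE
  }
  still <- is.na(nests$brood_cells)
  if (any(still))
    md_contract_error(sprintf(
      "%d nest(s) left without brood_cells after imputation", sum(still)))
  nests
}

#' Fit imputation models for the length-measured taxa of a nest table
#'
#' Convenience wrapper: for each taxon in `taxa` (defaults to every taxon
#' with at least one missing count), fits [fit_cells_vs_length()] on that
#' taxon's complete records.
#'
#' @param nests validated nest-record table.
#' @param taxa character vector of bee taxa to calibrate.
#' @return named list of `cells_length_model`.
#' @export
fit_imputation_models <- function(nests, taxa = NULL) {
  if (is.null(taxa))
    taxa <- sort(unique(nests$bee_taxon[is.na(nests$brood_cells)]))
  models <- lapply(taxa, function(bt)
    fit_cells_vs_length(nests[nests$bee_taxon == bt, , drop = FALSE],
                        bee_taxon = bt))
  setNames(models, taxa)
}
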