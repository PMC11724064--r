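#' Pearson correlation between two rating series
#'
#' Product-moment correlation with a two-sided p-value from the exact
#' t-distribution transform, as used to compare automated hair-coverage
#' percentages with expert ratings. No multiple-testing correction is
#' applied.
#'
#' @param x,y Equal-length numeric series (length >= 3) with nonzero
#'   variance.
#' @return A list with `r`, `p_value` and `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("series lengths differ")
  if (length(x) < 3) abort("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("correlation undefined for a zero-variance series",
      class = "leafhair_undefined_correlation"
    )
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Root-mean-square error between two series
#'
#' `sqrt(mean((x - y)^2))`, in the units of the inputs (percentage points
#' for hair-coverage ratings).
#'
#' @param x,y Equal-length numeric series (length >= 1).
#' @return Non-negative scalar.
#' @export
rmse <- function(x, y) {
  if (length(x) != length(y)) abort("series lengths differ")
  if (length(x) < 1) abort("need at least one pair")
  sqrt(mean((x - y)^2))
}

#' Signed rating error
#'
#' `measured - actual`: positive values are overestimation, negative
#' underestimation. (The evaluator-bias statistic often labeled "absolute
#' error" in rating studies; the sign is retained deliberately.)
#'
#' @param measured,actual Ratings in percent.
#' @return `measured - actual`.
#' @export
signed_error <- function(measured, actual) measured - actual

#' Read a ratings table
#'
#' Interchange CSV with one row per evaluator-image-method:
#' columns `evaluator_id`, `evaluator_class` (expert / non_expert / novice
#' / model / truth), `image_id`, `method` (slice_classification /
#' manual_rating), `value` (percent 0..100).
#'
#' @param path CSV path.
#' @return A validated tibble of rating records.
#' @export
read_ratings <- function(path) {
  r <- readr::read_csv(path, show_col_types = FALSE)
  validate_ratings(r)
}

validate_ratings <- function(records) {
  need <- c("evaluator_id", "image_id", "method", "value")
  missing <- setdiff(need, names(records))
  if (length(missing) > 0) {
    abort(paste("ratings table lacks columns:", paste(missing, collapse = ", ")))
  }
  if (!"evaluator_class" %in% names(records)) records$evaluator_class <- NA_character_
  if (any(records$value < 0 | records$value > 100, na.rm = TRUE)) {
    abort("rating values must lie in [0, 100]")
  }
  dup <- duplicated(records[c("evaluator_id", "image_id", "method")])
  if (any(dup)) abort("duplicate (evaluator, image, method) records")
  tibble::as_tibble(records)
}

#' Compare rating panels against a reference series
#'
#' Treats the reference evaluator's values (typically the automated
#' cascade output) as actual and every other evaluator's values as
#' measured. For each evaluator and method it computes per-image signed
#' errors ([signed_error()]) plus an agreement summary (Pearson R with
#' p-value, RMSE, n). Images without a reference value are excluded with a
#' warning. The tidy error table is the interchange format for
#' evaluator-bias dot plots.
#'
#' @param records Rating records (see [read_ratings()]).
#' @param reference_id `evaluator_id` of the reference series.
#' @return A `leafhair_panels` list: `summaries` (one row per
#'   evaluator-method: `r`, `p_value`, `rmse`, `mean_error`, `n`) and
#'   `errors` (one row per evaluator-image-method: `value`, `reference`,
#'   `error`, `abs_error`).
#' @export
compare_panels <- function(records, reference_id) {
  records <- validate_ratings(records)
  ref <- records[records$evaluator_id == reference_id, , drop = FALSE]
  if (nrow(ref) == 0) abort(sprintf("reference evaluator '%s' not found", reference_id))
  ref <- dplyr::distinct(ref, .data$image_id, .data$value)
  if (anyDuplicated(ref$image_id) > 0) {
    abort("reference series has conflicting values for an image")
  }
  others <- records[records$evaluator_id != reference_id, , drop = FALSE]
  no_ref <- setdiff(unique(others$image_id), ref$image_id)
  if (length(no_ref) > 0) {
    warn(sprintf(
      "excluding %d image(s) without a reference value: %s",
      length(no_ref), paste(no_ref, collapse = ", ")
    ))
    others <- others[others$image_id %in% ref$image_id, , drop = FALSE]
  }
  errors <- dplyr::inner_join(
    others,
    dplyr::rename(ref, reference = "value"),
    by = "image_id"
  )
  errors <- dplyr::mutate(errors,
    error = signed_error(.data$value, .data$reference),
    abs_error = abs(.data$error)
  )
  errors <- dplyr::arrange(errors, .data$evaluator_id, .data$method, .data$image_id)
  summaries <- dplyr::group_by(errors, .data$evaluator_id, .data$evaluator_class, .data$method)
  summaries <- dplyr::summarise(
    summaries,
    r = if (dplyr::n() >= 3 && stats::sd(.data$value) > 0 && stats::sd(.data$reference) > 0) {
      pearson_r(.data$value, .data$reference)$r
    } else {
      NA_real_
    },
    p_value = if (dplyr::n() >= 3 && stats::sd(.data$value) > 0 && stats::sd(.data$reference) > 0) {
      pearson_r(.data$value, .data$reference)$p_value
    } else {
      NA_real_
    },
    rmse = rmse(.data$value, .data$reference),
    mean_error = mean(.data$error),
    n = dplyr::n(),
    .groups = "drop"
  )
  structure(
    list(
      summaries = summaries,
      errors = errors[c(
        "evaluator_id", "evaluator_class", "method", "image_id",
        "value", "reference", "error", "abs_error"
      )],
      reference_id = reference_id
    ),
    class = "leafhair_panels"
  )
}

#' @export
print.leafhair_panels <- function(x, ...) {
  cat(sprintf(
    "<leafhair_panels> %d evaluator-method series vs reference '%s'\n",
    nrow(x$summaries), x$reference_id
  ))
  print(x$summaries)
  invisible(x)
}

#' @method tidy leafhair_panels
#' @export
tidy.leafhair_panels <- function(x, ...) x$errors

#' @method glance leafhair_panels
#' @export
glance.leafhair_panels <- function(x, ...) x$summaries

#' Write panel-comparison tables
#'
#' Exports the tidy per-image error table and the per-evaluator agreement
#' summaries as CSV.
#'
#' @param panels A [compare_panels()] result.
#' @param out_dir Output directory.
#' @return Invisibly, the two file paths.
#' @export
write_panel_csvs <- function(panels, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ep <- file.path(out_dir, "panel_errors.csv")
  sp <- file.path(out_dir, "panel_summaries.csv")
  readr::write_csv(panels$errors, ep)
  readr::write_csv(panels$summaries, sp)
  invisible(c(errors = ep, summaries = sp))
}

#' Evaluator-bias dot plot
#'
#' Per-image signed errors by evaluator, faceted by method, with the
#' zero-error line dashed in red — the standard way to visualise
#' over/underestimation of rating panels against the automated reference.
#'
#' @param object A `leafhair_panels` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot leafhair_panels
#' @export
autoplot.leafhair_panels <- function(object, ...) {
  ggplot2::ggplot(
    object$errors,
    ggplot2::aes(x = .data$evaluator_id, y = .data$error, shape = .data$evaluator_id)
  ) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "red") +
    ggplot2::geom_jitter(width = 0.1, height = 0) +
    ggplot2::facet_wrap(~method) +
    ggplot2::labs(
      x = NULL, y = "signed error (measured - reference, %)",
      shape = NULL
    )
}
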