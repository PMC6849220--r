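# Phenotype formulas: chlorophyll a/b/total from two absorbances with
# leaf-area normalization, and relative-expression fold change.

#' Chlorophyll content from absorbances at 664 and 649 nm
#'
#' Adds, per sample,
#' `chl_a = 13.36*A664 - 5.19*A649`,
#' `chl_b = 27.43*A649 - 8.12*A664`, and
#' `chl_total = 5.24*A664 + 22.24*A649`
#' (which is identically `chl_a + chl_b`). Values are in formula units
#' (concentration in the extract); a warning is attached when a component is
#' negative, which indicates absorbances outside the formula's valid range.
#'
#' @param data Data frame with numeric columns `A664` and `A649`.
#' @return The input tibble with `chl_a`, `chl_b`, `chl_total` appended.
#' @export
chlorophyll_content <- function(data) {
  stopifnot(is.data.frame(data), all(c("A664", "A649") %in% names(data)))
  if (any(data$A664 < 0 | data$A649 < 0, na.rm = TRUE)) {
    abort("absorbances must be non-negative")
  }
  out <- data |>
    mutate(chl_a = 13.36 * .data$A664 - 5.19 * .data$A649,
           chl_b = 27.43 * .data$A649 - 8.12 * .data$A664,
           chl_total = 5.24 * .data$A664 + 22.24 * .data$A649)
  n_neg <- sum(out$chl_a < 0 | out$chl_b < 0, na.rm = TRUE)
  if (n_neg > 0) {
    warn(paste0(n_neg, " sample(s) with a negative chlorophyll component; ",
                "absorbance ratio outside the formula's valid range"))
  }
  as_tibble(out)
}

#' Normalize chlorophyll amounts to leaf area
#'
#' Concentration times extract volume is an amount; dividing by the leaf area
#' used for the extraction gives amount per cm^2. Appends `<col>_per_cm2` for
#' each requested column.
#'
#' @param data Data frame with the chlorophyll columns plus `volume_ml`
#'   (extract volume, default column of 20 ml if absent) and `leaf_area_cm2`.
#' @param cols Columns to normalize (default the three chlorophyll columns
#'   present).
#' @return The tibble with per-area columns appended.
#' @export
normalize_per_area <- function(data, cols = intersect(c("chl_a", "chl_b", "chl_total"),
                                                      names(data))) {
  stopifnot(is.data.frame(data), "leaf_area_cm2" %in% names(data))
  if (length(cols) == 0) abort("no chlorophyll columns to normalize")
  if (any(data$leaf_area_cm2 <= 0, na.rm = TRUE)) {
    abort("leaf_area_cm2 must be positive")
  }
  vol <- if ("volume_ml" %in% names(data)) data$volume_ml else 20
  out <- data
  for (cl in cols) {
    out[[paste0(cl, "_per_cm2")]] <- out[[cl]] * vol / out$leaf_area_cm2
  }
  as_tibble(out)
}

#' Relative-expression fold change
#'
#' Reference-gene-normalized expression of the treated sample divided by the
#' same quantity for the control:
#' `fold = (target_treated / reference_treated) /
#'         (target_control / reference_control)`.
#' Inputs are linear-scale quantities.
#'
#' @param data Data frame with numeric columns `target_treated`,
#'   `reference_treated`, `target_control`, `reference_control`.
#' @return The tibble with a `fold` column appended.
#' @export
fold_change <- function(data) {
  need <- c("target_treated", "reference_treated",
            "target_control", "reference_control")
  stopifnot(is.data.frame(data), all(need %in% names(data)))
  if (any(data[need] < 0, na.rm = TRUE)) {
    abort("expression quantities must be non-negative")
  }
  if (any(data$reference_treated == 0 | data$reference_control == 0,
          na.rm = TRUE)) {
    abort("reference quantities must be positive")
  }
  if (any(data$target_control == 0, na.rm = TRUE)) {
    abort("control normalized ratio must be positive")
  }
  out <- data |>
    mutate(fold = (.data$target_treated / .data$reference_treated) /
             (.data$target_control / .data$reference_control))
  as_tibble(out)
}
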