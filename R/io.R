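# Parameter-table CSV input/output.

#' Write a parameter set as a CSV table
#'
#' Columns `(name, value, unit, source)`: `source` is `fitted` for free
#' parameters, `fixed` for Hill exponents, `derived` for steady-state-closed
#' decay rates.
#'
#' @param p A `parameter_set`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_parameter_table <- function(p, path) {
  unit_of <- function(nm) {
    if (grepl("^V_", nm)) "1/h"
    else if (grepl("^d_", nm)) "1/h"
    else if (nm == "k_a") "1/h^2"
    else "dimensionless"
  }
  flat_free <- flatten_parameters(p, include_derived = FALSE)
  fixed <- grepl("^n_", names(flat_free))
  src <- ifelse(fixed, "fixed", "fitted")
  der <- p$decay_derived
  df <- data.frame(
    name = c(names(flat_free), names(der)),
    value = unname(c(flat_free, der)),
    unit = vapply(c(names(flat_free), names(der)), unit_of, character(1)),
    source = c(src, rep("derived", length(der))),
    stringsAsFactors = FALSE)
  # EGFR-branch decay coefficients multiply t, so carry 1/h^2
  df$unit[df$name %in% paste0("d_", .egfr_branch_species)] <- "1/h^2"
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a parameter set from a CSV table
#'
#' Expects the [write_parameter_table()] layout. Derived decay rates are
#' always recomputed by steady-state closure; when the file carries derived
#' values too, they are cross-checked and a warning is raised on relative
#' mismatch above 1e-6. Missing derived rows are silently recomputed.
#'
#' @param path CSV path with columns `name`, `value` (and optionally `unit`,
#'   `source`).
#' @return A `parameter_set`.
#' @export
read_parameter_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("name", "value") %in% names(df)))
    stop("parameter table must have `name` and `value` columns")
  vals <- setNames(df$value, df$name)
  expected <- names(flatten_parameters(reference_parameters(),
                                       include_derived = FALSE))
  unknown <- setdiff(df$name, c(expected, paste0("d_", .derived_decay_species)))
  if (length(unknown))
    stop("unknown parameter name(s): ", paste(unknown, collapse = ", "),
         "; valid names: ", paste(expected, collapse = ", "))
  missing <- setdiff(expected, df$name)
  if (length(missing))
    stop("parameter table missing: ", paste(missing, collapse = ", "))
  p <- unflatten_parameters(vals[expected])
  file_der <- intersect(paste0("d_", .derived_decay_species), df$name)
  if (length(file_der)) {
    rel <- abs(vals[file_der] - p$decay_derived[file_der]) /
      pmax(abs(p$decay_derived[file_der]), 1e-12)
    if (any(rel > 1e-6))
      warning("derived decay rate(s) in file disagree with steady-state ",
              "closure (recomputed): ",
              paste(file_der[rel > 1e-6], collapse = ", "))
  }
  p
}
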