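#' Cell-line radiosensitivity parameters
#'
#' The reduced parameter triple of the microdosimetric-kinetic survival
#' model: `alpha0` (Gy^-1), the intrinsic linear coefficient before the
#' radiation-quality correction; `beta0` (Gy^-2), the quadratic
#' coefficient for acute exposure; and `repair_rate` (h^-1), the combined
#' first-order rate at which potentially lethal lesions are resolved
#' (sub-lethal damage repair).  Optional standard deviations carry the
#' marginal posterior uncertainty of each parameter.
#'
#' @param alpha0 Linear coefficient, Gy^-1 (>= 0).
#' @param beta0 Quadratic coefficient, Gy^-2 (>= 0).
#' @param repair_rate Sub-lethal damage repair rate, h^-1 (> 0).
#' @param alpha0_sd,beta0_sd,repair_rate_sd Optional uncertainties.
#' @param label Optional cell-line label.
#' @return A list of class `cell_params`.
#' @export
cell_params <- function(alpha0, beta0, repair_rate,
                        alpha0_sd = NA_real_, beta0_sd = NA_real_,
                        repair_rate_sd = NA_real_, label = NULL) {
  stopifnot(is_scalar_num(alpha0), is_scalar_num(beta0), is_scalar_num(repair_rate))
  if (alpha0 < 0) abort("`alpha0` must be >= 0.")
  if (beta0 < 0) abort("`beta0` must be >= 0.")
  if (repair_rate <= 0) abort("`repair_rate` must be > 0.")
  for (s in c(alpha0_sd, beta0_sd, repair_rate_sd)) {
    if (!is.na(s) && (!is.numeric(s) || s < 0)) abort("parameter SDs must be >= 0.")
  }
  structure(
    list(
      alpha0 = alpha0, beta0 = beta0, repair_rate = repair_rate,
      alpha0_sd = as.numeric(alpha0_sd), beta0_sd = as.numeric(beta0_sd),
      repair_rate_sd = as.numeric(repair_rate_sd), label = label
    ),
    class = "cell_params"
  )
}

#' @export
print.cell_params <- function(x, ...) {
  fmt <- function(v, s) if (is.na(s)) sprintf("%.4g", v) else sprintf("%.4g ± %.4g", v, s)
  cat(sprintf(
    "<cell_params%s>\n  alpha0 = %s Gy^-1\n  beta0  = %s Gy^-2\n  (a+c)  = %s h^-1\n",
    if (is.null(x$label)) "" else paste0(" ", x$label),
    fmt(x$alpha0, x$alpha0_sd), fmt(x$beta0, x$beta0_sd),
    fmt(x$repair_rate, x$repair_rate_sd)
  ))
  invisible(x)
}

#' Bundled human-melanoma parameter sets
#'
#' Radiosensitivity parameters for three human melanoma cell lines (HX34,
#' M8 primary, Mel-J metastatic) as published from Markov chain Monte
#' Carlo fits to 60Co gamma-ray clonogenic survival data; see the package
#' README for the modelling context.
#'
#' @param cell_line One of `"HX34"`, `"M8"`, `"Mel-J"`, or `NULL` to get
#'   the full table.
#' @return A [cell_params()] object, or a tibble when `cell_line` is
#'   `NULL`.
#' @examples
#' melanoma_params("M8")
#' @export
melanoma_params <- function(cell_line = NULL) {
  path <- system.file("extdata", "melanoma_cell_lines.csv", package = "microkin")
  tab <- read_cell_params_table(path)
  if (is.null(cell_line)) {
    return(tab)
  }
  row <- tab[tab$cell_line == cell_line, ]
  if (nrow(row) != 1) {
    abort(sprintf(
      "unknown cell line '%s' (available: %s).",
      cell_line, paste(tab$cell_line, collapse = ", ")
    ))
  }
  cell_params(row$alpha0, row$beta0, row$repair_rate,
    row$alpha0_sd, row$beta0_sd, row$repair_rate_sd,
    label = row$cell_line
  )
}

param_cols <- c("alpha0", "beta0", "repair_rate")

read_cell_params_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(param_cols, names(tab))
  if (length(missing)) {
    abort(paste0("parameter file lacks column(s): ", paste(missing, collapse = ", ")))
  }
  for (col in param_cols) {
    if (any(!is.finite(tab[[col]]))) {
      abort(sprintf("column '%s' contains missing or non-numeric values.", col))
    }
    if (any(tab[[col]] < 0)) abort(sprintf("column '%s' contains negative values.", col))
  }
  for (col in paste0(param_cols, "_sd")) {
    if (!col %in% names(tab)) tab[[col]] <- NA_real_
  }
  if (!"cell_line" %in% names(tab)) tab$cell_line <- paste0("line_", seq_len(nrow(tab)))
  tibble::as_tibble(tab)
}

#' Read / write cell-line parameters
#'
#' CSV with columns `alpha0`, `beta0`, `repair_rate` (plus optional
#' `*_sd` and `cell_line` columns), one row per parameter set.  Round
#' trips exactly at full double precision.
#'
#' @param path File path.
#' @param cell_line Row to select when the file holds several; default
#'   the first.
#' @return [load_cell_params()] returns a [cell_params()];
#'   [save_cell_params()] returns `path` invisibly.
#' @export
load_cell_params <- function(path, cell_line = NULL) {
  tab <- read_cell_params_table(path)
  row <- if (is.null(cell_line)) tab[1, ] else tab[tab$cell_line == cell_line, ]
  if (nrow(row) != 1) abort(sprintf("cell line '%s' not found in %s.", cell_line, path))
  cell_params(row$alpha0, row$beta0, row$repair_rate,
    row$alpha0_sd, row$beta0_sd, row$repair_rate_sd,
    label = row$cell_line
  )
}

#' @param params A [cell_params()] object.
#' @rdname load_cell_params
#' @export
save_cell_params <- function(params, path) {
  stopifnot(inherits(params, "cell_params"))
  tab <- tibble::tibble(
    cell_line = params$label %||% "unnamed",
    alpha0 = params$alpha0, alpha0_sd = params$alpha0_sd,
    beta0 = params$beta0, beta0_sd = params$beta0_sd,
    repair_rate = params$repair_rate, repair_rate_sd = params$repair_rate_sd
  )
  readr::write_csv(tab, path)
  invisible(path)
}
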