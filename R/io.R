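#' Read and validate a person-level cost table
#'
#' Expects a CSV with header
#' `person_id,area_id,sex,age_years,amg_code,cost_eur` (an `age_band` column
#' is recomputed regardless). Rows violating the record invariants --
#' non-positive cost, unknown AMG code, sex outside \{0, 1\}, negative age --
#' are rejected with a line-numbered report; counts of accepted and rejected
#' rows are logged.
#'
#' @param path CSV file path.
#' @return Validated person data frame; attribute `rejected` holds the
#'   line-numbered rejection report (line numbers refer to the file,
#'   including the header line).
#' @export
read_person_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("person_id", "area_id", "sex", "age_years", "amg_code", "cost_eur")
  miss <- setdiff(req, names(x))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!nrow(x)) stop("empty person table: ", path)
  codes <- amg_catalog()$amg_code
  why <- character(nrow(x))
  bad <- rep(FALSE, nrow(x))
  flag <- function(cond, msg) {
    cond[is.na(cond)] <- TRUE
    why[cond & !bad] <<- msg
    bad <<- bad | cond
  }
  flag(!(x$cost_eur > 0), "cost_eur must be > 0")
  flag(!(x$amg_code %in% codes), "unknown amg_code")
  flag(!(x$sex %in% c(0, 1)), "sex must be 0 or 1")
  flag(!(x$age_years >= 0), "age_years must be >= 0")
  rejected <- data.frame(line = which(bad) + 1L, reason = why[bad])
  if (nrow(rejected))
    message(nrow(rejected), " row(s) rejected, ", sum(!bad), " accepted; ",
            "first rejection at line ", rejected$line[1], " (",
            rejected$reason[1], ")")
  out <- x[!bad, req, drop = FALSE]
  if (!nrow(out)) stop("no valid rows in ", path)
  out$sex <- as.integer(out$sex)
  out$age_years <- as.integer(out$age_years)
  out$amg_code <- as.integer(out$amg_code)
  out$age_band <- age_band(out$age_years)
  out <- out[, c("person_id", "area_id", "sex", "age_years", "age_band",
                 "amg_code", "cost_eur")]
  attr(out, "rejected") <- rejected
  out
}

#' Write a person-level cost table
#'
#' @param records Person data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_person_table <- function(records, path) {
  cols <- c("person_id", "area_id", "sex", "age_years", "amg_code", "cost_eur")
  utils::write.csv(records[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an area-level financing table
#'
#' CSV with header `area_id,covered_population,historical_share`.
#'
#' @param path CSV file path.
#' @return Validated area data frame.
#' @export
read_area_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("area_id", "covered_population", "historical_share")
  miss <- setdiff(req, names(x))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!nrow(x)) stop("empty area table: ", path)
  if (any(x$covered_population <= 0))
    stop("covered populations must be positive")
  if (abs(sum(x$historical_share) - 1) > 1e-6)
    stop("historical shares must sum to 1")
  x
}

#' Write an area-level financing table
#'
#' @param areas Area data frame with `area_id`, `covered_population`,
#'   `historical_share`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_area_table <- function(areas, path) {
  utils::write.csv(areas[, c("area_id", "covered_population",
                             "historical_share")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialise a fitted cost GLM to structured text
#'
#' @param model A `cost_glm`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(list(
    spec = model$spec,
    coefficients = as.list(model$coefficients),
    dispersion = model$dispersion,
    dispersion_pearson = model$dispersion_pearson,
    deviance = model$deviance,
    null_deviance = model$null_deviance,
    loglik = model$loglik,
    n = model$n, k = model$k,
    converged = model$converged,
    iterations = model$iterations,
    encoding = model$encoding
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
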