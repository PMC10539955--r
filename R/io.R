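#' Read a table of integrated three-ion spectra
#'
#' Comma-separated text with a header row; required columns `sample_id`,
#' `m360`, `m361`, `m362` (glucose fragment) and optional `replicate`.
#' Validation failures name the offending column.
#'
#' @param path File path.
#' @return Data frame of spectra.
#' @export
read_spectra <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "m360", "m361", "m362")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("spectra file '", path, "' is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (cc in c("m360", "m361", "m362"))
    if (!is.numeric(d[[cc]]))
      stop("column '", cc, "' must be numeric in '", path, "'", call. = FALSE)
  .spectra_matrix(d)  # range validation
  d
}

#' Read an acetone standard curve
#'
#' Comma-separated text with columns `p_known` (known water enrichment,
#' fraction) and either `m1_fraction` directly or raw areas `m57`, `m58`,
#' `m59` from which the M+1 fraction is computed.
#'
#' @param path File path.
#' @return Data frame with columns `p_known`, `m1_fraction`.
#' @export
read_standard_curve <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"p_known" %in% names(d))
    stop("standard-curve file '", path, "' is missing column: p_known",
         call. = FALSE)
  if (!"m1_fraction" %in% names(d)) {
    need <- c("m57", "m58", "m59")
    miss <- setdiff(need, names(d))
    if (length(miss))
      stop("standard-curve file '", path, "' is missing column(s): ",
           paste(c(miss), collapse = ", "),
           " (or provide m1_fraction directly)", call. = FALSE)
    tot <- d$m57 + d$m58 + d$m59
    d$m1_fraction <- d$m58 / tot
  }
  d[, c("p_known", "m1_fraction")]
}

#' Write an estimates table with a run-metadata header
#'
#' Writes the per-sample results as comma-separated text. Metadata lines
#' (software version, isotope constants, window and baseline modes) are
#' prefixed with `#` so the file stays machine-readable with
#' `read.csv(..., comment.char = "#")`.
#'
#' @param fit A [gng_fit()] object, or a plain data frame of results.
#' @param path Output path.
#' @param metadata Write the commented metadata header?
#' @return `path`, invisibly.
#' @export
write_results <- function(fit, path, metadata = TRUE) {
  est <- if (inherits(fit, "gng_fit")) fit$estimates else fit
  con <- file(path, "w")
  on.exit(close(con))
  if (metadata) {
    ver <- as.character(utils::packageVersion("gngmida"))
    writeLines(sprintf("# gngmida %s", ver), con)
    if (inherits(fit, "gng_fit")) {
      writeLines(sprintf("# analysis: %s; window: %s; baseline: %s",
                         fit$type, fit$model$window, fit$baseline$mode), con)
      writeLines(sprintf("# 13C abundance: %.7g", fit$model$isotopes$C[2]), con)
    }
  }
  utils::write.csv(est, con, row.names = FALSE)
  invisible(path)
}
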