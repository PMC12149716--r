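#' Read and write dose profiles, sessions and spectra as CSV
#'
#' Plain-text exchange formats: profiles have columns `position_mm`,
#' `value`; sessions `detector_id, field_side_cm, SSD_cm, bias_V,
#' polarity, reading, repeat_index`; spectra `particle_id, Emin_MeV,
#' Emax_MeV, weight`.
#'
#' @param x object to write (data frame, or `quenching_input` for
#'   spectra).
#' @param path file path.
#' @return Readers return a data frame (or `quenching_input`); writers
#'   return `path` invisibly.
#' @name smallfield_io
NULL

#' @rdname smallfield_io
#' @export
write_profile_csv <- function(x, path) {
  stopifnot(all(c("position_mm", "value") %in% names(x)))
  utils::write.csv(x[c("position_mm", "value")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname smallfield_io
#' @export
read_profile_csv <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("position_mm", "value") %in% names(d)))
  d
}

#' @rdname smallfield_io
#' @export
write_session_csv <- function(x, path) {
  cols <- c("detector_id", "field_side_cm", "SSD_cm", "bias_V",
            "polarity", "reading", "repeat_index")
  stopifnot(all(cols %in% names(x)))
  utils::write.csv(x[cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname smallfield_io
#' @export
read_session_csv <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("detector_id", "field_side_cm", "reading") %in% names(d)))
  d
}

#' @rdname smallfield_io
#' @param field_side field side in cm recorded with spectra.
#' @export
write_spectra_csv <- function(x, path) {
  stopifnot(inherits(x, "quenching_input"))
  p <- x$particles
  utils::write.csv(data.frame(particle_id = seq_len(nrow(p)),
                              Emin_MeV = p$Emin_MeV, Emax_MeV = p$Emax_MeV,
                              weight = p$weight),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname smallfield_io
#' @export
read_spectra_csv <- function(path, field_side) {
  d <- utils::read.csv(path)
  quenching_input(field_side,
                  data.frame(Emin_MeV = d$Emin_MeV, Emax_MeV = d$Emax_MeV,
                             weight = if (is.null(d$weight)) 1 else d$weight))
}

#' Write or read a synthetic field specification as YAML
#'
#' @param spec a [field_spec()] (writer) or file path (reader).
#' @param path destination file.
#' @return The reader returns a [field_spec()]; the writer returns
#'   `path` invisibly.
#' @export
write_field_spec_yaml <- function(spec, path) {
  stopifnot(inherits(spec, "field_spec"))
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_field_spec_yaml
#' @export
read_field_spec_yaml <- function(path) {
  d <- yaml::read_yaml(path)
  field_spec(d$nominal_side, d$penumbra_sigma,
             unlist(d$center_offset), d$msr_side)
}

#' Serialize a bounded fit result as JSON
#'
#' Parameters, covariance, bounds and convergence metadata of a
#' [fit_bounded()] result, written with `jsonlite`.
#'
#' @param fit a `bounded_fit`.
#' @param path destination file; `NULL` returns the JSON string.
#' @return `path` (or the JSON string) invisibly.
#' @export
write_fit_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "bounded_fit"))
  obj <- list(params = fit$params,
              covariance = fit$covariance,
              bounds = fit$bounds,
              converged = fit$converged,
              message = fit$message,
              residual_rms = sqrt(mean(fit$residuals^2)))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(invisible(as.character(js)))
  writeLines(js, path)
  invisible(path)
}
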