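#' Serialize lumpy objects to and from JSON
#'
#' Plain-text persistence for field realizations and priors: hyperparameters
#' and arrays are stored in a single JSON document readable by any language.
#'
#' @param x a [lump_field()] or [lump_prior()].
#' @param path file path to write.
#' @return `write_lumpy_json` returns `path` invisibly; `read_lumpy_json`
#'   returns the reconstructed object.
#' @export
write_lumpy_json <- function(x, path) {
  if (inherits(x, "lump_field")) {
    obj <- list(type = "lump_field",
                centers = unname(x$centers), amplitudes = x$amplitudes,
                lump_variance = x$lump_variance, max_lumps = x$max_lumps)
  } else if (inherits(x, "lump_prior")) {
    obj <- list(type = "lump_prior",
                mean_lumps = x$mean_lumps, amplitude = x$amplitude,
                lump_variance = x$lump_variance, domain = x$domain,
                max_lumps = x$max_lumps)
  } else stop("x must be a lump_field or lump_prior")
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_lumpy_json
#' @export
read_lumpy_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(obj$type, "lump_field")) {
    centers <- matrix(as.numeric(obj$centers), ncol = 2)
    lump_field(centers, obj$amplitudes, obj$lump_variance, obj$max_lumps)
  } else if (identical(obj$type, "lump_prior")) {
    lump_prior(obj$mean_lumps, obj$amplitude, obj$lump_variance,
               domain = obj$domain, max_lumps = obj$max_lumps)
  } else stop("unrecognized JSON object type")
}

#' Write burden curves to CSV
#'
#' One `time` column plus one column per population member (or a single
#' `burden` column for a bare curve).
#'
#' @param x a `virtual_population`, or a numeric burden vector with a
#'   `times` attribute-style companion vector given via `times`.
#' @param path file path to write.
#' @param times time vector when `x` is a bare numeric curve.
#' @return `path`, invisibly.
#' @export
write_burden_csv <- function(x, path, times = NULL) {
  if (inherits(x, "virtual_population")) {
    df <- data.frame(time = x$times, x$burden)
    names(df) <- c("time", paste0("member_", seq_len(x$J)))
  } else {
    if (is.null(times)) stop("times is required for a bare burden curve")
    df <- data.frame(time = times, burden = as.numeric(x))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
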