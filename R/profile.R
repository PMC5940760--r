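#' Construct a SAXS scattering profile
#'
#' A scattering profile is a tibble with columns `s` (momentum transfer
#' \eqn{s = 4\pi\sin\theta/\lambda}, 1/Angstrom), `intensity` (arbitrary
#' units) and `sigma` (per-point standard error, same units as the intensity;
#' all `NA` when the experiment reported none). Every downstream stage of the
#' package consumes this object.
#'
#' Validity requires a strictly increasing, strictly positive `s` grid
#' (\eqn{s = 0} is never tabulated -- the forward scattering comes from Guinier
#' extrapolation), at least 50 points, and a span `max(s)/min(s) >= 10` so that
#' the invariant integrals are meaningful. Negative intensities are allowed:
#' they occur legitimately in background-subtracted data. Present sigmas must
#' be finite and positive.
#'
#' @param s Numeric vector of momentum-transfer values, 1/Angstrom.
#' @param intensity Numeric vector of intensities, arbitrary units.
#' @param sigma Optional numeric vector of standard errors; `NULL` for none.
#' @param label Free-text identifier attached as an attribute.
#' @return A tibble of class `saxs_profile`.
#' @examples
#' p <- saxs_profile(seq(0.001, 0.5, length.out = 100),
#'                   exp(-seq(0.001, 0.5, length.out = 100)^2 * 300))
#' @export
saxs_profile <- function(s, intensity, sigma = NULL, label = NULL) {
  s <- as.numeric(s)
  intensity <- as.numeric(intensity)
  if (is.null(sigma)) sigma <- rep(NA_real_, length(s))
  out <- tibble(s = s, intensity = intensity, sigma = as.numeric(sigma))
  class(out) <- c("saxs_profile", class(out))
  attr(out, "label") <- label %||% "profile"
  validate_saxs_profile(out)
}

#' Coerce a data frame to a SAXS profile
#'
#' @param x A data frame with columns `s` and `intensity` (optionally `sigma`).
#' @param label Free-text identifier.
#' @return A validated `saxs_profile` tibble.
#' @export
as_saxs_profile <- function(x, label = NULL) {
  stopifnot(is.data.frame(x), all(c("s", "intensity") %in% names(x)))
  saxs_profile(x$s, x$intensity, if ("sigma" %in% names(x)) x$sigma else NULL,
               label = label)
}

#' Validate a SAXS profile
#'
#' @param x A `saxs_profile` (or data frame shaped like one).
#' @return `x`, invisibly unchanged, or an error describing the violation.
#' @export
validate_saxs_profile <- function(x) {
  if (nrow(x) < 50)
    abort(sprintf("profile has %d points; at least 50 are required", nrow(x)))
  if (anyNA(x$s) || any(!is.finite(x$s)) || any(x$s <= 0))
    abort("all s values must be finite and > 0")
  if (is.unsorted(x$s, strictly = TRUE))
    abort("s values must be strictly increasing")
  if (max(x$s) / min(x$s) < 10)
    abort("s range too narrow: max(s)/min(s) must be >= 10")
  if (any(!is.finite(x$intensity)))
    abort("intensities must all be finite")
  if (has_sigma(x) && any(!is.finite(x$sigma) | x$sigma <= 0))
    abort("when present, sigma must be finite and > 0 at every point")
  x
}

#' Does a profile carry experimental errors?
#'
#' @param x A `saxs_profile`.
#' @return `TRUE` when the sigma column holds any values.
#' @export
has_sigma <- function(x) {
  !is.null(x$sigma) && any(!is.na(x$sigma))
}

#' Read a 1-D SAXS profile from a whitespace-delimited text file
#'
#' Reads the de-facto SAXS `.dat` convention: whitespace-delimited columns
#' `s`, `I(s)` and optionally `sigma`; columns beyond the third are ignored.
#' Lines starting with `#` and lines whose first token is not numeric are
#' treated as comments/headers and skipped without shifting the data. Rows
#' with a non-finite intensity or a non-positive / non-finite sigma are
#' dropped (with a message giving the count); negative intensities are kept,
#' as they are legitimate after background subtraction.
#'
#' @param path Path to the file.
#' @param label Identifier for the profile; defaults to the file name.
#' @return A `saxs_profile` tibble.
#' @export
read_profile <- function(path, label = NULL) {
  if (!file.exists(path)) abort(sprintf("cannot read '%s': no such file", path))
  lines <- readLines(path, warn = FALSE)
  toks <- strsplit(trimws(lines), "[ \t,;]+")
  first <- vapply(toks, function(t) if (length(t)) t[[1]] else "", character(1))
  numeric_first <- suppressWarnings(!is.na(as.numeric(first))) &
    !startsWith(trimws(lines), "#")
  data_idx <- which(numeric_first & lengths(toks) >= 2L)
  if (length(data_idx) < 1)
    abort(sprintf("'%s' contains no parseable data rows", path))

  ncol_data <- min(3L, min(lengths(toks[data_idx])))
  vals <- suppressWarnings(lapply(seq_len(ncol_data), function(j) {
    as.numeric(vapply(toks[data_idx], `[[`, character(1), j))
  }))
  s <- vals[[1]]; intensity <- vals[[2]]
  sigma <- if (ncol_data >= 3) vals[[3]] else rep(NA_real_, length(s))

  keep <- is.finite(s) & is.finite(intensity) &
    (is.na(sigma) | (is.finite(sigma) & sigma > 0))
  if (any(!keep)) {
    message(sprintf("read_profile: dropped %d row(s) with non-finite values or non-positive sigma",
                    sum(!keep)))
    s <- s[keep]; intensity <- intensity[keep]; sigma <- sigma[keep]
    data_idx <- data_idx[keep]
  }
  if (length(s) < 50)
    abort(sprintf("'%s' has %d valid data rows; at least 50 are required",
                  path, length(s)))
  bad <- which(diff(s) <= 0)
  if (length(bad))
    abort(sprintf("'%s': s values not strictly increasing at line %d",
                  path, data_idx[bad[1] + 1L]))
  saxs_profile(s, intensity, if (all(is.na(sigma))) NULL else sigma,
               label = label %||% basename(path))
}

#' Write a SAXS profile to a whitespace-delimited text file
#'
#' Writes a one-line `#` header followed by 3 data columns (2 when no sigma
#' is present), with enough digits that `read_profile()` round-trips the
#' values to at least 6 significant figures.
#'
#' @param profile A `saxs_profile`.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  validate_saxs_profile(profile)
  fmt <- function(v) formatC(v, format = "e", digits = 8)
  rows <- if (has_sigma(profile)) {
    paste(fmt(profile$s), fmt(profile$intensity), fmt(profile$sigma))
  } else {
    paste(fmt(profile$s), fmt(profile$intensity))
  }
  header <- sprintf("# %s | s [1/A]  I(s) [arb]%s", profile_label(profile),
                    if (has_sigma(profile)) "  sigma [arb]" else "")
  ok <- tryCatch({
    writeLines(c(header, rows), path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) abort(sprintf("cannot write '%s'", path))
  invisible(path)
}

#' Label of a profile
#' @param x A `saxs_profile`.
#' @return The free-text identifier.
#' @export
profile_label <- function(x) attr(x, "label") %||% "profile"

#' @export
print.saxs_profile <- function(x, ...) {
  cat(sprintf("<saxs_profile '%s': %d points, s in [%.4g, %.4g] 1/A, sigma %s>\n",
              profile_label(x), nrow(x), min(x$s), max(x$s),
              if (has_sigma(x)) "present" else "absent"))
  NextMethod()
}
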