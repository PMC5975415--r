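#' Laboratory reference thresholds for the five-marker panel
#'
#' Builds the set of positivity thresholds used by [classify_marker()] and
#' [mia_classify()]. Defaults are the kit reference ranges of the assay panel:
#' CA 125 is called positive above a menopause-dependent upper limit
#' (200 IU/L premenopausal, 35 IU/L postmenopausal; 1 U/ml and 1 IU/L are the
#' same quantity in CA 125 reporting, so no conversion is performed);
#' beta-2 microglobulin is positive above its upper reference limit; and
#' transferrin, apolipoprotein A1 and prealbumin are positive below their
#' lower reference limits. Comparisons are strict: a value exactly at a limit
#' is inside the normal range and therefore negative.
#'
#' The unused opposite bounds of the two-sided kit ranges (`b2m_lower`,
#' `transferrin_upper`, `apoa1_upper`, `prealbumin_upper`) are retained for
#' documentation and config round-tripping; they play no role in positivity.
#'
#' @param ca125_premenopausal_upper Upper limit for CA 125, premenopausal, IU/L.
#' @param ca125_postmenopausal_upper Upper limit for CA 125, postmenopausal, IU/L.
#' @param b2m_upper Upper limit for beta-2 microglobulin, g/L.
#' @param transferrin_lower Lower limit for transferrin, g/L.
#' @param apoa1_lower Lower limit for apolipoprotein A1, g/L.
#' @param prealbumin_lower Lower limit for prealbumin (transthyretin), g/L.
#' @param b2m_lower,transferrin_upper,apoa1_upper,prealbumin_upper Documentary
#'   opposite bounds of the two-sided reference ranges.
#' @return An object of class `mia_thresholds`: a named list of the ten bounds.
#' @examples
#' th <- marker_thresholds()
#' th$ca125_postmenopausal_upper
#' @seealso [read_thresholds()], [write_thresholds()]
#' @export
marker_thresholds <- function(ca125_premenopausal_upper = 200,
                              ca125_postmenopausal_upper = 35,
                              b2m_upper = 2.46,
                              transferrin_lower = 2.24,
                              apoa1_lower = 1.24,
                              prealbumin_lower = 0.216,
                              b2m_lower = 1.22,
                              transferrin_upper = 4.06,
                              apoa1_upper = 2.02,
                              prealbumin_upper = 0.328) {
  th <- list(
    ca125_premenopausal_upper = ca125_premenopausal_upper,
    ca125_postmenopausal_upper = ca125_postmenopausal_upper,
    b2m_upper = b2m_upper,
    transferrin_lower = transferrin_lower,
    apoa1_lower = apoa1_lower,
    prealbumin_lower = prealbumin_lower,
    b2m_lower = b2m_lower,
    transferrin_upper = transferrin_upper,
    apoa1_upper = apoa1_upper,
    prealbumin_upper = prealbumin_upper
  )
  for (nm in names(th)) {
    v <- th[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("threshold '", nm, "' must be a single positive number", call. = FALSE)
  }
  if (th$b2m_lower >= th$b2m_upper)
    stop("b2m_lower must be below b2m_upper", call. = FALSE)
  if (th$transferrin_lower >= th$transferrin_upper)
    stop("transferrin_lower must be below transferrin_upper", call. = FALSE)
  if (th$apoa1_lower >= th$apoa1_upper)
    stop("apoa1_lower must be below apoa1_upper", call. = FALSE)
  if (th$prealbumin_lower >= th$prealbumin_upper)
    stop("prealbumin_lower must be below prealbumin_upper", call. = FALSE)
  structure(th, class = "mia_thresholds")
}

#' @export
print.mia_thresholds <- function(x, ...) {
  cat("Marker positivity thresholds (strict comparisons)\n")
  cat(sprintf("  CA 125      > %g IU/L (premenopausal) / > %g IU/L (postmenopausal)\n",
              x$ca125_premenopausal_upper, x$ca125_postmenopausal_upper))
  cat(sprintf("  B2M         > %g g/L\n", x$b2m_upper))
  cat(sprintf("  Transferrin < %g g/L\n", x$transferrin_lower))
  cat(sprintf("  ApoA1       < %g g/L\n", x$apoa1_lower))
  cat(sprintf("  Prealbumin  < %g g/L\n", x$prealbumin_lower))
  invisible(x)
}

#' Read or write a thresholds configuration file
#'
#' Thresholds are stored as flat YAML (or JSON, which YAML parses) with keys
#' matching the [marker_thresholds()] arguments, so reference ranges of a
#' different kit can be substituted without touching code. Missing keys fall
#' back to the defaults.
#'
#' @param path Path to a YAML/JSON thresholds file.
#' @return `read_thresholds()` returns a `mia_thresholds` object;
#'   `write_thresholds()` returns `path` invisibly.
#' @export
read_thresholds <- function(path) {
  if (!file.exists(path)) stop("thresholds file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  known <- names(formals(marker_thresholds))
  extra <- setdiff(names(vals), known)
  if (length(extra))
    stop("unknown threshold keys: ", paste(extra, collapse = ", "), call. = FALSE)
  do.call(marker_thresholds, vals)
}

#' @param thresholds A `mia_thresholds` object.
#' @rdname read_thresholds
#' @export
write_thresholds <- function(thresholds, path) {
  stopifnot(inherits(thresholds, "mia_thresholds"))
  yaml::write_yaml(unclass(thresholds), path)
  invisible(path)
}
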