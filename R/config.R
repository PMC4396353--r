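#' Load model configuration over the defaults
#'
#' Reads a YAML configuration file and deep-merges it over
#' [default_parameters()]; `overrides` (a named list using the same nested
#' structure) is merged last. Unknown keys are rejected so that typos
#' cannot silently leave a default in place, and the merged bundle is
#' re-validated.
#'
#' Response-evidence entries are given as `{responders: n, total: N}`;
#' the proportion is recomputed.
#'
#' @param path Path to a YAML file, or `NULL` for overrides only.
#' @param overrides Named nested list merged after the file.
#' @return A validated `cc_parameters` bundle.
#' @export
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeLines("analysis:\n  horizon_months: 36", f)
#' load_config(f)$analysis$horizon_months
load_config <- function(path = NULL, overrides = list()) {
  par <- default_parameters()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- tryCatch(yaml::read_yaml(path), error = function(e)
      stop("failed to parse config '", path, "': ", conditionMessage(e),
           call. = FALSE))
    if (length(cfg)) par <- merge_config(par, cfg, key = "")
  }
  if (length(overrides)) par <- merge_config(par, overrides, key = "")
  par <- rebuild_evidence(par)
  class(par) <- "cc_parameters"
  validate_parameters(par)
  par
}

# recursive merge that refuses keys absent from the default skeleton
merge_config <- function(base, new, key) {
  if (is.null(names(new)) || any(names(new) == ""))
    stop("config section '", sub("^\\.", "", key),
         "' must be a named mapping", call. = FALSE)
  for (nm in names(new)) {
    here <- paste0(key, ".", nm)
    if (!nm %in% names(base))
      stop("unknown configuration key: ", sub("^\\.", "", here),
           call. = FALSE)
    if (is.list(base[[nm]]) && !inherits(base[[nm]], "response_evidence")) {
      if (!is.list(new[[nm]]))
        stop("configuration key ", sub("^\\.", "", here),
             " must be a mapping", call. = FALSE)
      base[[nm]] <- merge_config(base[[nm]], new[[nm]], here)
    } else if (inherits(base[[nm]], "response_evidence")) {
      ev <- new[[nm]]
      if (!is.list(ev) || !all(c("responders", "total") %in% names(ev)))
        stop("configuration key ", sub("^\\.", "", here),
             " needs fields responders and total", call. = FALSE)
      base[[nm]] <- list(responders = ev$responders, total = ev$total)
      class(base[[nm]]) <- "pending_evidence"
    } else if (!is.null(names(base[[nm]]))) {
      val <- new[[nm]]
      if (is.list(val)) val <- unlist(val)
      bad <- setdiff(names(val), names(base[[nm]]))
      if (length(bad))
        stop("unknown configuration key: ", sub("^\\.", "", here), ".",
             bad[1], call. = FALSE)
      if (is.null(names(val)) && length(val) == length(base[[nm]])) {
        base[[nm]][] <- val
      } else {
        base[[nm]][names(val)] <- val
      }
    } else {
      base[[nm]] <- new[[nm]]
    }
  }
  base
}

# recompute proportions for evidence replaced during a merge
rebuild_evidence <- function(x) {
  if (inherits(x, "pending_evidence"))
    return(response_evidence(x$responders, x$total))
  if (inherits(x, "response_evidence"))
    return(response_evidence(x$responders, x$total))
  if (is.list(x)) {
    for (nm in names(x)) x[[nm]] <- rebuild_evidence(x[[nm]])
  }
  x
}

#' Write a parameter bundle to YAML
#'
#' Serialises a bundle so that [load_config()] on the result reproduces
#' it exactly (round-trip property).
#'
#' @param par Parameter bundle.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(par, path) {
  strip <- function(x) {
    if (inherits(x, "response_evidence"))
      return(list(responders = x$responders, total = x$total))
    if (is.list(x)) return(lapply(x, strip))
    if (!is.null(names(x))) return(as.list(x))
    x
  }
  yaml::write_yaml(strip(unclass(par)), path)
  invisible(path)
}
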