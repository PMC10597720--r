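# Internal helpers shared across modules.

#' @keywords internal
kva_error <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "kva_error"), call = call))
}

#' Stable content fingerprint
#'
#' MD5 of the canonical JSON rendering of an R object. Used to stamp
#' compiled model libraries and corneal schemas so that a grade computed
#' against an edited chart/scale/schema fails loudly instead of silently
#' regrading.
#'
#' @param x an R object composed of lists, vectors and scalars.
#' @return a 32-character hex string.
#' @keywords internal
kva_fingerprint <- function(x) {
  txt <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = 10, null = "null")
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf), add = TRUE)
  writeLines(as.character(txt), tf)
  unname(tools::md5sum(tf))
}

# Format a logMAR value as the canonical chart string ("-0.3", "0.0", "1.0").
fmt_logmar <- function(m) {
  format(round(m, 1), nsmall = 1, trim = TRUE, scientific = FALSE)
}

# Format a Snellen denominator as "20/D"; integral denominators drop ".0".
fmt_snellen <- function(den) {
  d <- if (abs(den - round(den)) < 1e-9) {
    format(round(den), scientific = FALSE, trim = TRUE)
  } else {
    format(den, scientific = FALSE, trim = TRUE, drop0trailing = TRUE)
  }
  paste0("20/", d)
}

# Format a decimal acuity; always keeps at least one decimal place
# ("1.0", "2.0") and trims trailing zeros otherwise ("0.8", "0.63").
fmt_decimal <- function(x) {
  s <- format(x, scientific = FALSE, trim = TRUE, drop0trailing = TRUE)
  if (!grepl(".", s, fixed = TRUE)) s <- paste0(s, ".0")
  s
}

# Read a YAML or JSON config file based on its extension.
read_config_file <- function(path) {
  if (!file.exists(path)) {
    kva_error(sprintf("config file not found: '%s'", path), "kva_config_error")
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    kva_error(sprintf("unsupported config extension '.%s' (use .yaml or .json)", ext),
              "kva_config_error")
  }
}
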