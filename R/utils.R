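# internal helpers shared across modules

logistic <- function(x) stats::plogis(x)

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @importFrom rlang %||% abort warn
NULL

# md5 of a character scalar (via a temp file; tools::md5sum is file-based)
md5_string <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  con <- file(f, open = "wb")
  writeBin(charToRaw(enc2utf8(x)), con)
  close(con)
  unname(tools::md5sum(f))
}

md5_file <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: '%s'", path), class = "anchorpanel_io_error")
  }
  unname(tools::md5sum(path))
}

# canonical unordered-pair key: ids sorted lexicographically, joined by "|"
pair_key <- function(a, b) {
  purrr::map2_chr(a, b, function(x, y) paste(sort(c(x, y)), collapse = "|"))
}

# stable short fragment identifying a panel version, used to prefix trial ids
version_fragment <- function(panel_version) {
  substr(md5_string(panel_version), 1L, 6L)
}

stop_config <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "anchorpanel_config_error")
}

stop_parse <- function(msg, code, ...) {
  abort(sprintf(msg, ...), class = c(paste0("anchorpanel_parse_", code), "anchorpanel_parse_error"))
}
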