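`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ehg <- function(..., class = "ehg_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' @keywords internal
assert_that <- function(cond, ..., class = "ehg_error") {
  if (!isTRUE(cond)) stop_ehg(..., class = class)
  invisible(TRUE)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)

# stable 8-hex content hash used to tag pipeline artifacts (md5 of a file's bytes)
hash_string <- function(s) {
  tf <- tempfile()
  on.exit(unlink(tf), add = TRUE)
  writeLines(s, tf)
  substr(unname(tools::md5sum(tf)), 1L, 8L)
}
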