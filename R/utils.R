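# Internal helpers: seed substreams, validation, logging.

# All randomness in the package flows from one base seed through named
# substreams, so any stage can be re-run in isolation and still reproduce.
# splitmix-style integer mixing done in doubles (exact below 2^53), reduced
# into [1, 2^31 - 2] so the result is always a valid R/C++ seed.
substream_seed <- function(base_seed, name, index = 0L) {
  stopifnot(is.numeric(base_seed), length(base_seed) == 1L)
  h <- (base_seed %% 2147483647) + 1
  chars <- utf8ToInt(as.character(name))
  for (ch in chars) {
    h <- (h * 31 + ch) %% 2147483647
  }
  h <- (h * 2654435761 + (index %% 2147483647) * 40503 + 12345) %% 2147483629
  as.integer(h + 1)
}

with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name))
  }
  if (integer && x != round(x)) {
    abort(sprintf("`%s` must be a whole number.", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s].", name,
                  format(lower), format(upper)))
  }
  invisible(x)
}

zf_log <- function(fmt, ..., file = getOption("zipforest.log_file", NULL)) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  sprintf(fmt, ...))
  if (isTRUE(getOption("zipforest.verbose", FALSE))) message(line)
  if (!is.null(file)) cat(line, "\n", file = file, append = TRUE)
  invisible(line)
}

# Feature columns of a ZIP table = everything except the identifier.
feature_columns <- function(zips) {
  setdiff(names(zips), "zip_id")
}

as_feature_matrix <- function(zips, features = NULL) {
  features <- features %||% feature_columns(zips)
  missing <- setdiff(features, names(zips))
  if (length(missing) > 0) {
    abort(paste0("Features absent from table: ",
                 paste(missing, collapse = ", ")))
  }
  m <- as.matrix(zips[features])
  storage.mode(m) <- "double"
  rownames(m) <- zips$zip_id
  m
}
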