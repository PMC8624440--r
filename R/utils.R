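# Internal helpers shared across modules.

# Deterministic sub-seed for a named random stream.  Adding a new stream name
# never perturbs draws taken from existing streams, and an optional counter
# lets batched rejection sampling advance without reusing a seed.
stream_seed <- function(seed, stream, counter = 0L) {
  streams <- c(genotypes = 1L, occurrence = 2L, covariates = 3L,
               followup = 4L, recurrence = 5L, echo = 6L, generic = 7L)
  i <- streams[[stream]]
  (as.double(seed) + i * 1000003 + as.double(counter) * 7919) %% 2147483647
}

with_stream_seed <- function(seed, stream, code, counter = 0L) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stream_seed(seed, stream, counter))
  force(code)
}

# 95% two-sided normal quantile used for every Wald-type interval.
z975 <- function() qnorm(0.975)

assert_columns <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")),
          class = "afprs_validation_error")
  }
  invisible(data)
}

# Strict 0/1 boolean parser: anything other than 0, 1 or empty is an error.
parse_bool01 <- function(x, col) {
  x <- as.character(x)
  x[!is.na(x) & trimws(x) == ""] <- NA_character_
  bad <- !is.na(x) & !x %in% c("0", "1")
  if (any(bad)) {
    abort(sprintf("column '%s' must be coded 0/1 (or empty); found: %s",
                  col, paste(unique(x[bad]), collapse = ", ")),
          class = "afprs_validation_error")
  }
  x == "1"
}

parse_num <- function(x, col) {
  x <- as.character(x)
  x[!is.na(x) & trimws(x) == ""] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) {
    abort(sprintf("column '%s' must be numeric; found: %s",
                  col, paste(unique(x[bad]), collapse = ", ")),
          class = "afprs_validation_error")
  }
  out
}

# Order-insensitive content hash used for report provenance.
content_hash <- function(x) rlang::hash(x)
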