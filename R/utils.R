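# internal helpers shared across modules

# format a numeric at the report precision used throughout the tables
# (4 significant figures, round-half-even as implemented by signif())
format_sigfig <- function(x, digits = 4) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    format(signif(v, digits), scientific = FALSE, trim = TRUE)
  }, character(1))
  out
}

# round at report precision but keep numeric type
round_sigfig <- function(x, digits = 4) signif(x, digits)

assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          allow_null = FALSE, strict_lower = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(x))
    abort(sprintf("`%s` must be supplied.", name))
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict_lower && x <= lower) {
    abort(sprintf("`%s` must be > %s (got %s).", name, lower, x))
  }
  if (!strict_lower && x < lower) {
    abort(sprintf("`%s` must be >= %s (got %s).", name, lower, x))
  }
  if (x > upper) {
    abort(sprintf("`%s` must be <= %s (got %s).", name, upper, x))
  }
  invisible(x)
}

assert_columns <- function(data, cols, what = "input table") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0L) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(data)
}

maybe_set_seed <- function(seed) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
      abort("`seed` must be a single integer.")
    }
    set.seed(as.integer(seed))
  }
  invisible(seed)
}

# sdlog giving a lognormal with coefficient of variation `cv`
lognormal_sdlog <- function(cv) sqrt(log(1 + cv^2))
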