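#' @keywords internal
"_PACKAGE"

#' @useDynLib ctrseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang abort .data
#' @importFrom stats rnorm runif sd lm t.test pnorm qnorm coef var
#' @importFrom utils head tail
NULL

# Run code under a temporary RNG state seeded with `seed`; the caller's
# global RNG stream is left untouched.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic child seeds below 2^31, derived from a master seed.
derive_seeds <- function(seed, n, salt = 0L) {
  with_seed(seed + salt, sample.int(.Machine$integer.max - 1L, n))
}

stop_ctrseg <- function(msg, class) {
  abort(msg, class = c(class, "ctrseg_error"))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         open_lower = FALSE, open_upper = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open_lower) x > lower else x >= lower) &&
    (if (open_upper) x < upper else x <= upper)
  if (!ok) {
    stop_ctrseg(sprintf("`%s` must be a single finite number in %s%s, %s%s (got %s)",
                        name, if (open_lower) "(" else "[", format(lower),
                        format(upper), if (open_upper) ")" else "]",
                        paste(format(x), collapse = ", ")),
                "ctrseg_parameter_error")
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= min
  if (!ok) {
    stop_ctrseg(sprintf("`%s` must be an integer >= %d", name, min),
                "ctrseg_parameter_error")
  }
  invisible(as.integer(x))
}

CLASS_LEVELS <- c(background = 0L, lung = 1L, heart = 2L)

class_codes <- function(classes) {
  if (is.numeric(classes)) {
    codes <- as.integer(classes)
  } else {
    bad <- setdiff(classes, names(CLASS_LEVELS))
    if (length(bad) > 0) {
      stop_ctrseg(paste0("unknown class name(s): ", paste(bad, collapse = ", ")),
                  "ctrseg_parameter_error")
    }
    codes <- unname(CLASS_LEVELS[classes])
  }
  if (any(!codes %in% CLASS_LEVELS)) {
    stop_ctrseg("class codes must be in {0, 1, 2}", "ctrseg_parameter_error")
  }
  codes
}
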