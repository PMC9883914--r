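# internal helpers shared across modules

#' @importFrom withr with_seed
run_seeded <- function(seed, expr) {
  # evaluate expr under a fixed RNG state when a seed is given; a NULL seed
  # draws from (and advances) the session RNG
  if (is.null(seed)) {
    eval.parent(substitute(expr))
  } else {
    stopifnot(is.numeric(seed), length(seed) == 1L)
    withr::with_seed(as.integer(seed), eval.parent(substitute(expr)))
  }
}

stop_hk <- function(...) stop(sprintf(...), call. = FALSE)

check_proportion <- function(x, name, allow_one = TRUE) {
  hi_ok <- if (allow_one) x <= 1 else x < 1
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || !hi_ok)
    stop_hk("'%s' must be a proportion in [0,%s), got %s",
            name, if (allow_one) "1]" else "1", format(x))
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x))
    stop_hk("'%s' must be an integer >= %d", name, min)
  invisible(as.integer(x))
}

# stderr logging with levels; controlled via options(heterokaryon.verbose=)
hk_log <- function(fmt, ..., level = "INFO") {
  if (isFALSE(getOption("heterokaryon.verbose", TRUE))) return(invisible())
  message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
}
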