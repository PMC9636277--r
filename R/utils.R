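#' @keywords internal
"_PACKAGE"

#' @useDynLib grouprecip, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang abort .data
#' @importFrom stats setNames
NULL

# Numerically stable log(sum(exp(x))).
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

abort_invalid <- function(msg) {
  abort(msg, class = "grouprecip_invalid_argument")
}

abort_numeric_range <- function(msg) {
  abort(msg, class = "grouprecip_numeric_range")
}

abort_degenerate <- function(msg) {
  abort(msg, class = "grouprecip_degenerate_chain")
}

abort_no_convergence <- function(msg, last_state = NULL) {
  abort(msg, class = "grouprecip_no_convergence", last_state = last_state)
}

check_probability <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort_invalid(sprintf("`%s` must be a single probability in [0, 1].", name))
  }
  invisible(x)
}

check_error_rate <- function(e) {
  if (!is.numeric(e) || length(e) != 1L || is.na(e) || e < 0 || e >= 0.5) {
    abort_invalid("error rate `e` must lie in [0, 1/2).")
  }
  invisible(e)
}

check_benefit <- function(b) {
  if (!is.numeric(b) || length(b) != 1L || is.na(b) || b <= 1) {
    abort_invalid("benefit `b` must exceed the cost c = 1.")
  }
  invisible(b)
}

check_count <- function(x, name, min) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    abort_invalid(sprintf("`%s` must be an integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

check_selection <- function(s, name) {
  if (!is.numeric(s) || length(s) != 1L || !is.finite(s) || s < 0) {
    abort_invalid(sprintf("`%s` must be finite and non-negative.", name))
  }
  invisible(s)
}
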