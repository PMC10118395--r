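#' @importFrom rlang %||% abort warn inform .data
#' @importFrom tibble tibble as_tibble
#' @import Matrix
#' @importFrom methods as is
#' @importFrom stats rnorm rbinom runif setNames var cor sd coef
NULL

# stop with a consistent error class so callers/tests can catch precisely
sb_abort <- function(msg, class = "stepblup_error") {
  rlang::abort(msg, class = class)
}

sb_assert <- function(cond, msg, class = "stepblup_error") {
  if (!isTRUE(cond)) sb_abort(msg, class)
}

# symmetric positive-definite check via Cholesky
is_spd <- function(M, tol = 1e-10) {
  if (!isSymmetric(unname(as.matrix(M)), tol = 1e-8)) return(FALSE)
  ok <- tryCatch({
    chol(as.matrix(M))
    TRUE
  }, error = function(e) FALSE)
  ok
}

# default carcass trait names, in evaluation order
CARCASS_TRAITS <- c("CW", "EMA", "BF", "MS")
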