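# internal constants and argument checks shared across the package

.GRADES <- c("R0", "R1", "R2", "R3s", "R3a")
.REFERABLE_GRADES <- c("R2", "R3s", "R3a")
.PROB_COLS <- paste0("p_", .GRADES)
.THRESHOLD_COLS <- paste0("t_", .GRADES)
.THRESHOLD_GRID <- (0:9) / 10

abort_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_scalar_prob <- function(x, field, allow_one = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 &&
    (if (allow_one) x <= 1 else x < 1)
  if (!ok) {
    abort_field(field, if (allow_one) "must be a single probability in [0, 1]"
                else "must be a single probability in [0, 1)")
  }
  invisible(x)
}

check_scalar_nonneg <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    abort_field(field, "must be a single non-negative number")
  }
  invisible(x)
}

check_scalar_count <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 1 ||
      x != as.integer(x)) {
    abort_field(field, "must be a single positive integer")
  }
  invisible(as.integer(x))
}

`%||%` <- rlang::`%||%`

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
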