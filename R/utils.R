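#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data abort warn %||%
#' @importFrom stats sd median qnorm rpois runif rbeta rnorm optim
#'   coef glm binomial quantile t.test wilcox.test ks.test cor
#' @useDynLib twostepr, .registration = TRUE
NULL

PORTS <- c("left", "right")

port_to_int <- function(x) {
  i <- match(x, PORTS)
  if (anyNA(i)) abort("port labels must be 'left' or 'right'")
  i
}

int_to_port <- function(i) PORTS[i]

other_port <- function(x) ifelse(x == "left", "right", "left")

is_probability <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0 && x <= 1
}

#' @keywords internal
check_trials <- function(trials) {
  needed <- c("session_id", "trial_index", "choice", "transition",
              "outcome_port", "reward")
  missing <- setdiff(needed, names(trials))
  if (length(missing) > 0) {
    abort(paste0("trial table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  invisible(trials)
}

# per-row flag marking the first trial of each session, assuming trials
# are ordered within session
session_starts <- function(session_id) {
  n <- length(session_id)
  if (n == 0) return(integer(0))
  as.integer(c(TRUE, session_id[-1] != session_id[-n]))
}

# log-domain two-option softmax, max-subtracted: returns P(option 1)
softmax2 <- function(q1, q2) {
  m <- pmax(q1, q2)
  e1 <- exp(q1 - m)
  e1 / (e1 + exp(q2 - m))
}
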