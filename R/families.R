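#' Trajectory model families
#'
#' Six families describe how daily habit strength (SRBAI, 0--4 scale) evolves
#' over the decay phase: four polynomials in time plus two bounded decay
#' curves. The asymptotic family is an exponential approach to a lower
#' asymptote with a log rate constant; the logistic family is a four-parameter
#' sigmoid with distinct upper and lower asymptotes.
#'
#' @return A data frame with one row per family: `family`, `k_mean` (number of
#'   mean-structure parameters) and the comma-separated parameter names.
#' @export
trajectory_families <- function() {
  data.frame(
    family = c("constant", "linear", "quadratic", "cubic", "asymptotic", "logistic"),
    k_mean = c(1L, 2L, 3L, 4L, 3L, 4L),
    params = c("b0", "b0,b1", "b0,b1,b2", "b0,b1,b2,b3", "A,R0,lam", "L,U,m,s"),
    stringsAsFactors = FALSE
  )
}

# canonical family order; also the BIC tie-break order
.families <- c("constant", "linear", "quadratic", "cubic", "asymptotic", "logistic")

.k_mean <- c(constant = 1L, linear = 2L, quadratic = 3L, cubic = 4L,
             asymptotic = 3L, logistic = 4L)

.par_names <- list(
  constant   = "b0",
  linear     = c("b0", "b1"),
  quadratic  = c("b0", "b1", "b2"),
  cubic      = c("b0", "b1", "b2", "b3"),
  asymptotic = c("A", "R0", "lam"),
  logistic   = c("L", "U", "m", "s")
)

.check_family <- function(family) {
  if (length(family) != 1L || !family %in% .families) {
    stop("unknown trajectory family: ", paste(family, collapse = ", "), call. = FALSE)
  }
  family
}

#' Evaluate a trajectory family at given occasions
#'
#' Functional forms: `constant` b0; `linear` b0 + b1*t; `quadratic` and
#' `cubic` add the higher powers; `asymptotic`
#' f(t) = A + (R0 - A) * exp(-exp(lam) * t), so `R0` is the value at t = 0,
#' `A` the asymptote and `exp(lam)` the (positive) rate; `logistic`
#' f(t) = L + (U - L) / (1 + exp((t - m) / s)) with s > 0, decaying from the
#' upper asymptote `U` towards the lower asymptote `L`, halfway at t = m.
#'
#' @param family One of `"constant"`, `"linear"`, `"quadratic"`, `"cubic"`,
#'   `"asymptotic"`, `"logistic"`.
#' @param theta Numeric parameter vector, in the order documented above.
#' @param t Numeric vector of occasions (days since the start of the decay
#'   phase).
#' @return Numeric vector of fitted habit-strength values, same length as `t`.
#' @export
evaluate_trajectory <- function(family, theta, t) {
  .check_family(family)
  k <- .k_mean[[family]]
  if (length(theta) != k) {
    stop(sprintf("family '%s' needs %d parameters, got %d",
                 family, k, length(theta)), call. = FALSE)
  }
  theta <- as.numeric(theta)
  switch(family,
    constant   = rep(theta[1L], length(t)),
    linear     = theta[1L] + theta[2L] * t,
    quadratic  = theta[1L] + theta[2L] * t + theta[3L] * t^2,
    cubic      = theta[1L] + theta[2L] * t + theta[3L] * t^2 + theta[4L] * t^3,
    asymptotic = theta[1L] + (theta[2L] - theta[1L]) * exp(-exp(theta[3L]) * t),
    logistic   = theta[1L] + (theta[2L] - theta[1L]) / (1 + exp((t - theta[3L]) / theta[4L]))
  )
}

# box constraints for the nonlinear families; level parameters are allowed to
# roam a little outside the 0-4 response scale so boundary-flat fits converge
.traj_bounds <- function(family) {
  switch(family,
    asymptotic = list(lower = c(A = -1, R0 = -1, lam = log(1e-4)),
                      upper = c(A = 5, R0 = 5, lam = log(2))),
    logistic   = list(lower = c(L = -1, U = -1, m = -30, s = 0.25),
                      upper = c(L = 5, U = 5, m = 120, s = 60)),
    NULL
  )
}
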