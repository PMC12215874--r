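#' Analytic benchmark objectives
#'
#' Standard test surfaces with known minima, used to exercise the optimizers:
#' `"sphere"` (sum of squares, box `[-5, 5]^d`), `"rastrigin"`
#' (`10 d + sum(x^2 - 10 cos(2 pi x))`, box `[-5.12, 5.12]^d`) and
#' `"quadratic1d"` (`(x - 3)^2`, box `[1, 100]`).
#'
#' @param name One of `"sphere"`, `"rastrigin"`, `"quadratic1d"`.
#' @param dim Dimensionality (ignored for `"quadratic1d"`).
#' @return List with `objective` (callable), `bounds` ([bounds_spec()]),
#'   `optimum_position` and `optimum_value`.
#' @examples
#' b <- analytic_benchmark("sphere", dim = 2)
#' b$objective(c(0, 0))  # 0
#' @export
analytic_benchmark <- function(name = c("sphere", "rastrigin", "quadratic1d"),
                               dim = 10L) {
  name <- match.arg(name)
  switch(name,
    sphere = list(
      objective = function(x) sum(x^2),
      bounds = bounds_spec(-5, 5, dim),
      optimum_position = rep(0, dim),
      optimum_value = 0
    ),
    rastrigin = list(
      objective = function(x) 10 * length(x) + sum(x^2 - 10 * cos(2 * pi * x)),
      bounds = bounds_spec(-5.12, 5.12, dim),
      optimum_position = rep(0, dim),
      optimum_value = 0
    ),
    quadratic1d = list(
      objective = function(x) (x[1] - 3)^2,
      bounds = bounds_spec(1, 100, 1),
      optimum_position = 3,
      optimum_value = 0
    )
  )
}
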