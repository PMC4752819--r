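#' Anterior-posterior period gradient model
#'
#' Intrinsic oscillation periods in the presomitic mesoderm (PSM) are graded
#' along the anterior-posterior (A/P) axis: cells at the posterior tip
#' oscillate fastest and cells at the anterior end slowest. Positions are
#' expressed as a normalized A/P coordinate `x` in `[0, 1]`, with `x = 0` the
#' posterior tip and `x = 1` the anterior PSM end. The measured gradient spans
#' roughly 130 min (posterior) to 170 min (anterior); by default it is
#' interpolated linearly, but a different monotone shape can be plugged in.
#'
#' @param T_posterior period at the posterior tip, minutes. Must be smaller
#'   than `T_anterior`.
#' @param T_anterior period at the anterior end, minutes.
#' @param shape function mapping normalized position `x` in `[0,1]` to a
#'   normalized gradient level in `[0,1]`; must satisfy `shape(0) = 0`,
#'   `shape(1) = 1` and be non-decreasing. The default (identity) yields a
#'   linear period gradient.
#' @return an object of class `gradient_model`.
#' @examples
#' g <- period_gradient_model()
#' period_gradient(c(0, 0.5, 1), g) # 130 150 170
#' @export
period_gradient_model <- function(T_posterior = 130, T_anterior = 170,
                                  shape = identity) {
  stopifnot(is.numeric(T_posterior), is.numeric(T_anterior),
            length(T_posterior) == 1L, length(T_anterior) == 1L,
            is.function(shape))
  if (!(T_posterior < T_anterior)) {
    stop("`T_posterior` must be strictly smaller than `T_anterior`")
  }
  grid <- seq(0, 1, length.out = 201L)
  s <- shape(grid)
  if (abs(s[1L]) > 1e-9 || abs(s[201L] - 1) > 1e-9 || any(diff(s) < -1e-9)) {
    stop("`shape` must map [0,1] onto [0,1] monotonically with shape(0)=0, shape(1)=1")
  }
  structure(
    list(T_posterior = T_posterior, T_anterior = T_anterior, shape = shape),
    class = "gradient_model"
  )
}

#' @export
print.gradient_model <- function(x, ...) {
  cat(sprintf("A/P period gradient: %.4g min (posterior, x=0) -> %.4g min (anterior, x=1)\n",
              x$T_posterior, x$T_anterior))
  invisible(x)
}

#' Intrinsic period at a normalized A/P position
#'
#' @param x numeric vector of normalized A/P positions in `[0, 1]`
#'   (0 = posterior tip, 1 = anterior end).
#' @param model a [period_gradient_model()].
#' @return periods in minutes, same length as `x`.
#' @export
period_gradient <- function(x, model = period_gradient_model()) {
  stopifnot(inherits(model, "gradient_model"), is.numeric(x))
  if (any(x < 0 | x > 1 | is.na(x))) {
    stop("normalized A/P position `x` must lie in [0, 1]")
  }
  model$T_posterior + (model$T_anterior - model$T_posterior) * model$shape(x)
}

#' Mean intrinsic period over an A/P region
#'
#' Average of the period gradient over a sub-interval of the normalized A/P
#' axis, i.e. the expected intrinsic period of a cell sampled uniformly from
#' that region. For the default linear gradient this equals the period at the
#' interval midpoint; for other shapes the integral is evaluated numerically.
#'
#' @param region numeric length-2 vector `c(lo, hi)` with
#'   `0 <= lo < hi <= 1`. Conventional regions: posterior half "P/2" is
#'   `c(0, 0.5)`, anterior half "A/2" is `c(0.5, 1)`, tail bud is
#'   `c(0, 0.15)`.
#' @inheritParams period_gradient
#' @return mean period in minutes.
#' @examples
#' region_mean_period(c(0, 0.5))  # posterior half: 140
#' region_mean_period(c(0.5, 1))  # anterior half: 160
#' @export
region_mean_period <- function(region, model = period_gradient_model()) {
  stopifnot(inherits(model, "gradient_model"))
  region <- check_region(region)
  if (identical(model$shape, identity)) {
    # closed form for the linear gradient
    return(period_gradient(mean(region), model))
  }
  val <- stats::integrate(function(x) period_gradient(x, model),
                          region[1L], region[2L], rel.tol = 1e-10)$value
  val / diff(region)
}

check_region <- function(region) {
  if (!is.numeric(region) || length(region) != 2L || any(is.na(region))) {
    stop("`region` must be a numeric vector c(lo, hi)")
  }
  if (region[1L] < 0 || region[2L] > 1 || region[1L] >= region[2L]) {
    stop("`region` must be a non-empty sub-interval of [0, 1]")
  }
  region
}

# Named conventional regions of the normalized A/P axis.
REGION_P2 <- c(0, 0.5)
REGION_A2 <- c(0.5, 1)
REGION_TAILBUD <- c(0, 0.15)
REGION_FULL <- c(0, 1)

#' Conventional A/P regions
#'
#' Lookup of named regions of the normalized A/P axis used by the experiment
#' pipelines: `"P/2"` (posterior half, fast oscillators), `"A/2"` (anterior
#' half, slow oscillators), `"tailbud"` (very posterior PSM/tail bud) and
#' `"PSM"` (the full axis).
#'
#' @param name one of `"P/2"`, `"A/2"`, `"tailbud"`, `"PSM"`, or a numeric
#'   length-2 region passed through unchanged.
#' @return numeric length-2 region.
#' @export
ap_region <- function(name) {
  if (is.numeric(name)) return(check_region(name))
  switch(match.arg(name, c("P/2", "A/2", "tailbud", "PSM")),
         "P/2" = REGION_P2, "A/2" = REGION_A2,
         "tailbud" = REGION_TAILBUD, "PSM" = REGION_FULL)
}
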