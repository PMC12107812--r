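# Derringer-Suich desirability transforms and their weighted geometric
# aggregation.  Each transform maps a raw property value onto [0, 1]
# (1 = fully satisfactory); a weighted geometric mean combines the
# per-property desirabilities into one overall desirability D, and the
# engine minimizes cost = 1 - D.

#' Desirability parameter constructor
#'
#' @param shape \code{"larger_the_best"}, \code{"smaller_the_best"} or
#'   \code{"nominal_the_best"}.
#' @param l,u,t lower limit, upper limit and target.  The lower limit is
#'   not used by \code{smaller_the_best} nor the upper limit by
#'   \code{larger_the_best} (their formulas never reference them).
#' @param r exponent for the monotone shapes (default 1 = linear ramp).
#' @param r1,r2 rising/falling exponents for \code{nominal_the_best}.
#' @param w non-negative aggregation weight (default 1).
#' @return A \linkS4class{DesirabilityParams}.
#' @export
desirabilityParams <- function(shape, l = NA_real_, u = NA_real_, t,
                               r = 1, r1 = 1, r2 = 1, w = 1) {
  new("DesirabilityParams", shape = shape, l = as.numeric(l),
      u = as.numeric(u), t = as.numeric(t), r = as.numeric(r),
      r1 = as.numeric(r1), r2 = as.numeric(r2), w = as.numeric(w))
}

#' Larger-the-best desirability
#'
#' 0 below the lower limit \code{l}, \eqn{((x-l)/(t-l))^r} on
#' \eqn{[l, t]}, and 1 above the target \code{t}.  Knot points take the
#' closed-interval branch, so \code{x = l} gives 0 and \code{x = t} gives 1.
#'
#' @param x numeric value(s) of the raw property.
#' @param p \linkS4class{DesirabilityParams} with shape
#'   \code{larger_the_best}.
#' @return numeric in [0, 1], vectorized over \code{x}.
#' @export
largerTheBest <- function(x, p) {
  stopifnot(is(p, "DesirabilityParams"))
  if (p@shape != "larger_the_best" || is.na(p@l) || p@l >= p@t)
    stop("parameter error: larger_the_best requires l < t", call. = FALSE)
  d <- ((x - p@l) / (p@t - p@l))^p@r
  d[x < p@l] <- 0
  d[x > p@t] <- 1
  pmin(pmax(d, 0), 1)
}

#' Smaller-the-best desirability
#'
#' 1 below the target \code{t}, \eqn{((u-x)/(u-t))^r} on \eqn{[t, u]},
#' and 0 above the upper limit \code{u}.
#'
#' @param x numeric value(s).
#' @param p \linkS4class{DesirabilityParams} with shape
#'   \code{smaller_the_best}.
#' @return numeric in [0, 1], vectorized over \code{x}.
#' @export
smallerTheBest <- function(x, p) {
  stopifnot(is(p, "DesirabilityParams"))
  if (p@shape != "smaller_the_best" || is.na(p@u) || p@t >= p@u)
    stop("parameter error: smaller_the_best requires t < u", call. = FALSE)
  d <- ((p@u - x) / (p@u - p@t))^p@r
  d[x < p@t] <- 1
  d[x > p@u] <- 0
  pmin(pmax(d, 0), 1)
}

#' Nominal-the-best desirability
#'
#' 0 outside \eqn{[l, u]}; rises as \eqn{((x-l)/(t-l))^{r_1}} on
#' \eqn{[l, t]} and falls as \eqn{((u-x)/(u-t))^{r_2}} on \eqn{(t, u]},
#' with its unique maximum of 1 exactly at the target.
#'
#' @param x numeric value(s).
#' @param p \linkS4class{DesirabilityParams} with shape
#'   \code{nominal_the_best}.
#' @return numeric in [0, 1], vectorized over \code{x}.
#' @export
nominalTheBest <- function(x, p) {
  stopifnot(is(p, "DesirabilityParams"))
  if (p@shape != "nominal_the_best" || is.na(p@l) || is.na(p@u) ||
      !(p@l < p@t && p@t < p@u))
    stop("parameter error: nominal_the_best requires l < t < u",
         call. = FALSE)
  d <- numeric(length(x))
  ris <- x >= p@l & x <= p@t
  fal <- x > p@t & x <= p@u
  d[ris] <- ((x[ris] - p@l) / (p@t - p@l))^p@r1
  d[fal] <- ((p@u - x[fal]) / (p@u - p@t))^p@r2
  pmin(pmax(d, 0), 1)
}

#' Apply a desirability transform
#'
#' Dispatches on the shape stored in \code{p}.
#'
#' @param x numeric value(s).
#' @param p \linkS4class{DesirabilityParams}.
#' @return numeric in [0, 1].
#' @export
applyDesirability <- function(x, p) {
  switch(p@shape,
         larger_the_best = largerTheBest(x, p),
         smaller_the_best = smallerTheBest(x, p),
         nominal_the_best = nominalTheBest(x, p))
}

#' Weighted geometric mean of desirabilities
#'
#' \eqn{D = (\prod_i d_i^{w_i})^{1/\sum_i w_i}}.  Any zero desirability
#' with positive weight annihilates the aggregate; a zero-weight factor is
#' ignored entirely (its value, even 0, does not contribute).
#'
#' @param d numeric desirabilities in [0, 1].
#' @param w non-negative weights, same length; their sum must be > 0.
#' @return numeric D in [0, 1].
#' @export
weightedGeometricMean <- function(d, w = rep(1, length(d))) {
  if (!length(d) || length(d) != length(w))
    stop("parameter error: d and w must be non-empty and equal length",
         call. = FALSE)
  if (any(w < 0))
    stop("parameter error: negative weight", call. = FALSE)
  sw <- sum(w)
  if (sw <= 0)
    stop("parameter error: at least one weight must be positive",
         call. = FALSE)
  if (any(d < -1e-12 | d > 1 + 1e-12))
    stop("parameter error: desirabilities must lie in [0, 1]",
         call. = FALSE)
  d <- pmin(pmax(d, 0), 1)
  act <- w > 0
  if (any(d[act] == 0)) return(0)
  exp(sum(w[act] * log(d[act])) / sw)
}

#' Default desirability set of the Cost fitness
#'
#' The standard three-property desirability configuration: the docking
#' score axis is smaller-the-best with target -10 and upper limit -2
#' kcal/mol, drug-likeness (qed) is larger-the-best with lower limit 0.1
#' and target 0.75, and synthetic accessibility is smaller-the-best with
#' target 3 and upper limit 7.  All exponents and weights are 1, so every
#' ramp is linear and the three properties aggregate evenly.
#'
#' @return named list of \linkS4class{DesirabilityParams} with elements
#'   \code{vina_score}, \code{qed}, \code{sa_score}.
#' @export
defaultDesirabilities <- function() {
  list(
    vina_score = desirabilityParams("smaller_the_best", t = -10, u = -2),
    qed = desirabilityParams("larger_the_best", l = 0.1, t = 0.75),
    sa_score = desirabilityParams("smaller_the_best", t = 3, u = 7)
  )
}

# ---- YAML (de)serialization of desirability tables -------------------------

.SHAPE_YAML <- c(larger_the_best = "LargerTheBest",
                 smaller_the_best = "SmallerTheBest",
                 nominal_the_best = "NominalTheBest")

#' Convert desirability parameters to/from their configuration keys
#'
#' Configuration files describe each property's desirability with the keys
#' \code{Function}, \code{LowerLimit}, \code{UpperLimit}, \code{Target},
#' \code{r} (or \code{r1}/\code{r2}) and \code{w}; a \code{LowerLimit} or
#' \code{UpperLimit} that the shape's formula never references may be
#' omitted or set to \code{"-"}.
#'
#' @param x named list as read from YAML.
#' @return \code{desirabilityFromConfig}: a
#'   \linkS4class{DesirabilityParams}; \code{desirabilityToConfig}: a
#'   named list.
#' @export
desirabilityFromConfig <- function(x) {
  shape <- names(.SHAPE_YAML)[match(x$Function, .SHAPE_YAML)]
  if (is.na(shape))
    stop("configuration error: unknown desirability Function ",
         sQuote(x$Function), call. = FALSE)
  num <- function(v, default = NA_real_) {
    if (is.null(v) || identical(v, "-")) default else as.numeric(v)
  }
  desirabilityParams(shape, l = num(x$LowerLimit), u = num(x$UpperLimit),
                     t = num(x$Target), r = num(x$r, 1),
                     r1 = num(x$r1, 1), r2 = num(x$r2, 1),
                     w = num(x$w, 1))
}

#' @rdname desirabilityFromConfig
#' @param p a \linkS4class{DesirabilityParams}.
#' @export
desirabilityToConfig <- function(p) {
  out <- list(Function = unname(.SHAPE_YAML[p@shape]),
              LowerLimit = if (is.na(p@l)) "-" else p@l,
              UpperLimit = if (is.na(p@u)) "-" else p@u,
              Target = p@t, w = p@w)
  if (p@shape == "nominal_the_best") {
    out$r1 <- p@r1; out$r2 <- p@r2
  } else out$r <- p@r
  out
}
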