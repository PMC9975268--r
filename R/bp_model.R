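# PWV / blood-pressure relation -------------------------------------------
#
# ECG-referenced cuff-less BP devices measure the pulse-arrival time
# PAT = PEP + PTT and convert it to pressure through a calibration curve.
# The published coefficients of such curves vary, so the relation is a
# pluggable component with two built-in monotone forms; every property of
# the uncertainty analysis is form-agnostic.  The curve maps SBP to an
# effective pulse-wave velocity, and the arterial path length (a fraction of
# body height) turns velocity into the device's arrival-time delay.

#' Construct a PWV/blood-pressure relation
#'
#' Two built-in forms, both strictly monotone and closed-form invertible
#' over the supported SBP range:
#' \describe{
#'   \item{`exponential`}{`pwv(sbp) = a * exp(b * sbp)` (defaults
#'     `a = 1.5` m/s, `b = 0.0073` per mmHg), the usual stiffening-artery
#'     shape whose slope steepens with pressure.}
#'   \item{`quadratic`}{`sbp = c0 + c1 * pwv + c2 * pwv^2` (defaults
#'     `c0 = 40`, `c1 = 8`, `c2 = 0.5`).}
#' }
#'
#' @param form `"exponential"` or `"quadratic"`.
#' @param params named numeric vector overriding the form's defaults.
#' @param height_m subject height in metres (default 1.80, a "standard"
#'   adult).
#' @param path_length_factor arterial path length as a fraction of height
#'   (default 0.5, heart-to-periphery convention).
#' @param sbp_support supported SBP range in mmHg (default 80-200).
#' @return Object of class `pwv_bp_model`.
#' @examples
#' mod <- pwv_bp_model()
#' pat_from_sbp(mod, sbp = 120, pep = 100)
#' @export
pwv_bp_model <- function(form = c("exponential", "quadratic"), params = NULL,
                         height_m = 1.80, path_length_factor = 0.5,
                         sbp_support = c(80, 200)) {
  form <- match.arg(form)
  defaults <- switch(form,
                     exponential = c(a = 1.5, b = 0.0073),
                     quadratic = c(c0 = 40, c1 = 8, c2 = 0.5))
  if (!is.null(params)) {
    bad <- setdiff(names(params), names(defaults))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    defaults[names(params)] <- params
  }
  if (height_m <= 0 || path_length_factor <= 0)
    stop("path length must be positive", call. = FALSE)
  m <- structure(list(form = form, params = defaults, height_m = height_m,
                      path_length_factor = path_length_factor,
                      sbp_support = sbp_support), class = "pwv_bp_model")
  # invertibility: pwv must be strictly increasing and positive on support
  s <- seq(sbp_support[1], sbp_support[2], length.out = 101)
  v <- pwv_at(m, s)
  if (any(!is.finite(v)) || any(v <= 0) || any(diff(v) <= 0))
    stop("model is not strictly monotone/positive over its SBP support",
         call. = FALSE)
  m
}

#' @export
print.pwv_bp_model <- function(x, ...) {
  cat("<pwv_bp_model> form:", x$form, "\n")
  cat("  params:", paste(names(x$params), signif(x$params, 4),
                         sep = "=", collapse = " "), "\n")
  cat("  path length:", x$height_m * x$path_length_factor, "m | SBP support:",
      paste(x$sbp_support, collapse = "-"), "mmHg\n")
  invisible(x)
}

.check_support <- function(model, sbp) {
  if (any(sbp < model$sbp_support[1] - 1e-9 |
            sbp > model$sbp_support[2] + 1e-9))
    stop("SBP outside the model support [",
         model$sbp_support[1], ", ", model$sbp_support[2], "] mmHg",
         call. = FALSE)
  invisible(sbp)
}

#' Pulse-wave velocity at a given SBP
#' @param model a [pwv_bp_model()].
#' @param sbp systolic pressure, mmHg (within the model support).
#' @return velocity in m/s.
#' @export
pwv_at <- function(model, sbp) {
  p <- model$params
  switch(model$form,
         exponential = p["a"] * exp(p["b"] * sbp),
         quadratic = (-p["c1"] + sqrt(p["c1"]^2 - 4 * p["c2"] * (p["c0"] - sbp))) /
           (2 * p["c2"])) |> unname()
}

#' Device arrival-time delay implied by an SBP level
#'
#' The model curve gives the transit delay `path_length / pwv(sbp)`; adding
#' a pre-ejection period yields the ECG-referenced pulse-arrival time, so
#' `pat_from_sbp(model, sbp, pep = 0)` is exactly the transit component and
#' `PAT = PTT + PEP` holds to machine precision.
#'
#' @inheritParams pwv_at
#' @param pep pre-ejection period in ms (default 0).
#' @return Time in ms.
#' @export
pat_from_sbp <- function(model, sbp, pep = 0) {
  .check_support(model, sbp)
  if (any(pep < 0)) stop("pep must be non-negative", call. = FALSE)
  ptt_at(model, sbp) + pep
}

#' @rdname pat_from_sbp
#' @export
ptt_at <- function(model, sbp) {
  .check_support(model, sbp)
  1000 * model$height_m * model$path_length_factor / pwv_at(model, sbp)
}

#' Invert the model: SBP from a transit delay
#'
#' Closed-form inverse of [ptt_at()]; errors when the delay maps outside the
#' supported SBP range.
#'
#' @param model a [pwv_bp_model()].
#' @param ptt delay in ms.
#' @return SBP in mmHg.
#' @export
sbp_from_ptt <- function(model, ptt) {
  if (any(ptt <= 0)) stop("ptt must be positive", call. = FALSE)
  path <- model$height_m * model$path_length_factor
  v <- 1000 * path / ptt
  p <- model$params
  sbp <- switch(model$form,
                exponential = log(v / p["a"]) / p["b"],
                quadratic = p["c0"] + p["c1"] * v + p["c2"] * v^2) |> unname()
  .check_support(model, sbp)
  sbp
}
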