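# Shared helpers ----------------------------------------------------------

#' Controlled vocabulary of measurement phases
#'
#' The protocol comprises a baseline rest measurement, eight Trier Social
#' Stress Test questions (`tsst_Q1`..`tsst_Q8`), up to ten ergometer treading
#' measurements (`ergo_E1`..`ergo_E10`), six break/recovery measurements
#' (`ergo_B1`..`ergo_B6`) and an optional terminal `final_rest`.
#'
#' @return Character vector of admissible phase labels, in protocol order.
#' @export
phase_levels <- function() {
  c("rest",
    paste0("tsst_Q", 1:8),
    paste0("ergo_E", 1:10),
    paste0("ergo_B", 1:6),
    "final_rest")
}

#' Map a phase label to its load state
#'
#' States drive the stratified regressions and the load classifier:
#' `rest` (baseline, late break measurements once heart rate has returned to
#' baseline, final rest), `mental` (TSST questions), `physical` (active
#' treading) and `recovery` (the first measurement of each break, taken while
#' heart rate is still falling; excluded from the three-state analyses).
#'
#' @param phase character vector of phase labels (see [phase_levels()]).
#' @return Character vector of states: `"rest"`, `"mental"`, `"physical"` or
#'   `"recovery"`.
#' @examples
#' phase_state(c("rest", "tsst_Q3", "ergo_E5", "ergo_B1", "ergo_B2"))
#' @export
phase_state <- function(phase) {
  bad <- setdiff(unique(phase), phase_levels())
  if (length(bad))
    stop("unknown phase label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  out <- rep("rest", length(phase))
  out[grepl("^tsst_Q", phase)] <- "mental"
  out[grepl("^ergo_E", phase)] <- "physical"
  out[phase %in% c("ergo_B1", "ergo_B4")] <- "recovery"
  out[phase %in% c("ergo_B2", "ergo_B3", "ergo_B5", "ergo_B6")] <- "rest"
  out
}

# derive independent sub-stream seeds from one master seed; values stay
# below .Machine$integer.max
.derive_seeds <- function(seed, n) {
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# R^2 of a simple least-squares fit y ~ x (optionally polynomial)
.r_squared <- function(fit) summary(fit)$r.squared

.stop_if_constant <- function(x, label) {
  if (length(unique(x[is.finite(x)])) < 2L)
    stop("predictor '", label, "' is constant; correlation undefined",
         call. = FALSE)
  invisible(x)
}
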