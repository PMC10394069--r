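#' Ancient-DNA damage and library parameters
#'
#' Parameters of the read simulator's two-rate deamination model, in the
#' Briggs-style overhang/core parameterisation: each fragment terminus carries
#' a single-stranded overhang whose length is geometric with parameter
#' `overhang_p` (number of overhanging bases = failures before first success,
#' so a read position `i` bases from the 5' end lies in the overhang with
#' probability `(1 - overhang_p)^i`).  Cytosines deaminate with probability
#' `delta_ss` inside an overhang and `delta_ds` in the double-stranded core;
#' on the sequenced strand this shows as C->T near the 5' end and, through the
#' complementary strand, G->A near the 3' end.
#'
#' Defaults are conventional ancient-DNA values; the underlying studies report
#' the damage signature only qualitatively, so every value is overridable.
#'
#' @param overhang_p Geometric parameter for overhang length, in (0, 1].
#' @param delta_ss Deamination probability in single-stranded overhangs.
#' @param delta_ds Deamination probability in the double-stranded core.
#' @param frag_mean Median fragment length in bases (`meanlog = log(frag_mean)`
#'   of the log-normal length model).
#' @param frag_sd Log-scale standard deviation of fragment length.
#' @param seq_error Per-base uniform sequencing error rate.
#' @param coverage Target mean depth.
#' @return A `damage_params` object.
#' @examples
#' damage_params(delta_ss = 0.5, coverage = 10)
#' @export
damage_params <- function(overhang_p = 0.3, delta_ss = 0.4, delta_ds = 0.02,
                          frag_mean = 70, frag_sd = 0.3, seq_error = 0.001,
                          coverage = 30) {
  probs <- c(overhang_p = overhang_p, delta_ss = delta_ss,
             delta_ds = delta_ds, seq_error = seq_error)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (overhang_p <= 0)
    stop("`overhang_p` must be > 0 (geometric parameter)", call. = FALSE)
  if (!is.finite(frag_mean) || frag_mean <= 0)
    stop("`frag_mean` must be > 0", call. = FALSE)
  if (!is.finite(frag_sd) || frag_sd < 0)
    stop("`frag_sd` must be >= 0", call. = FALSE)
  if (!is.finite(coverage) || coverage <= 0)
    stop("`coverage` must be > 0", call. = FALSE)
  structure(
    list(overhang_p = overhang_p, delta_ss = delta_ss, delta_ds = delta_ds,
         frag_mean = frag_mean, frag_sd = frag_sd, seq_error = seq_error,
         coverage = coverage),
    class = "damage_params"
  )
}

#' @export
print.damage_params <- function(x, ...) {
  cat(sprintf(
    "<damage_params> overhang_p=%.3g delta_ss=%.3g delta_ds=%.3g frag~LN(log %.4g, %.3g) err=%.3g cov=%.3gx\n",
    x$overhang_p, x$delta_ss, x$delta_ds, x$frag_mean, x$frag_sd,
    x$seq_error, x$coverage))
  invisible(x)
}

# Expected fragment length under the log-normal model.
lognormal_mean <- function(params) {
  exp(log(params$frag_mean) + params$frag_sd^2 / 2)
}

# Closed-form expected C->T rate at 5'-distance i (1-based) on reference-C
# sites, marginalising over the geometric overhang; used by tests as the
# independent oracle for the profiler.  The symmetric G->A rate at 3'-distance
# i is identical by construction.
expected_ct_rate <- function(params, i = 1) {
  p_over <- (1 - params$overhang_p)^i
  dam <- params$delta_ss * p_over + params$delta_ds * (1 - p_over)
  # a sequencing error converts C to one of three bases, T being one of them
  dam + (1 - dam) * params$seq_error / 3
}
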