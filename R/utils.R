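#' Logit and inverse-logit transforms
#'
#' Thin wrappers over [stats::qlogis()] / [stats::plogis()] used throughout:
#' the formative-stage solution process lives on the logit scale, the
#' decline-stage one on the log scale.
#'
#' @param p abundance in (0, 1).
#' @param x real value.
#' @return `logit()` returns log(p/(1-p)); `invlogit()` returns 1/(1+exp(-x)).
#' @export
logit <- function(p) stats::qlogis(p)

#' @rdname logit
#' @export
invlogit <- function(x) stats::plogis(x)

# Derive a reproducible 32-bit sub-seed from a top-level seed and a stream
# label, so subsystems (flow, cohorts, fixtures) draw independently.
sub_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729 + 1) %% 2147483647)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG state is restored afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Shared argument checks ------------------------------------------------

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  }
  if (positive && x <= 0) stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  if (nonneg && x < 0) stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  invisible(x)
}

# Uniform-grid check with relative tolerance on the step.
check_uniform_grid <- function(times, rel_tol = 1e-9) {
  if (length(times) < 2L) stop("time grid needs at least 2 points", call. = FALSE)
  d <- diff(times)
  if (any(d <= 0)) stop("time grid must be strictly increasing", call. = FALSE)
  if (max(abs(d - d[1])) > rel_tol * max(abs(d[1]), 1)) {
    stop("time grid must be uniformly spaced", call. = FALSE)
  }
  d[1]
}
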