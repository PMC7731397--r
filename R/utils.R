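#' @keywords internal
#' @importFrom stats runif rnorm
"_PACKAGE"

# Evaluate `expr` under a local RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Splittable per-item seed: derives a child seed below 2^31 from a base seed
# and an item index, so each image draws from an independent stream.
derive_seed <- function(base_seed, index) {
  stopifnot(is.numeric(base_seed), is.numeric(index))
  as.integer((as.numeric(base_seed) %% 2147483647 + 1000003 * as.numeric(index)) %% 2147483647)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Round half-up to a given number of decimals
#'
#' Rounds `x` with ties going away from zero at the requested precision, the
#' convention used when reporting germination rates and composition shares
#' (e.g. 453/600 -> 76 percent).
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places (default 0).
#' @return numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(75.5)   # 76
#' round_half_up(87.45, 1)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Stop with a classed condition so callers can distinguish parameter errors
# from degenerate-input errors.
stop_param <- function(msg, class = "seedxray_parameter_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stop_degenerate <- function(msg) stop_param(msg, class = "seedxray_degenerate_error")

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
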