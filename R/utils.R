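#' @importFrom methods new validObject is slot setValidity show
#' @importFrom stats rgamma rmultinom rpois rnorm runif rbinom quantile
#'   setNames
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame
NULL

# Derive a reproducible 32-bit substream seed from a master seed and a stage
# name, so independent pipeline stages draw from independent streams.
substreamSeed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 31 + k) %% 2147480989
  as.integer((abs(seed) %% 2147480989 * 1009 + h) %% 2147480989 + 1)
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf,
                               integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (x < lower || x > upper)
    stop(sprintf("'%s' must be in [%s, %s]", name, lower, upper),
         call. = FALSE)
  if (integer && x != round(x))
    stop(sprintf("'%s' must be an integer", name), call. = FALSE)
  invisible(x)
}

# Dirichlet draws via normalized gamma variates; rows are samples.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(rgamma(n * k, shape = alpha, rate = 1), nrow = n, byrow = TRUE)
  sums <- rowSums(x)
  # Guard against all-zero rows from tiny shapes (numerically possible).
  bad <- sums <= 0
  if (any(bad)) {
    x[bad, ] <- matrix(rep(alpha / sum(alpha), sum(bad)),
                       nrow = sum(bad), byrow = TRUE)
    sums[bad] <- 1
  }
  x / sums
}
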