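#' @useDynLib pgsdisparity, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef lm glm plogis qnorm pnorm rnorm runif rbinom sd var
#'   quantile complete.cases terms model.matrix predict uniroot cor binomial
#'   setNames
#' @importFrom utils write.csv read.csv packageVersion
NULL

# Run `expr` under a private RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package functions never clobber the
# user's stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic substream seeds derived from a master seed; kept below 2^31.
derive_seed <- function(seed, i) {
  x <- (as.numeric(seed) %% 2147483647) * 48271 + as.numeric(i) * 69621
  as.integer(x %% 2147483629) + 1L
}

# Polynomial rolling hash of a deparsed object, for config fingerprints in
# output metadata (not cryptographic).
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

check_scalar <- function(x, field, positive = FALSE, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_field(field, "must be a finite numeric scalar")
  if (positive && x <= 0) stop_field(field, "must be strictly positive")
  if (integer && x != round(x)) stop_field(field, "must be an integer")
  invisible(x)
}
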