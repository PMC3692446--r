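#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global random stream set to `seed`, then restores the
#' previous stream so library calls never perturb a caller's randomness.
#' All stochastic functions in the package route through this helper.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a per-stage seed from the pipeline's global seed
#'
#' One global seed fans out deterministically so every stage is independently
#' reproducible: stage k uses `seed + k`.
#'
#' @param seed global integer seed.
#' @param stage integer stage index (0-based).
#' @return integer seed for the stage.
#' @export
stage_seed <- function(seed, stage) {
  as.integer(seed) + as.integer(stage)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

LAYER_LEVELS <- c("extracellular", "membrane", "cytoplasm", "nucleus")

CONDITION_LEVELS <- c("UC", "CRC")
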