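`%||%` <- function(x, y) if (is.null(x)) y else x

#' Run code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded package internals do not
#' perturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Parse numbers that may carry a Unicode minus (U+2212) or surrounding blanks.
# Unparseable entries become NA without warnings; "" and "NA" are NA.
parse_num <- function(x) {
  x <- trimws(as.character(x))
  x <- gsub("−", "-", x)
  x[x %in% c("", "NA", "na", "NaN")] <- NA_character_
  suppressWarnings(as.numeric(x))
}

stopf <- function(fmt, ..., class = "screenclean_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error")))
}
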